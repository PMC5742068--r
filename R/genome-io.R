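#' Coerce a genome to a named character vector of uppercase sequences
#'
#' Accepts a FASTA path (gzip accepted), a [Biostrings::DNAStringSet], or a
#' named character vector.  Sequences are uppercased and validated against
#' the \{A, C, G, T, N\} alphabet; anything else is rejected.
#'
#' @param x FASTA path, `DNAStringSet`, or named character vector.
#' @return Named character vector of sequences.
#' @export
as_genome <- function(x) {
  if (inherits(x, "DNAStringSet")) {
    out <- toupper(as.character(x))
  } else if (is.character(x) && length(x) == 1 && is.null(names(x)) &&
             file.exists(x)) {
    out <- toupper(as.character(Biostrings::readDNAStringSet(x)))
    names(out) <- sub("\\s.*$", "", names(out))
  } else if (is.character(x)) {
    out <- toupper(x)
  } else {
    stop("cannot interpret input as a genome")
  }
  if (is.null(names(out)) || anyDuplicated(names(out)) || any(names(out) == ""))
    stop("sequence names must be present and unique")
  if (any(nchar(out) == 0)) stop("empty sequences are not allowed")
  bad <- grepl("[^ACGTN]", out)
  if (any(bad))
    stop("non-ACGTN characters in sequence(s): ",
         paste(names(out)[bad], collapse = ", "))
  out
}

#' Write a genome to FASTA
#'
#' @param genome Named character vector or `DNAStringSet`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  if (!inherits(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(unlist(genome))
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read a repeat/feature annotation as 0-based half-open intervals
#'
#' BED input (0-based half-open) and GFF3 input (1-based inclusive) are both
#' normalised to the package-internal 0-based half-open convention.  The
#' dialect is auto-detected from the file extension and can be overridden.
#'
#' @param x Path to a BED or GFF3 file, or a data frame already holding
#'   `seqname`, `start`, `end` (0-based half-open) and optionally `label`.
#' @param format `"auto"`, `"bed"` or `"gff3"`.
#' @return Tibble with columns `seqname`, `start`, `end`, `label`.
#' @export
read_annotation <- function(x, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (is.data.frame(x)) {
    stopifnot(all(c("seqname", "start", "end") %in% names(x)))
    out <- as_tibble(x)
    if (!"label" %in% names(out)) out$label <- "repeat"
    return(out[, c("seqname", "start", "end", "label")])
  }
  if (format == "auto") {
    format <- if (grepl("\\.gff3?(\\.gz)?$", x, ignore.case = TRUE))
      "gff3" else "bed"
  }
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(x, format = if (format == "bed") "BED" else "GFF3")
    lab <- if (!is.null(gr$name)) as.character(gr$name)
      else if (!is.null(gr$type)) as.character(gr$type) else "repeat"
    df <- as.data.frame(gr)
    tibble(
      seqname = as.character(df$seqnames),
      start = as.integer(df$start) - 1L,  # GRanges is 1-based inclusive
      end = as.integer(df$end),
      label = lab
    )
  } else {
    # minimal fallback readers
    if (format == "bed") {
      tab <- readr::read_tsv(x, col_names = FALSE, comment = "#",
                             show_col_types = FALSE)
      tibble(seqname = as.character(tab[[1]]), start = as.integer(tab[[2]]),
             end = as.integer(tab[[3]]),
             label = if (ncol(tab) >= 4) as.character(tab[[4]]) else "repeat")
    } else {
      tab <- readr::read_tsv(x, col_names = FALSE, comment = "#",
                             show_col_types = FALSE)
      tibble(seqname = as.character(tab[[1]]),
             start = as.integer(tab[[4]]) - 1L, end = as.integer(tab[[5]]),
             label = as.character(tab[[3]]))
    }
  }
}

#' Write intervals as BED (0-based half-open)
#' @param ann Tibble with `seqname`, `start`, `end` and optionally `label`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(ann, path) {
  lab <- if ("label" %in% names(ann)) ann$label else "."
  readr::write_tsv(tibble(ann$seqname, ann$start, ann$end, lab),
                   path, col_names = FALSE)
  invisible(path)
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# mask intervals to 'N' (anchoring only; callers keep the unmasked original)
mask_sequences <- function(genome, mask) {
  if (is.null(mask)) return(genome)
  mask <- read_annotation(mask)
  for (i in seq_len(nrow(mask))) {
    sn <- mask$seqname[i]
    if (!sn %in% names(genome)) next
    s <- max(0L, mask$start[i])
    e <- min(nchar(genome[[sn]]), mask$end[i])
    if (e > s)
      substr(genome[[sn]], s + 1L, e) <- strrep("N", e - s)
  }
  genome
}
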