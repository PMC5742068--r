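#' Find maximal exact matches between two assemblies
#'
#' Enumerates every maximal exact match (MEM) of length at least `min_len`
#' between a reference and a query assembly, optionally restricted to
#' matches whose reference substring is unique in the reference (the
#' `mumreference` behaviour) and optionally on both strands.  `N` (and any
#' masked position) never matches anything, so masked intervals are
#' excluded from anchoring while base-level alignment later still sees the
#' real sequence.
#'
#' Query coordinates are reported on the searched strand: for `-` matches,
#' `qry_start` counts from the start of the reverse-complemented query
#' sequence.  All coordinates are 0-based half-open internally.
#'
#' @param ref,qry Genomes (FASTA path, `DNAStringSet`, or named character
#'   vector; see [as_genome()]).
#' @param min_len Minimum match length in bp.
#' @param unique_in_ref Keep only matches whose reference substring occurs
#'   exactly once in the whole reference.
#' @param both_strands Also search the reverse complement of the query.
#' @param ref_mask,qry_mask Optional repeat masks (BED/GFF3 path or interval
#'   data frame; see [read_annotation()]) excluded from anchoring.
#' @return Tibble with one row per match: `ref_name`, `ref_start`,
#'   `qry_name`, `qry_start`, `length`, `strand`, `qry_len`.
#' @export
find_mems <- function(ref, qry, min_len = 20, unique_in_ref = TRUE,
                      both_strands = TRUE, ref_mask = NULL, qry_mask = NULL) {
  stopifnot(min_len >= 1)
  ref <- as_genome(ref)
  qry <- as_genome(qry)
  ref_anchor <- mask_sequences(ref, ref_mask)
  qry_anchor <- mask_sequences(qry, qry_mask)

  # concatenate reference sequences (N-separated) so that ref-uniqueness is
  # assessed over the whole reference, as mumreference does
  sep <- strrep("N", 50)
  refcat <- paste(ref_anchor, collapse = sep)
  offsets <- cumsum(c(0L, head(nchar(ref_anchor) + nchar(sep), -1)))
  names(offsets) <- names(ref_anchor)

  run_one <- function(qseqs, strand) {
    hits <- .mem_find_cpp(refcat, unname(qseqs), as.integer(min_len),
                          isTRUE(unique_in_ref))
    if (nrow(hits) == 0) return(NULL)
    # map concatenated coordinates back to sequences
    ridx <- findInterval(hits$ref_start, offsets)
    tibble(
      ref_name = names(offsets)[ridx],
      ref_start = hits$ref_start - unname(offsets)[ridx],
      qry_name = names(qseqs)[hits$qry_idx],
      qry_start = hits$qry_start,
      length = hits$length,
      strand = strand,
      qry_len = unname(nchar(qry)[names(qseqs)[hits$qry_idx]])
    )
  }

  out <- list(run_one(qry_anchor, "+"))
  if (both_strands)
    out <- c(out, list(run_one(
      setNames(reverse_complement(qry_anchor), names(qry_anchor)), "-")))
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble(ref_name = character(), ref_start = integer(),
                  qry_name = character(), qry_start = integer(),
                  length = integer(), strand = character(),
                  qry_len = integer())
  }
  arrange(res, .data$ref_name, .data$qry_name, .data$strand,
          .data$ref_start, .data$qry_start)
}

#' Convert strand-local query coordinates to forward-strand coordinates
#'
#' @param start,end 0-based half-open interval on the searched strand.
#' @param strand `"+"` or `"-"`.
#' @param qry_len Length of the query sequence.
#' @return Tibble with forward-strand `start`, `end`.
#' @export
strand_to_forward <- function(start, end, strand, qry_len) {
  fs <- ifelse(strand == "+", start, qry_len - end)
  fe <- ifelse(strand == "+", end, qry_len - start)
  tibble(start = as.integer(fs), end = as.integer(fe))
}
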