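#' Discover structural variants between two assemblies
#'
#' End-to-end assembly-to-assembly SV discovery: maximal exact matches are
#' chained into clusters in both directions (reference vs query and query
#' vs reference), filled to base-level alignments, filtered to one-to-one
#' synteny blocks and stitched across sub-structural gaps.  Overlapping
#' clusters yield copy-number gain/loss candidates that are verified by
#' re-alignment copy counting; block gaps yield insertions and deletions;
#' reverse-orientation blocks yield inversions; block columns yield SNPs
#' and small indels.  Nearby CNVs are merged into complex events.
#'
#' @param ref,qry Genomes (FASTA path, `DNAStringSet`, or named character).
#' @param repeats_ref,repeats_qry Optional repeat annotations used for TE
#'   classification and inversion filtering.
#' @param min_match Minimum anchor length (bp).
#' @param cluster_sep,cluster_frac Cluster chaining parameters `s` and `f`.
#' @param min_sv Minimum structural-variant length (bp); also the cluster
#'   `l` parameter.
#' @param merge_dist Complex-event merge distance (bp).
#' @param verify Verify copy-number candidates by re-alignment and drop
#'   equal-copy false positives.
#' @param min_identity Identity floor for blocks entering one-to-one
#'   filtering; alignments below it (diverged repeat-family homology) are
#'   not competing placements of unique sequence.
#' @param regions Optional include-regions annotation (e.g. euchromatin);
#'   calls outside it are dropped.
#' @return An `sv_catalog`: list with `calls`, `small_variants`, `events`,
#'   `counts`, `affected_bp`, `blocks`, `clusters_fwd`, `clusters_rev`,
#'   `params`.
#' @export
sv_call <- function(ref, qry, repeats_ref = NULL, repeats_qry = NULL,
                    min_match = 20, cluster_sep = 200, cluster_frac = 0.12,
                    min_sv = 100, merge_dist = 2000, verify = TRUE,
                    regions = NULL, min_identity = 0.95) {
  ref <- as_genome(ref)
  qry <- as_genome(qry)

  mems_fwd <- find_mems(ref, qry, min_len = min_match)
  clusters_fwd <- cluster_matches(mems_fwd, s = cluster_sep, f = cluster_frac,
                                  l = min_sv)
  mems_rev <- find_mems(qry, ref, min_len = min_match)
  clusters_rev <- cluster_matches(mems_rev, s = cluster_sep, f = cluster_frac,
                                  l = min_sv)

  # diverged repeat-to-repeat alignments (low identity) are not competing
  # placements of unique sequence; an identity floor keeps them out of the
  # one-to-one selection, as alignment-identity filters do in this setting
  blocks <- fill_clusters(clusters_fwd, ref, qry) |>
    filter(.data$identity >= min_identity) |>
    filter_mutual_best("both", rescue = TRUE, min_len = min_sv,
                       ref = ref, qry = qry) |>
    stitch_blocks(ref, qry, max_gap = min_sv)

  # copy-number candidates from overlapping clusters, both polarities
  gains <- call_duplications(clusters_fwd, min_len = min_sv)
  losses_raw <- call_duplications(clusters_rev, min_len = min_sv)
  losses <- if (nrow(losses_raw) > 0) {
    tibble(
      sv_type = "CNV_LOSS_QRY",
      ref_name = losses_raw$qry_name, ref_start = losses_raw$qry_start,
      ref_end = losses_raw$qry_end, qry_name = losses_raw$ref_name,
      qry_start = losses_raw$ref_start, qry_end = losses_raw$ref_end,
      length = losses_raw$length, te_status = NA_character_,
      spacer_start = losses_raw$spacer_start,
      spacer_end = losses_raw$spacer_end,
      copies_ref = NA_integer_, copies_qry = NA_integer_,
      evidence = losses_raw$evidence
    )
  } else sv_call_schema()

  cnvs <- bind_rows(gains, losses)
  # duplicated units that are pure repeat sequence are TE-family matches,
  # not unique-sequence CNVs; drop them as the repeat filter
  if (nrow(cnvs) > 0) {
    ann_ref <- if (!is.null(repeats_ref)) read_annotation(repeats_ref)
    ann_qry <- if (!is.null(repeats_qry)) read_annotation(repeats_qry)
    te_cov <- vapply(seq_len(nrow(cnvs)), function(i) {
      if (cnvs$sv_type[i] == "CNV_GAIN_QRY") {
        if (is.null(ann_ref)) return(0)
        coverage_fraction(cnvs$ref_start[i], cnvs$ref_end[i],
                          ann_ref[ann_ref$seqname == cnvs$ref_name[i], ])
      } else {
        if (is.null(ann_qry)) return(0)
        coverage_fraction(cnvs$qry_start[i], cnvs$qry_end[i],
                          ann_qry[ann_qry$seqname == cnvs$qry_name[i], ])
      }
    }, numeric(1))
    cnvs <- cnvs[te_cov < 0.8, , drop = FALSE]
  }
  if (verify && nrow(cnvs) > 0) {
    keep <- logical(nrow(cnvs))
    for (i in seq_len(nrow(cnvs))) {
      unit <- if (cnvs$sv_type[i] == "CNV_GAIN_QRY") {
        substr(ref[[cnvs$ref_name[i]]], cnvs$ref_start[i] + 1,
               cnvs$ref_end[i])
      } else {
        substr(qry[[cnvs$qry_name[i]]], cnvs$qry_start[i] + 1,
               cnvs$qry_end[i])
      }
      if (nchar(unit) < 100) { keep[i] <- FALSE; next }
      rep <- verify_copy_number(unit, ref, qry)
      cnvs$copies_ref[i] <- rep$copies_ref
      cnvs$copies_qry[i] <- rep$copies_qry
      keep[i] <- rep$accepted
    }
    cnvs <- cnvs[keep, , drop = FALSE]
  }

  indels <- call_indels(blocks, min_len = min_sv)
  divergent <- indels[indels$sv_type == "DIVERGENT", , drop = FALSE]
  indels <- indels[indels$sv_type != "DIVERGENT", , drop = FALSE]
  # an indel footprint inside a CNV span is the duplication seen twice
  if (nrow(indels) > 0 && nrow(cnvs) > 0) {
    sup <- vapply(seq_len(nrow(indels)), function(i) {
      ins <- indels$sv_type[i] == "INS_QRY"
      any(vapply(seq_len(nrow(cnvs)), function(j) {
        if (ins) {
          !is.na(cnvs$qry_start[j]) &&
            indels$qry_name[i] == cnvs$qry_name[j] &&
            interval_overlap(indels$qry_start[i], indels$qry_end[i],
                             cnvs$qry_start[j], cnvs$qry_end[j]) > 0
        } else {
          indels$ref_name[i] == cnvs$ref_name[j] &&
            interval_overlap(indels$ref_start[i], indels$ref_end[i],
                             cnvs$ref_start[j], cnvs$ref_end[j]) > 0
        }
      }, logical(1)))
    }, logical(1))
    indels <- indels[!sup, , drop = FALSE]
  }

  invs <- call_inversions(blocks, repeats = repeats_ref, min_len = min_sv)

  small <- call_snps_small_indels(blocks, ref, qry, max_len = min_sv)
  # gap runs >= min_sv living inside stitched blocks are structural
  big_in_block <- small[small$kind %in% c("INS_GE", "DEL_GE"), , drop = FALSE]
  small <- small[!small$kind %in% c("INS_GE", "DEL_GE"), , drop = FALSE]
  if (nrow(big_in_block) > 0) {
    promoted <- tibble(
      sv_type = ifelse(big_in_block$kind == "INS_GE", "INS_QRY", "DEL_QRY"),
      ref_name = big_in_block$ref_name,
      ref_start = big_in_block$ref_pos,
      ref_end = big_in_block$ref_pos +
        ifelse(big_in_block$kind == "DEL_GE", big_in_block$length, 0L),
      qry_name = big_in_block$qry_name,
      qry_start = NA_integer_, qry_end = NA_integer_,
      length = big_in_block$length, te_status = NA_character_,
      spacer_start = NA_integer_, spacer_end = NA_integer_,
      copies_ref = NA_integer_, copies_qry = NA_integer_,
      evidence = "in-block gap"
    )
    dup_of_existing <- vapply(seq_len(nrow(promoted)), function(i) {
      any(indels$ref_name == promoted$ref_name[i] &
            abs(indels$ref_start - promoted$ref_start[i]) < 100)
    }, logical(1))
    indels <- bind_rows(indels, promoted[!dup_of_existing, , drop = FALSE])
  }

  calls <- bind_rows(cnvs, indels, invs) |>
    annotate_te_status(repeats_ref = repeats_ref, repeats_qry = repeats_qry)

  if (!is.null(regions) && nrow(calls) > 0) {
    reg <- read_annotation(regions)
    keep <- vapply(seq_len(nrow(calls)), function(i) {
      any(reg$seqname == calls$ref_name[i] &
            reg$start < calls$ref_end[i] & reg$end > calls$ref_start[i])
    }, logical(1))
    calls <- calls[keep, , drop = FALSE]
  }

  merged <- merge_complex_events(bind_rows(calls, divergent), d = merge_dist)

  structure(list(
    calls = merged$calls[merged$calls$sv_type != "DIVERGENT", , drop = FALSE],
    divergent = divergent,
    small_variants = small,
    events = merged$events,
    counts = merged$counts,
    affected_bp = merged$affected_bp,
    blocks = blocks,
    clusters_fwd = clusters_fwd,
    clusters_rev = clusters_rev,
    params = list(min_match = min_match, cluster_sep = cluster_sep,
                  cluster_frac = cluster_frac, min_sv = min_sv,
                  merge_dist = merge_dist, verify = verify)
  ), class = "sv_catalog")
}

#' @export
print.sv_catalog <- function(x, ...) {
  cat("<sv_catalog>\n")
  cat("  structural calls:", nrow(x$calls), "\n")
  if (nrow(x$counts) > 0) {
    for (i in seq_len(nrow(x$counts)))
      cat(sprintf("    %-14s %d\n", x$counts$sv_type[i],
                  x$counts$n_events[i]))
  }
  cat("  small variants:  ", nrow(x$small_variants), "\n")
  cat("  synteny blocks:  ", nrow(x$blocks), "\n")
  invisible(x)
}

#' Tidy an SV catalog into one row per structural call
#' @param x An `sv_catalog`.
#' @param ... Unused.
#' @export
tidy.sv_catalog <- function(x, ...) as_tibble(x$calls)

#' One-row summary of an SV catalog
#' @param x An `sv_catalog`.
#' @param ... Unused.
#' @export
glance.sv_catalog <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$counts, names_from = "sv_type",
                             values_from = "n_events")
  bind_cols(tibble(n_calls = nrow(x$calls),
                   n_small_variants = nrow(x$small_variants),
                   n_blocks = nrow(x$blocks),
                   affected_bp = sum(x$affected_bp$affected_bp)), wide)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot an SV catalog along the reference
#'
#' @param object An `sv_catalog`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sv_catalog <- function(object, ...) {
  calls <- object$calls
  ggplot2::ggplot(calls) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$ref_start / 1e3, xend = pmax(.data$ref_end,
                                             .data$ref_start + 200) / 1e3,
      y = .data$sv_type, yend = .data$sv_type, colour = .data$te_status),
      linewidth = 4) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$ref_name)) +
    ggplot2::labs(x = "reference position (kb)", y = NULL,
                  colour = "TE status") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Write an SV catalog as TSV (1-based inclusive coordinates)
#'
#' @param catalog An `sv_catalog`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_sv_tsv <- function(catalog, path) {
  calls <- catalog$calls
  out <- tibble(
    ref_name = calls$ref_name, ref_start = calls$ref_start + 1L,
    ref_end = calls$ref_end, qry_name = calls$qry_name,
    qry_start = calls$qry_start + 1L, qry_end = calls$qry_end,
    sv_type = calls$sv_type, te_status = calls$te_status,
    length = calls$length,
    spacer = ifelse(is.na(calls$spacer_start), ".",
                    paste0(calls$spacer_start + 1L, "-", calls$spacer_end)),
    evidence = calls$evidence
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write an SV catalog as VCF 4.2 with symbolic alleles
#'
#' @param catalog An `sv_catalog`.
#' @param ref Reference genome (for anchor bases).
#' @param path Output VCF path.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(catalog, ref, path) {
  ref <- as_genome(ref)
  calls <- catalog$calls
  alt_of <- c(CNV_GAIN_QRY = "<DUP>", CNV_LOSS_QRY = "<DEL>",
              INS_QRY = "<INS>", DEL_QRY = "<DEL>", INV = "<INV>")
  hdr <- c("##fileformat=VCFv4.2",
           "##source=svmap",
           paste0("##contig=<ID=", names(ref), ",length=", nchar(ref), ">"),
           "##ALT=<ID=DUP,Description=\"Duplication\">",
           "##ALT=<ID=DEL,Description=\"Deletion\">",
           "##ALT=<ID=INS,Description=\"Insertion\">",
           "##ALT=<ID=INV,Description=\"Inversion\">",
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
           "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
           "##INFO=<ID=TE,Number=1,Type=String,Description=\"TE status\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- character(0)
  if (nrow(calls) > 0) {
    svtype <- sub("<|>", "", sub("_QRY", "", calls$sv_type))
    svtype <- c(CNV_GAIN = "DUP", CNV_LOSS = "DEL", INS = "INS",
                DEL = "DEL", INV = "INV")[svtype]
    pos <- pmax(calls$ref_start, 1L)  # VCF anchors on the previous base
    anchor <- vapply(seq_len(nrow(calls)), function(i) {
      substr(ref[[calls$ref_name[i]]], pos[i], pos[i])
    }, character(1))
    svlen <- ifelse(calls$sv_type %in% c("DEL_QRY", "CNV_LOSS_QRY"),
                    -calls$length, calls$length)
    body <- paste(calls$ref_name, pos, paste0("sv", seq_len(nrow(calls))),
                  anchor, alt_of[calls$sv_type], ".", "PASS",
                  paste0("SVTYPE=", svtype, ";SVLEN=", svlen,
                         ";END=", pmax(calls$ref_end, pos + 1L),
                         ";TE=", calls$te_status),
                  sep = "\t")
  }
  readr::write_lines(c(hdr, body), path)
  invisible(path)
}

#' Write SNPs and small indels as VCF 4.2 with explicit alleles
#'
#' @param small Small-variant tibble from [call_snps_small_indels()].
#' @param ref Reference genome.
#' @param path Output VCF path.
#' @return `path`, invisibly.
#' @export
write_small_variant_vcf <- function(small, ref, path) {
  ref <- as_genome(ref)
  hdr <- c("##fileformat=VCFv4.2", "##source=svmap",
           paste0("##contig=<ID=", names(ref), ",length=", nchar(ref), ">"),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- character(0)
  if (nrow(small) > 0) {
    fields <- purrr::map_chr(seq_len(nrow(small)), function(i) {
      k <- small$kind[i]
      if (k == "SNP") {
        paste(small$ref_name[i], small$ref_pos[i] + 1L, ".",
              small$ref_allele[i], small$qry_allele[i], ".", "PASS", ".",
              sep = "\t")
      } else if (k == "INS") {
        p <- small$ref_pos[i]  # anchor base before the insertion
        anc <- substr(ref[[small$ref_name[i]]], p, p)
        if (p == 0) anc <- "N"
        paste(small$ref_name[i], max(p, 1L), ".", anc,
              paste0(anc, small$qry_allele[i]), ".", "PASS", ".", sep = "\t")
      } else {
        p <- small$ref_pos[i]
        anc <- substr(ref[[small$ref_name[i]]], p, p)
        if (p == 0) anc <- "N"
        paste(small$ref_name[i], max(p, 1L), ".",
              paste0(anc, small$ref_allele[i]), anc, ".", "PASS", ".",
              sep = "\t")
      }
    })
    body <- fields
  }
  readr::write_lines(c(hdr, body), path)
  invisible(path)
}
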