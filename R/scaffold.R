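#' Assign contigs to chromosome arms by mutually best alignment
#'
#' Each contig is assigned to the arm that holds the largest share of its
#' aligned bases, provided that share is at least `threshold` of the
#' contig's total alignment; otherwise it stays unplaced.  Orientation is
#' the strand carrying the majority of the contig's aligned bases on the
#' assigned arm.
#'
#' @param blocks Block (or cluster) tibble from the contig-vs-arms
#'   alignment, after single-axis mutually-best filtering
#'   ([filter_mutual_best()] with `mode = "qry"`): `qry_name` is the
#'   contig, `ref_name` the arm.
#' @param threshold Minimum aligned share on the best arm (default 0.40,
#'   exclusive: a share below the threshold is unplaced).
#' @return Tibble: `contig`, `arm` (`NA` = unplaced), `aligned_frac`,
#'   `orientation`, `anchor_start`, `aligned_len`, and an `alignments`
#'   list-column with the contig's blocks on its assigned arm.
#' @export
assign_contigs <- function(blocks, threshold = 0.40) {
  empty <- tibble(contig = character(), arm = character(),
                  aligned_frac = numeric(), orientation = character(),
                  anchor_start = integer(), aligned_len = numeric(),
                  alignments = list())
  if (is.null(blocks) || nrow(blocks) == 0) return(empty)
  per <- blocks |>
    group_by(contig = .data$qry_name, arm2 = .data$ref_name) |>
    summarise(aligned = sum(.data$weight), .groups = "drop_last") |>
    mutate(frac = .data$aligned / sum(.data$aligned)) |>
    slice_max(.data$aligned, n = 1, with_ties = FALSE) |>
    ungroup()
  purrr::map_dfr(seq_len(nrow(per)), function(i) {
    ctg <- per$contig[i]
    if (per$frac[i] < threshold) {
      return(tibble(contig = ctg, arm = NA_character_,
                    aligned_frac = per$frac[i], orientation = "+",
                    anchor_start = NA_integer_, aligned_len = per$aligned[i],
                    alignments = list(tibble())))
    }
    aln <- blocks[blocks$qry_name == ctg & blocks$ref_name == per$arm2[i], ]
    by_strand <- tapply(aln$weight, aln$strand, sum)
    ori <- names(by_strand)[which.max(by_strand)]
    tibble(contig = ctg, arm = per$arm2[i], aligned_frac = per$frac[i],
           orientation = ori,
           anchor_start = as.integer(min(aln$ref_start)),
           aligned_len = per$aligned[i], alignments = list(aln))
  })
}

#' Build scaffolds from contig assignments
#'
#' Per arm, contigs are ordered by the starting coordinate of their first
#' alignment that does not overlap the preceding contig's alignment;
#' reverse-orientation contigs are reverse-complemented and neighbours are
#' joined with exactly `gap` Ns.  Unplaced contigs are emitted unchanged
#' under a `U` prefix.
#'
#' @param assignments Tibble from [assign_contigs()].
#' @param contigs Contig sequences (see [as_genome()]).
#' @param gap Join gap length (bp; default 100).
#' @return List: `scaffolds` (named character), `plan` (ordered layout
#'   tibble), `agp` (AGP v2.1 tibble).
#' @export
build_scaffolds <- function(assignments, contigs, gap = 100) {
  contigs <- as_genome(contigs)
  if (anyDuplicated(names(contigs)) > 0) stop("duplicate contig names")
  placed <- assignments[!is.na(assignments$arm), , drop = FALSE]
  plan <- list()
  scaffolds <- character(0)
  agp <- list()
  for (arm in unique(placed$arm)) {
    aa <- placed[placed$arm == arm, , drop = FALSE]
    aa <- aa[order(aa$anchor_start, -aa$aligned_len), , drop = FALSE]
    # anchor = first alignment clear of the previous contig's alignment
    prev_end <- -Inf
    anchors <- integer(nrow(aa))
    for (i in seq_len(nrow(aa))) {
      aln <- aa$alignments[[i]]
      aln <- aln[order(aln$ref_start), ]
      free <- which(aln$ref_start >= prev_end)
      use <- if (length(free) > 0) free[1] else 1L
      anchors[i] <- aln$ref_start[use]
      prev_end <- max(prev_end, aln$ref_end[use])
    }
    ord <- order(anchors, -aa$aligned_len)
    if (anyDuplicated(anchors) > 0 &&
        anyDuplicated(aa$aligned_len[ord]) > 0)
      stop("unresolvable contig order tie on arm ", arm)
    aa <- aa[ord, , drop = FALSE]
    seqs <- vapply(seq_len(nrow(aa)), function(i) {
      s <- contigs[[aa$contig[i]]]
      if (aa$orientation[i] == "-") reverse_complement(s) else s
    }, character(1))
    scaffolds[[arm]] <- paste(seqs, collapse = strrep("N", gap))
    plan[[arm]] <- tibble(scaffold = arm, position = seq_len(nrow(aa)),
                          contig = aa$contig,
                          orientation = aa$orientation,
                          anchor_start = anchors[ord])
    # AGP rows: alternating contig components and gap rows
    beg <- 1L
    for (i in seq_len(nrow(aa))) {
      len <- nchar(seqs[i])
      agp[[length(agp) + 1]] <- tibble(
        object = arm, object_beg = beg, object_end = beg + len - 1L,
        part_number = 2L * i - 1L, component_type = "W",
        component_id = aa$contig[i], component_beg = "1",
        component_end = as.character(len),
        orientation = aa$orientation[i])
      beg <- beg + len
      if (i < nrow(aa)) {
        agp[[length(agp) + 1]] <- tibble(
          object = arm, object_beg = beg, object_end = beg + gap - 1L,
          part_number = 2L * i, component_type = "N",
          component_id = as.character(gap), component_beg = "scaffold",
          component_end = "yes", orientation = "align_genus")
        beg <- beg + gap
      }
    }
  }
  unplaced <- assignments$contig[is.na(assignments$arm)]
  unaligned <- setdiff(names(contigs), assignments$contig)
  for (ctg in c(unplaced, unaligned)) {
    scaffolds[[paste0("U", ctg)]] <- contigs[[ctg]]
    plan[[paste0("U", ctg)]] <- tibble(scaffold = paste0("U", ctg),
                                       position = 1L, contig = ctg,
                                       orientation = "+",
                                       anchor_start = NA_integer_)
  }
  list(scaffolds = scaffolds, plan = bind_rows(plan), agp = bind_rows(agp))
}

#' Reference-guided comparative scaffolding
#'
#' Aligns (optionally repeat-masked) contigs to reference chromosome arms,
#' filters to mutually best alignments along the contig axis, assigns each
#' contig to the arm holding at least 40% of its alignment, orders and
#' orients contigs along each arm and joins them with 100-N gaps.
#'
#' @param ref Reference arms (see [as_genome()]).
#' @param contigs Contig set to scaffold.
#' @param ref_mask,contig_mask Optional repeat masks excluded from
#'   anchoring.
#' @param min_match Anchor length (bp).
#' @param threshold Assignment threshold (fraction of aligned bases).
#' @param gap Join gap (bp).
#' @return List as [build_scaffolds()], plus `assignments`.
#' @export
scaffold_assembly <- function(ref, contigs, ref_mask = NULL,
                              contig_mask = NULL, min_match = 20,
                              threshold = 0.40, gap = 100) {
  ref <- as_genome(ref)
  contigs <- as_genome(contigs)
  mems <- find_mems(ref, contigs, min_len = min_match, ref_mask = ref_mask,
                    qry_mask = contig_mask)
  clusters <- cluster_matches(mems)
  blocks <- fill_clusters(clusters, ref, contigs) |>
    filter_mutual_best(mode = "qry")
  assignments <- assign_contigs(blocks, threshold = threshold)
  out <- build_scaffolds(assignments, contigs, gap = gap)
  out$assignments <- assignments
  out
}

#' Write an AGP v2.1 file
#'
#' @param agp AGP tibble from [build_scaffolds()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_agp <- function(agp, path) {
  readr::write_lines(c("##agp-version 2.1",
                       purrr::map_chr(seq_len(nrow(agp)), function(i) {
                         paste(unlist(agp[i, ]), collapse = "\t")
                       })), path)
  invisible(path)
}
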