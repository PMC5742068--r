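sv_call_schema <- function() {
  tibble(
    sv_type = character(), ref_name = character(), ref_start = integer(),
    ref_end = integer(), qry_name = character(), qry_start = integer(),
    qry_end = integer(), length = integer(), te_status = character(),
    spacer_start = integer(), spacer_end = integer(),
    copies_ref = integer(), copies_qry = integer(), evidence = character()
  )
}

#' Call duplications from overlapping alignment clusters
#'
#' When the reference intervals of two alignment clusters overlap by at
#' least `min_len` while their query intervals are disjoint, the
#' overlapping reference segment is inferred to be duplicated in the query
#' (a copy-number gain in the query).  When the two query-side copies are
#' separated by intervening sequence, the gap is recorded as the spacer
#' interval (the tandem-duplication-with-spacer geometry).
#'
#' @param clusters Cluster tibble from [cluster_matches()] for the
#'   reference-to-query run.
#' @param min_len Minimum reference overlap (bp).
#' @return SV-call tibble of `CNV_GAIN_QRY` records (query coordinates are
#'   forward-strand; the query interval spans both copies).
#' @export
call_duplications <- function(clusters, min_len = 100) {
  out <- sv_call_schema()
  if (is.null(clusters) || nrow(clusters) < 2) return(out)
  cl <- clusters
  rows <- list()
  for (rn in unique(cl$ref_name)) {
    cc <- cl[cl$ref_name == rn, ]
    if (nrow(cc) < 2) next
    for (i in seq_len(nrow(cc) - 1)) {
      for (j in seq((i + 1), nrow(cc))) {
        ov_s <- max(cc$ref_start[i], cc$ref_start[j])
        ov_e <- min(cc$ref_end[i], cc$ref_end[j])
        if (ov_e - ov_s < min_len) next
        # project the overlap through each cluster to get the copy intervals
        copy_i <- cluster_project(cc[i, ], ov_s, ov_e)
        copy_j <- cluster_project(cc[j, ], ov_s, ov_e)
        # query copies must be disjoint (different sequences qualify)
        same_q <- cc$qry_name[i] == cc$qry_name[j]
        if (same_q &&
            interval_overlap(copy_i[1], copy_i[2], copy_j[1], copy_j[2]) > 20)
          next
        q_s <- min(copy_i[1], copy_j[1])
        q_e <- max(copy_i[2], copy_j[2])
        gap_s <- min(copy_i[2], copy_j[2])
        gap_e <- max(copy_i[1], copy_j[1])
        has_spacer <- same_q && gap_e > gap_s
        rows[[length(rows) + 1]] <- tibble(
          sv_type = "CNV_GAIN_QRY", ref_name = rn,
          ref_start = as.integer(ov_s), ref_end = as.integer(ov_e),
          qry_name = cc$qry_name[i],
          qry_start = as.integer(if (same_q) q_s else NA),
          qry_end = as.integer(if (same_q) q_e else NA),
          length = as.integer(ov_e - ov_s), te_status = NA_character_,
          spacer_start = as.integer(if (has_spacer) gap_s else NA),
          spacer_end = as.integer(if (has_spacer) gap_e else NA),
          copies_ref = NA_integer_, copies_qry = NA_integer_,
          evidence = paste0("cl", cc$cluster_id[i], ",cl", cc$cluster_id[j])
        )
      }
    }
  }
  res <- bind_rows(out, rows)
  if (nrow(res) == 0) return(res)
  # collapse duplicate overlaps reported by multiple cluster pairs
  res |>
    group_by(.data$ref_name, .data$ref_start, .data$ref_end) |>
    slice(1) |>
    ungroup() |>
    arrange(.data$ref_name, .data$ref_start)
}

# project a reference interval through a cluster's anchors onto the query
# (forward-strand coordinates)
cluster_project <- function(cl, ref_s, ref_e) {
  m <- cl$matches[[1]]
  proj <- function(pos) {
    inside <- which(m$ref_start <= pos & pos <= m$ref_start + m$length)
    if (length(inside) > 0) {
      i <- inside[1]
      return(m$qry_start[i] + (pos - m$ref_start[i]))
    }
    d <- pmin(abs(pos - m$ref_start), abs(pos - (m$ref_start + m$length)))
    i <- which.min(d)
    if (pos < m$ref_start[i]) m$qry_start[i] - (m$ref_start[i] - pos)
    else m$qry_start[i] + m$length[i] + (pos - m$ref_start[i] - m$length[i])
  }
  s <- proj(ref_s); e <- proj(ref_e)
  fwd <- strand_to_forward(min(s, e), max(s, e), cl$strand, cl$qry_len)
  c(max(fwd$start, 0L), min(fwd$end, cl$qry_len))
}

#' Verify the copy number of a duplication candidate
#'
#' Re-aligns the candidate sequence to both genomes with maximal-match
#' anchoring (uniqueness not required) and counts disjoint alignment chains
#' that cover at least `1 - rco` of the candidate, allowing internal
#' unaligned runs of up to `qco` bp per copy.  Candidates with equal copy
#' counts in both genomes are false positives of the overlapping-cluster
#' rule (e.g. diverged repeats present in both assemblies).
#'
#' @param candidate_seq Candidate sequence (single string), length >= 100.
#' @param ref,qry Genomes.
#' @param c Maximum reported copy number.
#' @param qco Maximum internal unaligned run within one copy (bp).
#' @param rco Maximum unaligned fraction of the candidate per copy.
#' @param min_match Anchor length for the re-alignment.
#' @return One-row tibble: `copies_ref`, `copies_qry`, `accepted` (TRUE
#'   when the copy numbers differ), plus per-genome copy intervals in a
#'   `copies` list-column.
#' @export
verify_copy_number <- function(candidate_seq, ref, qry, c = 500, qco = 10000,
                               rco = 0.2, min_match = 20) {
  stopifnot(nchar(candidate_seq) >= 100)
  count_in <- function(genome) {
    genome <- as_genome(genome)
    mems <- find_mems(genome, c(candidate = candidate_seq),
                      min_len = min_match, unique_in_ref = FALSE,
                      both_strands = TRUE)
    if (nrow(mems) == 0)
      return(list(n = 0L, copies = tibble(seqname = character(),
                                          start = integer(),
                                          end = integer())))
    L <- nchar(candidate_seq)
    copies <- list()
    n <- 0L
    for (part in group_split(group_by(mems, .data$ref_name, .data$strand))) {
      part <- arrange(part, .data$ref_start)
      flush <- function(idx) {
        if (length(idx) == 0) return()
        iv <- tibble(s = part$qry_start[idx],
                     e = part$qry_start[idx] + part$length[idx])
        cov <- coverage_fraction(0L, L, tibble(start = iv$s, end = iv$e)) * L
        if (cov >= (1 - rco) * L) {
          n <<- n + 1L
          copies[[length(copies) + 1]] <<- tibble(
            seqname = part$ref_name[1],
            start = min(part$ref_start[idx]),
            end = max(part$ref_start[idx] + part$length[idx]))
        }
      }
      chain <- integer(0)
      for (i in seq_len(nrow(part))) {
        if (length(chain) > 0) {
          last <- chain[length(chain)]
          g_gap <- part$ref_start[i] - (part$ref_start[last] +
                                          part$length[last])
          backtrack <- part$qry_start[i] <
            part$qry_start[last] + part$length[last] - 20
          if (g_gap > qco || backtrack) { flush(chain); chain <- integer(0) }
        }
        chain <- c(chain, i)
      }
      flush(chain)
    }
    list(n = min(n, c), copies = bind_rows(copies))
  }
  r <- count_in(ref)
  q <- count_in(qry)
  if (r$n == 0 && q$n == 0)
    warning("copy-number candidate absent from both genomes")
  tibble(copies_ref = r$n, copies_qry = q$n, accepted = r$n != q$n,
         copies = list(list(ref = r$copies, qry = q$copies)))
}

#' Call structural indels from gaps between adjacent synteny blocks
#'
#' For each pair of adjacent one-to-one blocks (same sequences, same
#' strand, collinear), a gap longer than `min_len` in one genome with a
#' counterpart gap smaller than `reciprocal_frac` times its length in the
#' other genome is an insertion in the gapped genome.  Gap pairs that are
#' large on both sides fail both tests and are flagged as divergent
#' regions rather than indels.
#'
#' @param blocks Filtered, stitched block tibble.
#' @param min_len Minimum indel length (bp); gaps must exceed it strictly.
#' @param reciprocal_frac Maximum opposite-genome gap as a fraction of the
#'   indel gap.
#' @return SV-call tibble with `sv_type` in `INS_QRY`, `DEL_QRY`,
#'   `DIVERGENT` (divergent rows carry the gap geometry but are not
#'   variant calls).
#' @export
call_indels <- function(blocks, min_len = 100, reciprocal_frac = 0.10) {
  out <- sv_call_schema()
  if (is.null(blocks) || nrow(blocks) < 2) return(out)
  rows <- list()
  grouped <- blocks |>
    arrange(.data$ref_name, .data$qry_name, .data$strand, .data$ref_start) |>
    group_by(.data$ref_name, .data$qry_name, .data$strand)
  for (part in group_split(grouped)) {
    if (nrow(part) < 2) next
    for (i in seq_len(nrow(part) - 1)) {
      cur <- part[i, ]; nxt <- part[i + 1, ]
      rgap <- nxt$ref_start - cur$ref_end
      qgap <- nxt$qry_start - cur$qry_end
      if (rgap < -20 || qgap < -20) next # non-collinear (e.g. trimmed copy)
      rgap <- max(rgap, 0); qgap <- max(qgap, 0)
      sv_type <- if (qgap > min_len && rgap < reciprocal_frac * qgap)
        "INS_QRY"
      else if (rgap > min_len && qgap < reciprocal_frac * rgap)
        "DEL_QRY"
      else if (rgap > min_len || qgap > min_len)
        "DIVERGENT"
      else next
      qf <- strand_to_forward(cur$qry_end, nxt$qry_start, cur$strand,
                              cur$qry_len)
      rows[[length(rows) + 1]] <- tibble(
        sv_type = sv_type, ref_name = cur$ref_name,
        ref_start = as.integer(cur$ref_end), ref_end = as.integer(nxt$ref_start),
        qry_name = cur$qry_name, qry_start = qf$start, qry_end = qf$end,
        length = as.integer(max(rgap, qgap)), te_status = NA_character_,
        spacer_start = NA_integer_, spacer_end = NA_integer_,
        copies_ref = NA_integer_, copies_qry = NA_integer_,
        evidence = paste0("bl", cur$block_id, ",bl", nxt$block_id)
      )
    }
  }
  bind_rows(out, rows) |> arrange(.data$ref_name, .data$ref_start)
}

#' Call inversions from reverse-orientation blocks
#'
#' A reverse-strand block flanked by forward-strand synteny on both sides
#' (within `flank_window` bp on the reference) is an inversion.  Inversions
#' fully covered by the repeat annotation are removed, since a
#' transposable element present in opposite orientations at homologous
#' positions is not an inversion of unique sequence.
#'
#' @param blocks Filtered block tibble (both strands).
#' @param repeats Reference repeat annotation (tibble or path), or `NULL`.
#' @param min_len Minimum inversion length (bp).
#' @param flank_window Maximum distance to the flanking forward block (bp).
#' @param te_cov Repeat-coverage fraction above which an inversion is
#'   dropped as a TE artifact.
#' @return SV-call tibble of `INV` records.
#' @export
call_inversions <- function(blocks, repeats = NULL, min_len = 100,
                            flank_window = 20000, te_cov = 0.95) {
  out <- sv_call_schema()
  if (is.null(blocks) || nrow(blocks) == 0) return(out)
  rev_blocks <- blocks[blocks$strand == "-", , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(rev_blocks))) {
    b <- rev_blocks[i, ]
    if (b$ref_end - b$ref_start < min_len) next
    fwd <- blocks[blocks$strand == "+" & blocks$ref_name == b$ref_name &
                    blocks$qry_name == b$qry_name, , drop = FALSE]
    left <- any(fwd$ref_end <= b$ref_start + 20 &
                  fwd$ref_end >= b$ref_start - flank_window)
    right <- any(fwd$ref_start >= b$ref_end - 20 &
                   fwd$ref_start <= b$ref_end + flank_window)
    if (!left || !right) next
    rows[[length(rows) + 1]] <- tibble(
      sv_type = "INV", ref_name = b$ref_name,
      ref_start = as.integer(b$ref_start), ref_end = as.integer(b$ref_end),
      qry_name = b$qry_name, qry_start = b$qry_fwd_start,
      qry_end = b$qry_fwd_end,
      length = as.integer(b$ref_end - b$ref_start),
      te_status = NA_character_, spacer_start = NA_integer_,
      spacer_end = NA_integer_, copies_ref = NA_integer_,
      copies_qry = NA_integer_, evidence = paste0("bl", b$block_id)
    )
  }
  res <- bind_rows(out, rows)
  if (nrow(res) > 0 && !is.null(repeats)) {
    ann <- read_annotation(repeats)
    cov <- purrr::map_dbl(seq_len(nrow(res)), function(i) {
      coverage_fraction(res$ref_start[i], res$ref_end[i],
                        ann[ann$seqname == res$ref_name[i], ])
    })
    res <- res[cov < te_cov, , drop = FALSE]
  }
  arrange(res, .data$ref_name, .data$ref_start)
}

# fraction of [start,end) covered by the union of annotation intervals
coverage_fraction <- function(start, end, ann) {
  if (end <= start || nrow(ann) == 0) return(0)
  s <- pmax(ann$start, start)
  e <- pmin(ann$end, end)
  keep <- e > s
  if (!any(keep)) return(0)
  iv <- tibble(s = s[keep], e = e[keep]) |> arrange(s)
  covered <- 0; hi <- -Inf
  for (i in seq_len(nrow(iv))) {
    if (iv$s[i] > hi) { covered <- covered + iv$e[i] - iv$s[i]; hi <- iv$e[i] }
    else if (iv$e[i] > hi) { covered <- covered + iv$e[i] - hi; hi <- iv$e[i] }
  }
  covered / (end - start)
}

#' Call SNPs and small indels from base-level synteny blocks
#'
#' Walks the alignment columns of each one-to-one block and emits
#' substitution and sub-`max_len` indel records with both alleles.  Indel
#' records are left-aligned against the reference.  Gap runs of `max_len`
#' bp or more are returned with kind `INS_GE` / `DEL_GE` so the caller can
#' treat them as structural; they are not small variants.
#'
#' @param blocks Filtered, stitched block tibble.
#' @param ref,qry Genomes.
#' @param max_len Small-indel upper bound (exclusive; default 100 bp).
#' @return Tibble: `kind` (`SNP`, `INS`, `DEL`, `INS_GE`, `DEL_GE`),
#'   `ref_name`, `ref_pos` (0-based), `ref_allele`, `qry_allele`,
#'   `length`, `qry_name`, `strand`.
#' @export
call_snps_small_indels <- function(blocks, ref, qry, max_len = 100) {
  ref <- as_genome(ref)
  qry <- as_genome(qry)
  empty <- tibble(kind = character(), ref_name = character(),
                  ref_pos = integer(), ref_allele = character(),
                  qry_allele = character(), length = integer(),
                  qry_name = character(), strand = character())
  if (is.null(blocks) || nrow(blocks) == 0) return(empty)
  rows <- list()
  for (b in seq_len(nrow(blocks))) {
    blk <- blocks[b, ]
    rseq <- ref[[blk$ref_name]]
    qseq <- qry[[blk$qry_name]]
    if (blk$strand == "-") qseq <- reverse_complement(qseq)
    runs <- cigar_runs(blk$cigar)
    rpos <- blk$ref_start
    qpos <- blk$qry_start
    for (k in seq_len(nrow(runs))) {
      len <- runs$len[k]; op <- runs$op[k]
      if (op == "=") { rpos <- rpos + len; qpos <- qpos + len; next }
      if (op == "X") {
        ra <- strsplit(substr(rseq, rpos + 1, rpos + len), "")[[1]]
        qa <- strsplit(substr(qseq, qpos + 1, qpos + len), "")[[1]]
        rows[[length(rows) + 1]] <- tibble(
          kind = "SNP", ref_name = blk$ref_name,
          ref_pos = as.integer(rpos + seq_len(len) - 1L), ref_allele = ra,
          qry_allele = qa, length = 1L, qry_name = blk$qry_name,
          strand = blk$strand)
        rpos <- rpos + len; qpos <- qpos + len
      } else if (op == "I") { # extra sequence in the query
        allele <- substr(qseq, qpos + 1, qpos + len)
        la <- left_align_insertion(rseq, rpos, allele)
        rows[[length(rows) + 1]] <- tibble(
          kind = if (len < max_len) "INS" else "INS_GE",
          ref_name = blk$ref_name, ref_pos = as.integer(la$pos),
          ref_allele = "", qry_allele = la$allele, length = as.integer(len),
          qry_name = blk$qry_name, strand = blk$strand)
        qpos <- qpos + len
      } else if (op == "D") { # sequence missing from the query
        la <- left_align_deletion(rseq, rpos, len)
        rows[[length(rows) + 1]] <- tibble(
          kind = if (len < max_len) "DEL" else "DEL_GE",
          ref_name = blk$ref_name, ref_pos = as.integer(la$pos),
          ref_allele = la$allele, qry_allele = "", length = as.integer(len),
          qry_name = blk$qry_name, strand = blk$strand)
        rpos <- rpos + len
      }
    }
  }
  res <- bind_rows(empty, rows)
  if (nrow(res) == 0) return(res)
  res |>
    distinct(.data$ref_name, .data$ref_pos, .data$kind, .data$ref_allele,
             .data$qry_allele, .keep_all = TRUE) |>
    arrange(.data$ref_name, .data$ref_pos)
}

# VCF-style left normalisation of indels against the reference context
left_align_deletion <- function(rseq, pos, len) {
  while (pos > 0 &&
         substr(rseq, pos, pos) == substr(rseq, pos + len, pos + len)) {
    pos <- pos - 1L
  }
  list(pos = pos, allele = substr(rseq, pos + 1, pos + len))
}

left_align_insertion <- function(rseq, pos, allele) {
  L <- nchar(allele)
  while (pos > 0 && substr(rseq, pos, pos) == substr(allele, L, L)) {
    allele <- paste0(substr(rseq, pos, pos), substr(allele, 1, L - 1))
    pos <- pos - 1L
  }
  list(pos = pos, allele = allele)
}

#' Annotate the TE status of SV calls
#'
#' A call is `TE` when at least `te_frac` of its variant sequence is
#' covered by repeat annotation, else `non-TE`.  The annotation of the
#' genome carrying the variant sequence is used: query-side gains and
#' insertions need `repeats_qry`; reference-side losses, deletions and
#' inversions need `repeats_ref`.  Missing annotation yields `non-TE` with
#' a warning.
#'
#' @param calls SV-call tibble.
#' @param repeats_ref,repeats_qry Repeat annotations (tibble or path).
#' @param te_frac Coverage threshold (inclusive).
#' @return `calls` with `te_status` filled in.
#' @export
annotate_te_status <- function(calls, repeats_ref = NULL, repeats_qry = NULL,
                               te_frac = 0.8) {
  if (nrow(calls) == 0) return(calls)
  ann_ref <- if (!is.null(repeats_ref)) read_annotation(repeats_ref)
  ann_qry <- if (!is.null(repeats_qry)) read_annotation(repeats_qry)
  warned <- FALSE
  calls$te_status <- vapply(seq_len(nrow(calls)), function(i) {
    type <- calls$sv_type[i]
    qry_side <- type %in% c("INS_QRY", "CNV_GAIN_QRY")
    ann <- if (qry_side) ann_qry else ann_ref
    if (is.null(ann)) {
      if (!warned) warning("missing repeat annotation for the ",
                           if (qry_side) "query" else "reference",
                           " genome; calls marked non-TE")
      warned <<- TRUE
      return("non-TE")
    }
    cov <- if (qry_side) {
      if (is.na(calls$qry_start[i])) 0 else
        coverage_fraction(calls$qry_start[i], calls$qry_end[i],
                          ann[ann$seqname == calls$qry_name[i], ])
    } else {
      coverage_fraction(calls$ref_start[i], calls$ref_end[i],
                        ann[ann$seqname == calls$ref_name[i], ])
    }
    if (cov >= te_frac) "TE" else "non-TE"
  }, character(1))
  calls
}

#' Merge nearby CNV calls into complex events
#'
#' Copy-number calls within `d` bp of each other on the reference are
#' combined into one counted complex event.  The total affected bp is
#' computed from the unmerged calls.
#'
#' @param calls SV-call tibble.
#' @param d Merge distance (bp).
#' @return List: `calls` (with `event_id`), `events` (merged CNV event
#'   intervals), `counts` (per-type tallies of merged events),
#'   `affected_bp` (per-type pre-merge totals).
#' @export
merge_complex_events <- function(calls, d = 2000) {
  calls$event_id <- NA_integer_
  cnv <- calls$sv_type %in% c("CNV_GAIN_QRY", "CNV_LOSS_QRY")
  events <- tibble(event_id = integer(), ref_name = character(),
                   ref_start = integer(), ref_end = integer(),
                   n_calls = integer(), complex = logical())
  if (any(cnv)) {
    cc <- calls[cnv, ]
    ord <- order(cc$ref_name, cc$ref_start)
    eid <- integer(nrow(cc))
    cur_id <- 0L; cur_name <- ""; cur_end <- -Inf
    for (k in ord) {
      if (cc$ref_name[k] != cur_name || cc$ref_start[k] > cur_end + d) {
        cur_id <- cur_id + 1L
        cur_name <- cc$ref_name[k]
        cur_end <- cc$ref_end[k]
      } else cur_end <- max(cur_end, cc$ref_end[k])
      eid[k] <- cur_id
    }
    calls$event_id[cnv] <- eid
    events <- calls[cnv, ] |>
      group_by(event_id2 = .data$event_id) |>
      summarise(ref_name = first(.data$ref_name),
                ref_start = min(.data$ref_start),
                ref_end = max(.data$ref_end), n_calls = n(),
                complex = n() > 1, .groups = "drop") |>
      rename(event_id = "event_id2")
  }
  non_cnv <- which(!cnv & calls$sv_type != "DIVERGENT")
  calls$event_id[non_cnv] <- max(0L, events$event_id, na.rm = TRUE) +
    seq_along(non_cnv)
  counted <- calls[calls$sv_type != "DIVERGENT", ]
  counts <- counted |>
    distinct(.data$sv_type, .data$event_id) |>
    count(.data$sv_type, name = "n_events")
  affected <- counted |>
    group_by(.data$sv_type) |>
    summarise(affected_bp = sum(.data$length), .groups = "drop")
  list(calls = calls, events = events, counts = counts,
       affected_bp = affected)
}
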