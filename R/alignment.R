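#' Global alignment with affine gap costs
#'
#' Needleman-Wunsch/Gotoh global alignment.  A gap of length `g` costs
#' `gap_open + g * gap_ext`.  Defaults: match +1, mismatch -1, gap open 2,
#' gap extension 0.5.
#'
#' @param a,b Sequences (single strings); `a` is the reference side.
#' @param match,mismatch Match score and mismatch penalty (both positive).
#' @param gap_open,gap_ext Gap opening / per-base extension penalties.
#' @return List with `score` and `cigar` (ops `=`, `X`, `I`, `D`; `D`
#'   consumes the reference, `I` the query).
#' @export
align_global <- function(a, b, match = 1, mismatch = 1, gap_open = 2,
                         gap_ext = 0.5) {
  .affine_align_cpp(a, b, match, mismatch, gap_open, gap_ext)
}

cigar_runs <- function(cigar) {
  if (is.na(cigar) || cigar == "")
    return(data.frame(len = integer(), op = character()))
  toks <- regmatches(cigar, gregexpr("\\d+[=XIDMSH]", cigar))[[1]]
  nc <- nchar(toks)
  data.frame(len = as.integer(substr(toks, 1, nc - 1)),
             op = substr(toks, nc, nc))
}

# accepts a data frame of runs or parallel len/op vectors
cigar_string <- function(runs, op = NULL) {
  if (is.null(op)) { len <- runs$len; op <- runs$op } else len <- runs
  keep <- len > 0
  len <- len[keep]; op <- op[keep]
  n <- length(op)
  if (n == 0) return("")
  grp <- cumsum(c(TRUE, op[-1] != op[-n]))
  len <- as.vector(rowsum(len, grp))
  op <- op[!duplicated(grp)]
  paste0(len, op, collapse = "")
}

cigar_stats <- function(cigar) {
  r <- cigar_runs(cigar)
  tibble(
    n_match = sum(r$len[r$op == "="]),
    n_mismatch = sum(r$len[r$op %in% c("X")]),
    n_gapcols = sum(r$len[r$op %in% c("I", "D")]),
    ref_span = sum(r$len[r$op %in% c("=", "X", "D", "M")]),
    qry_span = sum(r$len[r$op %in% c("=", "X", "I", "M")])
  )
}

#' Fill one cluster to a base-level alignment
#'
#' Builds a global alignment of the cluster's full reference interval
#' against its full query interval that passes through every anchor match:
#' anchors become exact-match columns and the regions between anchors are
#' resolved by affine-gap global alignment ([align_global()]).
#'
#' @param cluster One row of the tibble returned by [cluster_matches()].
#' @param ref,qry Genomes (see [as_genome()]).
#' @inheritParams align_global
#' @return One-row tibble: coordinates, `weight`, `cigar`, alignment
#'   statistics and `identity`.
#' @export
fill_cluster_alignment <- function(cluster, ref, qry, match = 1, mismatch = 1,
                                   gap_open = 2, gap_ext = 0.5) {
  ref <- as_genome(ref)
  qry <- as_genome(qry)
  stopifnot(nrow(cluster) == 1)
  rseq <- ref[[cluster$ref_name]]
  qseq <- qry[[cluster$qry_name]]
  if (cluster$strand == "-") qseq <- reverse_complement(qseq)

  anchors <- cluster$matches[[1]] |> arrange(.data$ref_start, .data$qry_start)
  # anchors must advance on both axes
  if (is.unsorted(anchors$qry_start))
    stop("inconsistent (crossing) anchors in cluster")

  runs <- list()
  score <- 0
  pr <- anchors$ref_start[1]
  pq <- anchors$qry_start[1]
  for (i in seq_len(nrow(anchors))) {
    rs <- anchors$ref_start[i]
    qs <- anchors$qry_start[i]
    len <- anchors$length[i]
    ov <- max(pr - rs, pq - qs, 0)
    rs <- rs + ov; qs <- qs + ov; len <- len - ov
    if (len <= 0) next
    if (rs < pr || qs < pq) stop("inconsistent (crossing) anchors in cluster")
    rgap <- rs - pr
    qgap <- qs - pq
    if (rgap > 0 && qgap > 0) {
      aln <- align_global(substr(rseq, pr + 1, rs), substr(qseq, pq + 1, qs),
                          match, mismatch, gap_open, gap_ext)
      runs <- c(runs, list(cigar_runs(aln$cigar)))
      score <- score + aln$score
    } else if (rgap > 0) {
      runs <- c(runs, list(tibble(len = rgap, op = "D")))
      score <- score - gap_open - gap_ext * rgap
    } else if (qgap > 0) {
      runs <- c(runs, list(tibble(len = qgap, op = "I")))
      score <- score - gap_open - gap_ext * qgap
    }
    runs <- c(runs, list(tibble(len = len, op = "=")))
    score <- score + match * len
    pr <- rs + len
    pq <- qs + len
  }
  cigar <- cigar_string(bind_rows(runs))
  st <- cigar_stats(cigar)
  out <- tibble(
    cluster_id = cluster$cluster_id,
    ref_name = cluster$ref_name, qry_name = cluster$qry_name,
    strand = cluster$strand,
    ref_start = anchors$ref_start[1], ref_end = pr,
    qry_start = anchors$qry_start[1], qry_end = pq,
    qry_len = cluster$qry_len,
    weight = cluster$total_match_len,
    score = score, cigar = cigar
  )
  out <- bind_cols(out, st)
  out$identity <- out$n_match / (out$n_match + out$n_mismatch + out$n_gapcols)
  fwd <- strand_to_forward(out$qry_start, out$qry_end, out$strand, out$qry_len)
  out$qry_fwd_start <- fwd$start
  out$qry_fwd_end <- fwd$end
  out
}

#' Fill every cluster to a base-level synteny block
#'
#' @param clusters Tibble from [cluster_matches()].
#' @inheritParams fill_cluster_alignment
#' @return Tibble of base-level blocks, one row per cluster.
#' @export
fill_clusters <- function(clusters, ref, qry, match = 1, mismatch = 1,
                          gap_open = 2, gap_ext = 0.5) {
  ref <- as_genome(ref)
  qry <- as_genome(qry)
  out <- purrr::map(seq_len(nrow(clusters)), function(i) {
    fill_cluster_alignment(clusters[i, ], ref, qry, match, mismatch,
                           gap_open, gap_ext)
  })
  res <- bind_rows(out)
  if (nrow(res) > 0) res$block_id <- seq_len(nrow(res))
  res
}

# overlap length of [a1,a2) and [b1,b2)
interval_overlap <- function(a1, a2, b1, b2) {
  pmax(0, pmin(a2, b2) - pmax(a1, b1))
}

# exact maximum-weight independent set for small conflict components,
# greedy (by weight) above `exact_max` nodes
mwis_select <- function(conflict, weight, exact_max = 16) {
  n <- length(weight)
  if (n == 0) return(logical(0))
  if (n == 1) return(TRUE)
  if (n <= exact_max) {
    best_w <- -1
    best_set <- NULL
    order_pref <- order(-weight)
    for (s in 0:(2^n - 1)) {
      members <- which(bitwAnd(s, 2^(0:(n - 1))) > 0)
      if (length(members) > 1 && any(conflict[members, members])) next
      w <- sum(weight[members])
      if (w > best_w + 1e-9) { best_w <- w; best_set <- members }
    }
    out <- rep(FALSE, n)
    out[best_set] <- TRUE
    out
  } else {
    out <- rep(FALSE, n)
    for (i in order(-weight, seq_len(n))) {
      if (!any(conflict[i, out])) out[i] <- TRUE
    }
    out
  }
}

#' Filter base-level alignments to one-to-one synteny blocks
#'
#' Keeps a maximum-weight subset of blocks that is consistent
#' (non-overlapping beyond `tol`) along the chosen genome axes: with
#' `mode = "both"` along the reference axis and the query axis (the
#' one-to-one contract used before SNP/small-indel calling); with
#' `mode = "ref"` or `mode = "qry"` along a single axis only (the
#' mutually-best contract used for contig-to-arm assignment).  Weight is
#' the block's total anchored match length.
#'
#' With `rescue = TRUE`, a rejected block whose conflict is confined to its
#' head or tail is trimmed back to the non-conflicting remainder and
#' retained when at least `min_len` aligned bp survive; this keeps the
#' sequence flanking a tandem duplication aligned instead of discarding it
#' with the redundant copy.
#'
#' @param blocks Block tibble from [fill_clusters()].
#' @param mode Axis/axes on which overlaps are forbidden.
#' @param tol Overlap tolerance in bp.
#' @param rescue Trim-and-keep rejected blocks where possible.
#' @param min_len Minimum surviving aligned length for a rescued block.
#' @param ref,qry Genomes; only needed when `rescue = TRUE`.
#' @return Tibble of retained (possibly trimmed) blocks.
#' @export
filter_mutual_best <- function(blocks, mode = c("both", "ref", "qry"),
                               tol = 50, rescue = FALSE, min_len = 100,
                               ref = NULL, qry = NULL) {
  mode <- match.arg(mode)
  if (is.null(blocks) || nrow(blocks) == 0) return(blocks)

  # absorb redundant sub-alignments: a block contained in a heavier block
  # on the same diagonal is a fragment of the same homology, not a
  # competing placement
  n <- nrow(blocks)
  drop <- rep(FALSE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || drop[j]) next
      if (blocks$ref_name[i] != blocks$ref_name[j] ||
          blocks$qry_name[i] != blocks$qry_name[j] ||
          blocks$strand[i] != blocks$strand[j]) next
      contained <- blocks$ref_start[i] >= blocks$ref_start[j] - tol &&
        blocks$ref_end[i] <= blocks$ref_end[j] + tol &&
        blocks$qry_start[i] >= blocks$qry_start[j] - tol &&
        blocks$qry_end[i] <= blocks$qry_end[j] + tol
      same_diag <- abs((blocks$qry_start[i] - blocks$ref_start[i]) -
                         (blocks$qry_start[j] - blocks$ref_start[j])) <= 2 * tol
      if (contained && same_diag &&
          (blocks$weight[i] < blocks$weight[j] ||
             (blocks$weight[i] == blocks$weight[j] && i > j))) {
        drop[i] <- TRUE
        break
      }
    }
  }
  blocks <- blocks[!drop, , drop = FALSE]
  n <- nrow(blocks)

  ref_conf <- outer(seq_len(n), seq_len(n), function(i, j) {
    same <- blocks$ref_name[i] == blocks$ref_name[j]
    ov <- interval_overlap(blocks$ref_start[i], blocks$ref_end[i],
                           blocks$ref_start[j], blocks$ref_end[j])
    same & ov > tol
  })
  qry_conf <- outer(seq_len(n), seq_len(n), function(i, j) {
    same <- blocks$qry_name[i] == blocks$qry_name[j]
    ov <- interval_overlap(blocks$qry_fwd_start[i], blocks$qry_fwd_end[i],
                           blocks$qry_fwd_start[j], blocks$qry_fwd_end[j])
    same & ov > tol
  })
  conflict <- switch(mode, both = ref_conf | qry_conf, ref = ref_conf,
                     qry = qry_conf)
  diag(conflict) <- FALSE

  # connected components of the conflict graph
  comp <- seq_len(n)
  repeat {
    new <- comp
    for (i in seq_len(n)) {
      nb <- which(conflict[i, ])
      if (length(nb)) new[i] <- min(new[i], min(new[nb]))
    }
    if (identical(new, comp)) break
    comp <- new
  }

  keep <- rep(FALSE, n)
  for (cc in unique(comp)) {
    members <- which(comp == cc)
    keep[members] <- mwis_select(conflict[members, members, drop = FALSE],
                                 blocks$weight[members])
  }

  kept <- blocks[keep, , drop = FALSE]
  if (rescue && any(!keep)) {
    rejected <- which(!keep)
    rejected <- rejected[order(-blocks$weight[rejected])]
    for (i in rejected) {
      cand <- blocks[i, ]
      # a light block conflicting only in the candidate's interior (a
      # repeat-homology fragment sitting inside a genuine flank) cannot be
      # trimmed around; evict it so the heavier candidate can be rescued
      evict <- vapply(seq_len(nrow(kept)), function(j) {
        if (kept$weight[j] >= 0.25 * cand$weight) return(FALSE)
        r_conf <- mode %in% c("both", "ref") &&
          kept$ref_name[j] == cand$ref_name &&
          interval_overlap(cand$ref_start, cand$ref_end,
                           kept$ref_start[j], kept$ref_end[j]) > tol
        q_conf <- mode %in% c("both", "qry") &&
          kept$qry_name[j] == cand$qry_name &&
          interval_overlap(cand$qry_fwd_start, cand$qry_fwd_end,
                           kept$qry_fwd_start[j], kept$qry_fwd_end[j]) > tol
        if (!r_conf && !q_conf) return(FALSE)
        r_int <- !r_conf || (kept$ref_start[j] > cand$ref_start + tol &&
                               kept$ref_end[j] < cand$ref_end - tol)
        q_int <- !q_conf || (kept$qry_fwd_start[j] > cand$qry_fwd_start + tol &&
                               kept$qry_fwd_end[j] < cand$qry_fwd_end - tol)
        r_int && q_int
      }, logical(1))
      kept_try <- kept[!evict, , drop = FALSE]
      tr <- trim_against(cand, kept_try, mode, tol)
      if (!is.null(tr) && (tr$n_match + tr$n_mismatch) >= min_len) {
        kept <- bind_rows(kept_try, tr)
      }
    }
  }
  arrange(kept, .data$ref_name, .data$ref_start)
}

# Trim block's head/tail so it no longer conflicts with any kept block on
# the active axes.  Returns NULL when the conflict is interior.
trim_against <- function(block, kept, mode, tol) {
  for (pass in 1:4) {
    conf_head_ref <- conf_tail_ref <- conf_head_qry <- conf_tail_qry <- 0
    for (j in seq_len(nrow(kept))) {
      if (mode %in% c("both", "ref") &&
          kept$ref_name[j] == block$ref_name) {
        ov <- interval_overlap(block$ref_start, block$ref_end,
                               kept$ref_start[j], kept$ref_end[j])
        if (ov > tol) {
          if (kept$ref_start[j] <= block$ref_start &&
              kept$ref_end[j] < block$ref_end) {
            conf_head_ref <- max(conf_head_ref, kept$ref_end[j] - block$ref_start)
          } else if (kept$ref_start[j] > block$ref_start &&
                     kept$ref_end[j] >= block$ref_end) {
            conf_tail_ref <- max(conf_tail_ref, block$ref_end - kept$ref_start[j])
          } else return(NULL) # containment / interior conflict
        }
      }
      if (mode %in% c("both", "qry") &&
          kept$qry_name[j] == block$qry_name) {
        ov <- interval_overlap(block$qry_fwd_start, block$qry_fwd_end,
                               kept$qry_fwd_start[j], kept$qry_fwd_end[j])
        if (ov > tol) {
          head_side <- kept$qry_fwd_start[j] <= block$qry_fwd_start &&
            kept$qry_fwd_end[j] < block$qry_fwd_end
          tail_side <- kept$qry_fwd_start[j] > block$qry_fwd_start &&
            kept$qry_fwd_end[j] >= block$qry_fwd_end
          if (!head_side && !tail_side) return(NULL)
          amt_fwd_head <- if (head_side) kept$qry_fwd_end[j] - block$qry_fwd_start else 0
          amt_fwd_tail <- if (tail_side) block$qry_fwd_end - kept$qry_fwd_start[j] else 0
          # forward-head corresponds to strand-local head on +, tail on -
          if (block$strand == "+") {
            conf_head_qry <- max(conf_head_qry, amt_fwd_head)
            conf_tail_qry <- max(conf_tail_qry, amt_fwd_tail)
          } else {
            conf_head_qry <- max(conf_head_qry, amt_fwd_tail)
            conf_tail_qry <- max(conf_tail_qry, amt_fwd_head)
          }
        }
      }
    }
    if (conf_head_ref + conf_tail_ref + conf_head_qry + conf_tail_qry == 0)
      return(block)
    block <- trim_block(block, head_ref = conf_head_ref,
                        tail_ref = conf_tail_ref,
                        head_qry = conf_head_qry, tail_qry = conf_tail_qry)
    if (is.null(block)) return(NULL)
  }
  NULL
}

# remove >= head/tail bp on the given axes from a base-level block,
# keeping cigar and both coordinate systems consistent
trim_block <- function(block, head_ref = 0, tail_ref = 0, head_qry = 0,
                       tail_qry = 0) {
  runs <- cigar_runs(block$cigar)
  consume <- function(runs, need_ref, need_qry, from_head) {
    if (!from_head) runs <- runs[rev(seq_len(nrow(runs))), ]
    got_ref <- 0; got_qry <- 0; drop_ref <- 0; drop_qry <- 0
    i <- 0
    while ((got_ref < need_ref || got_qry < need_qry) && i < nrow(runs)) {
      i <- i + 1
      op <- runs$op[i]; len <- runs$len[i]
      cr <- if (op %in% c("=", "X", "D", "M")) len else 0
      cq <- if (op %in% c("=", "X", "I", "M")) len else 0
      need_more_ref <- max(need_ref - got_ref, 0)
      need_more_qry <- max(need_qry - got_qry, 0)
      serve_ref <- cr > 0 && need_more_ref > 0
      serve_qry <- cq > 0 && need_more_qry > 0
      take <- if (serve_ref || serve_qry) {
        min(len, max(if (serve_ref) need_more_ref else 0,
                     if (serve_qry) need_more_qry else 0))
      } else len  # dangling gap run on the trimmed edge: drop it
      if (cr > 0) { got_ref <- got_ref + take; drop_ref <- drop_ref + take }
      if (cq > 0) { got_qry <- got_qry + take; drop_qry <- drop_qry + take }
      runs$len[i] <- len - take
      if (runs$len[i] > 0) break
    }
    runs <- runs[runs$len > 0, , drop = FALSE]
    if (!from_head) runs <- runs[rev(seq_len(nrow(runs))), , drop = FALSE]
    list(runs = runs, ref = drop_ref, qry = drop_qry)
  }
  h <- consume(runs, head_ref, head_qry, TRUE)
  t <- consume(h$runs, tail_ref, tail_qry, FALSE)
  if (nrow(t$runs) == 0) return(NULL)
  block$ref_start <- block$ref_start + h$ref
  block$ref_end <- block$ref_end - t$ref
  block$qry_start <- block$qry_start + h$qry
  block$qry_end <- block$qry_end - t$qry
  block$cigar <- cigar_string(t$runs)
  st <- cigar_stats(block$cigar)
  block$n_match <- st$n_match
  block$n_mismatch <- st$n_mismatch
  block$n_gapcols <- st$n_gapcols
  block$weight <- st$n_match
  block$identity <- st$n_match / max(st$n_match + st$n_mismatch + st$n_gapcols, 1)
  fwd <- strand_to_forward(block$qry_start, block$qry_end, block$strand,
                           block$qry_len)
  block$qry_fwd_start <- fwd$start
  block$qry_fwd_end <- fwd$end
  block
}

#' Stitch adjacent collinear blocks across sub-SV gaps
#'
#' Adjacent one-to-one blocks on the same sequences and strand whose gaps on
#' both genomes are below `max_gap` are merged into a single base-level
#' block, with the gap region resolved by global alignment.  This restores
#' base-level continuity across small indels (which break anchor chains) so
#' that they are emitted as small variants rather than lost between blocks;
#' gaps of `max_gap` bp or more are left for structural indel calling.
#'
#' @param blocks Filtered block tibble.
#' @param ref,qry Genomes.
#' @param max_gap Stitch gaps strictly below this many bp (default 100).
#' @return Block tibble with stitched rows.
#' @export
stitch_blocks <- function(blocks, ref, qry, max_gap = 100) {
  if (is.null(blocks) || nrow(blocks) == 0) return(blocks)
  ref <- as_genome(ref)
  qry <- as_genome(qry)
  out <- list()
  grouped <- blocks |>
    arrange(.data$ref_name, .data$qry_name, .data$strand, .data$ref_start) |>
    group_by(.data$ref_name, .data$qry_name, .data$strand)
  for (part in group_split(grouped)) {
    cur <- part[1, ]
    qseq <- qry[[cur$qry_name]]
    if (cur$strand == "-") qseq <- reverse_complement(qseq)
    rseq <- ref[[cur$ref_name]]
    i <- 2
    while (i <= nrow(part)) {
      nxt <- part[i, ]
      rgap <- nxt$ref_start - cur$ref_end
      qgap <- nxt$qry_start - cur$qry_end
      # chance micro-overlaps (an anchor extended past a junction): trim and go on
      if ((rgap < 0 && rgap >= -20) || (qgap < 0 && qgap >= -20)) {
        trimmed <- trim_block(nxt, head_ref = max(0, -rgap),
                              head_qry = max(0, -qgap))
        if (!is.null(trimmed)) {
          nxt <- trimmed
          rgap <- nxt$ref_start - cur$ref_end
          qgap <- nxt$qry_start - cur$qry_end
        }
      }
      if (rgap >= 0 && qgap >= 0 && rgap < max_gap && qgap < max_gap) {
        mid <- if (rgap > 0 && qgap > 0) {
          cigar_runs(align_global(substr(rseq, cur$ref_end + 1, nxt$ref_start),
                                  substr(qseq, cur$qry_end + 1, nxt$qry_start))$cigar)
        } else if (rgap > 0) tibble(len = rgap, op = "D")
        else if (qgap > 0) tibble(len = qgap, op = "I")
        else tibble(len = integer(), op = character())
        cur$cigar <- cigar_string(bind_rows(cigar_runs(cur$cigar), mid,
                                            cigar_runs(nxt$cigar)))
        cur$ref_end <- nxt$ref_end
        cur$qry_end <- nxt$qry_end
        cur$weight <- cur$weight + nxt$weight
        st <- cigar_stats(cur$cigar)
        cur$n_match <- st$n_match
        cur$n_mismatch <- st$n_mismatch
        cur$n_gapcols <- st$n_gapcols
        cur$identity <- st$n_match /
          max(st$n_match + st$n_mismatch + st$n_gapcols, 1)
      } else {
        out <- c(out, list(cur))
        cur <- nxt
      }
      i <- i + 1
    }
    out <- c(out, list(cur))
  }
  res <- bind_rows(out)
  fwd <- strand_to_forward(res$qry_start, res$qry_end, res$strand, res$qry_len)
  res$qry_fwd_start <- fwd$start
  res$qry_fwd_end <- fwd$end
  res$block_id <- seq_len(nrow(res))
  arrange(res, .data$ref_name, .data$ref_start)
}
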