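#' Align long reads to an assembly with anchored chaining
#'
#' Seeds every read with maximal exact matches against the assembly,
#' chains the seeds per strand with a wide separation allowance (so a read
#' crossing a structural difference still yields one alignment whose gap
#' columns expose the difference), and resolves inter-anchor regions by
#' affine-gap alignment.  Regions whose gap-by-gap alignment problem is
#' too large to resolve at base level are represented as paired
#' insertion/deletion runs, which is the conservative choice for the
#' gap-ratio quality metric.
#'
#' @param reads Tibble with `name` and `seq` ([simulate_long_reads()]
#'   output works directly).
#' @param genome Target assembly.
#' @param min_seed Seed length (bp).
#' @param chain_sep Maximum separation when chaining read seeds (bp).
#' @param min_chain Minimum chained seed length to report an alignment.
#' @return Tibble of read alignment records: `read_id`, `read_len`,
#'   `target`, `t_start`, `t_end`, `strand`, `q_start`, `q_end`,
#'   `aligned_bases`, `gap_cols`, `p_aligned`, `r_gaps`, `cigar`.
#' @export
map_long_reads <- function(reads, genome, min_seed = 18, chain_sep = 20000,
                           min_chain = 200) {
  genome <- as_genome(genome)
  qry <- setNames(toupper(reads$seq), reads$name)
  mems <- find_mems(genome, qry, min_len = min_seed, unique_in_ref = FALSE,
                    both_strands = TRUE)
  empty <- tibble(read_id = character(), read_len = integer(),
                  target = character(), t_start = integer(),
                  t_end = integer(), strand = character(),
                  q_start = integer(), q_end = integer(),
                  aligned_bases = integer(), gap_cols = integer(),
                  p_aligned = numeric(), r_gaps = numeric(),
                  cigar = character())
  if (nrow(mems) == 0) return(empty)
  mem_idx <- split(seq_len(nrow(mems)), mems$qry_name)
  out <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    idx <- mem_idx[[reads$name[i]]]
    if (is.null(idx)) next
    mm <- mems[idx, , drop = FALSE]
    best <- NULL
    for (grp in group_split(group_by(mm, .data$ref_name, .data$strand))) {
      grp <- arrange(grp, .data$ref_start, .data$qry_start)
      cid <- .chain_matches_cpp(grp$ref_start, grp$qry_start, grp$length,
                                chain_sep, 1.0, 20L, min_chain)
      if (!any(cid > 0)) next
      tab <- tapply(grp$length, cid, sum)
      tab <- tab[names(tab) != "0"]
      top <- names(tab)[which.max(tab)]
      cand <- list(anchors = grp[cid == as.integer(top), , drop = FALSE],
                   total = max(tab), target = grp$ref_name[1],
                   strand = grp$strand[1])
      if (is.null(best) || cand$total > best$total) best <- cand
    }
    if (is.null(best)) next
    read_seq <- qry[[reads$name[i]]]
    rl <- nchar(read_seq)
    qseq <- if (best$strand == "-") reverse_complement(read_seq) else read_seq
    aln <- fill_anchored(best$anchors, genome[[best$target]], qseq)
    # report read coordinates on the original strand
    qs <- aln$q_start; qe <- aln$q_end
    if (best$strand == "-") { qs <- rl - aln$q_end; qe <- rl - aln$q_start }
    out[[i]] <- tibble(
      read_id = reads$name[i], read_len = rl, target = best$target,
      t_start = aln$t_start, t_end = aln$t_end, strand = best$strand,
      q_start = qs, q_end = qe,
      aligned_bases = aln$aligned, gap_cols = aln$gap_cols,
      p_aligned = aln$aligned / rl, r_gaps = aln$gap_cols / rl,
      cigar = aln$cigar
    )
  }
  bind_rows(empty, out)
}

# anchored fill for read alignment; large double-sided gaps become paired
# I/D runs instead of base-level alignment
fill_anchored <- function(anchors, tseq, qseq, max_dp_area = 1e6) {
  ord <- order(anchors$ref_start, anchors$qry_start)
  a_rs <- anchors$ref_start[ord]
  a_qs <- anchors$qry_start[ord]
  a_len <- anchors$length[ord]
  lens <- integer(0); ops <- character(0)
  pr <- a_rs[1]; pq <- a_qs[1]
  t_start <- pr; q_start <- pq
  for (i in seq_along(a_rs)) {
    rs <- a_rs[i]; qs <- a_qs[i]; len <- a_len[i]
    ov <- max(pr - rs, pq - qs, 0)
    rs <- rs + ov; qs <- qs + ov; len <- len - ov
    if (len <= 0) next
    if (rs < pr || qs < pq) next # skip crossing anchor
    rgap <- rs - pr; qgap <- qs - pq
    if (rgap > 0 && rgap == qgap && rgap <= 30) {
      # error-cluster scale: compare columns directly (all substitutions)
      eq <- utf8ToInt(substr(tseq, pr + 1, rs)) ==
        utf8ToInt(substr(qseq, pq + 1, qs))
      lens <- c(lens, rep(1L, rgap)); ops <- c(ops, ifelse(eq, "=", "X"))
    } else if (rgap > 0 && qgap > 0) {
      if (as.numeric(rgap) * qgap <= max_dp_area) {
        aln <- align_global(substr(tseq, pr + 1, rs), substr(qseq, pq + 1, qs))
        r <- cigar_runs(aln$cigar)
        lens <- c(lens, r$len); ops <- c(ops, r$op)
      } else {
        lens <- c(lens, qgap, rgap); ops <- c(ops, "I", "D")
      }
    } else if (rgap > 0) {
      lens <- c(lens, rgap); ops <- c(ops, "D")
    } else if (qgap > 0) {
      lens <- c(lens, qgap); ops <- c(ops, "I")
    }
    lens <- c(lens, len); ops <- c(ops, "=")
    pr <- rs + len; pq <- qs + len
  }
  aligned <- sum(lens[ops %in% c("=", "X")])
  gap_cols <- sum(lens[ops %in% c("I", "D")])
  list(t_start = t_start, t_end = pr, q_start = q_start, q_end = pq,
       aligned = aligned, gap_cols = gap_cols,
       cigar = cigar_string(lens, ops))
}

#' Read alignment records from SAM/BAM
#'
#' Converts primary alignments to the record format used by
#' [collect_spanning_evidence()].  Requires the Rsamtools package; SAM
#' input is converted to BAM on the fly.
#'
#' @param path SAM or BAM file.
#' @return Alignment-record tibble as [map_long_reads()].
#' @export
read_alignment_records <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("Rsamtools is required to read SAM/BAM input")
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                             indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq"),
    flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE,
                                  isUnmappedQuery = FALSE))
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  purrr::map_dfr(seq_along(b$qname), function(i) {
    runs <- cigar_runs(b$cigar[i])
    aligned <- sum(runs$len[runs$op %in% c("M", "=", "X")])
    gaps <- sum(runs$len[runs$op %in% c("I", "D")])
    rl <- sum(runs$len[runs$op %in% c("M", "=", "X", "I", "S", "H")])
    tspan <- sum(runs$len[runs$op %in% c("M", "=", "X", "D")])
    tibble(read_id = b$qname[i], read_len = rl,
           target = as.character(b$rname[i]),
           t_start = b$pos[i] - 1L, t_end = b$pos[i] - 1L + tspan,
           strand = if (bitwAnd(b$flag[i], 16L) > 0) "-" else "+",
           q_start = NA_integer_, q_end = NA_integer_,
           aligned_bases = aligned, gap_cols = gaps,
           p_aligned = aligned / rl, r_gaps = gaps / rl, cigar = b$cigar[i])
  })
}

# aligned (read-and-target-consuming) columns within a target window
aligned_in_window <- function(cigar, t_start, win_s, win_e) {
  runs <- cigar_runs(cigar)
  pos <- t_start
  total <- 0
  for (i in seq_len(nrow(runs))) {
    op <- runs$op[i]; len <- runs$len[i]
    if (op %in% c("M", "=", "X")) {
      total <- total + max(0, min(pos + len, win_e) - max(pos, win_s))
      pos <- pos + len
    } else if (op == "D") pos <- pos + len
  }
  total
}

#' Collect spanning-read evidence for one SV
#'
#' Classifies each alignment record against the SV interval: `FULL` when
#' the read covers the whole SV with at least `anchor` aligned bp of flank
#' on both sides, `OVERLAP_LEFT`/`OVERLAP_RIGHT` when it covers one
#' breakpoint with sufficient flank on that side, `NONE` otherwise.  The
#' per-read quality metrics `p_aligned` (aligned bases over read length)
#' and `r_gaps` (gap columns over read length) ride along.
#'
#' @param sv One-row tibble or list with `chrom`, `start`, `end` (0-based
#'   half-open, on the assembly the reads were mapped to).
#' @param records Alignment-record tibble ([map_long_reads()] or
#'   [read_alignment_records()]).
#' @param anchor Required aligned flank (bp).
#' @return Evidence tibble: `read_id`, `span_class`, `p_aligned`,
#'   `r_gaps`, `left_flank`, `right_flank`.
#' @export
collect_spanning_evidence <- function(sv, records, anchor = 250) {
  recs <- records[records$target == sv$chrom &
                    records$t_end > sv$start - anchor &
                    records$t_start < sv$end + anchor, , drop = FALSE]
  purrr::map_dfr(seq_len(nrow(recs)), function(i) {
    r <- recs[i, ]
    lf <- aligned_in_window(r$cigar, r$t_start, r$t_start, sv$start)
    rf <- aligned_in_window(r$cigar, r$t_start, sv$end, r$t_end)
    cls <- if (r$t_start <= sv$start && r$t_end >= sv$end &&
               lf >= anchor && rf >= anchor) "FULL"
    else if (lf >= anchor && r$t_end > sv$start) "OVERLAP_LEFT"
    else if (rf >= anchor && r$t_start < sv$end) "OVERLAP_RIGHT"
    else "NONE"
    tibble(read_id = r$read_id, span_class = cls, p_aligned = r$p_aligned,
           r_gaps = r$r_gaps, left_flank = lf, right_flank = rf)
  })
}

#' Classify validation evidence into a verdict
#'
#' `STRINGENT`: at least two fully spanning reads, each with alignment
#' coverage of at least 99.5% and a gap ratio below 0.005.  `STANDARD`:
#' either at least two overlap-spanning reads on each side meeting the
#' stringent quality thresholds, or at least two fully spanning reads with
#' coverage of at least 97.5% and gap ratio below 0.025.  Anything else is
#' `UNVALIDATED`.  Fully spanning reads cover both breakpoints and count
#' toward both sides.
#'
#' @param evidence Evidence tibble from [collect_spanning_evidence()].
#' @return One-row tibble: `verdict`, `n_full`, `n_left`, `n_right`,
#'   `best_p_aligned`, `best_r_gaps`, `supporting` (comma-joined ids).
#' @export
classify_validation <- function(evidence) {
  ev <- evidence[evidence$span_class != "NONE", , drop = FALSE]
  hq <- ev$p_aligned >= 0.995 & ev$r_gaps < 0.005
  mq <- ev$p_aligned >= 0.975 & ev$r_gaps < 0.025
  full <- ev$span_class == "FULL"
  left <- full | ev$span_class == "OVERLAP_LEFT"
  right <- full | ev$span_class == "OVERLAP_RIGHT"
  stringent <- sum(full & hq) >= 2
  standard <- stringent ||
    (sum(left & hq) >= 2 && sum(right & hq) >= 2) ||
    sum(full & mq) >= 2
  support <- ev$read_id[(full & mq) | (left & hq) | (right & hq)]
  tibble(
    verdict = if (stringent) "STRINGENT" else if (standard) "STANDARD"
      else "UNVALIDATED",
    n_full = sum(full), n_left = sum(left & !full),
    n_right = sum(right & !full),
    best_p_aligned = if (nrow(ev) > 0) max(ev$p_aligned) else NA_real_,
    best_r_gaps = if (nrow(ev) > 0) min(ev$r_gaps) else NA_real_,
    supporting = paste(support, collapse = ",")
  )
}

#' Validate a set of SVs against long-read alignments
#'
#' @param svs Tibble with `sv_id`, `chrom`, `start`, `end` (assembly
#'   coordinates, 0-based half-open).
#' @param records Alignment-record tibble.
#' @param anchor Required aligned flank (bp).
#' @return Verdict tibble, one row per SV.
#' @export
validate_svs <- function(svs, records, anchor = 250) {
  purrr::map_dfr(seq_len(nrow(svs)), function(i) {
    ev <- collect_spanning_evidence(svs[i, ], records, anchor = anchor)
    bind_cols(tibble(sv_id = svs$sv_id[i]), classify_validation(ev))
  })
}
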