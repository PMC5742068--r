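# Independent oracles used across the suite.  These deliberately avoid the
# package's own algorithms: the MEM oracle is a direct substring scan, the
# alignment oracle is Biostrings' full dynamic program, the block-selection
# oracle is subset enumeration, and the rank-sum oracle enumerates label
# assignments.

random_seq <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, TRUE, prob = p), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# all maximal exact matches between two strings (forward strand), by a
# quadratic extension-length table; N never matches
oracle_mems <- function(ref, qry, min_len, unique_in_ref = TRUE) {
  rc <- strsplit(ref, "")[[1]]
  qc <- strsplit(qry, "")[[1]]
  nr <- length(rc); nq <- length(qc)
  valid_r <- rc %in% c("A", "C", "G", "T")
  valid_q <- qc %in% c("A", "C", "G", "T")
  M <- outer(rc, qc, "==") & outer(valid_r, valid_q, "&")
  L <- matrix(0L, nr + 1, nq + 1)
  for (i in nr:1) {
    L[i, 1:nq] <- ifelse(M[i, ], L[i + 1, 2:(nq + 1)] + 1L, 0L)
  }
  hits <- which(L[1:nr, 1:nq, drop = FALSE] >= min_len, arr.ind = TRUE)
  if (nrow(hits) > 0) {
    left_max <- apply(hits, 1, function(h) {
      i <- h[1]; j <- h[2]
      i == 1 || j == 1 || !M[i - 1, j - 1]
    })
    hits <- hits[left_max, , drop = FALSE]
  }
  out <- tibble::tibble(ref_start = as.integer(hits[, 1] - 1L),
                        qry_start = as.integer(hits[, 2] - 1L),
                        length = L[hits])
  if (unique_in_ref && nrow(out) > 0) {
    keep <- vapply(seq_len(nrow(out)), function(k) {
      len <- out$length[k]
      sub <- substr(ref, out$ref_start[k] + 1, out$ref_start[k] + len)
      # count all (also overlapping) occurrences
      occ <- sum(vapply(seq_len(nr - len + 1), function(p) {
        substr(ref, p, p + len - 1) == sub
      }, logical(1)))
      occ == 1
    }, logical(1))
    out <- out[keep, , drop = FALSE]
  }
  dplyr::arrange(out, ref_start, qry_start)
}

# Biostrings full dynamic program as the global-alignment score oracle
oracle_align_score <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  Biostrings::score(Biostrings::pairwiseAlignment(
    Biostrings::DNAString(b), Biostrings::DNAString(a), type = "global",
    substitutionMatrix = mat, gapOpening = 2, gapExtension = 0.5))
}

# brute-force maximum-weight consistent subset of blocks
oracle_block_weight <- function(blocks, tol = 50, mode = "both") {
  n <- nrow(blocks)
  conflicts <- function(i, j) {
    rc <- blocks$ref_name[i] == blocks$ref_name[j] &&
      min(blocks$ref_end[i], blocks$ref_end[j]) -
        max(blocks$ref_start[i], blocks$ref_start[j]) > tol
    qc <- blocks$qry_name[i] == blocks$qry_name[j] &&
      min(blocks$qry_fwd_end[i], blocks$qry_fwd_end[j]) -
        max(blocks$qry_fwd_start[i], blocks$qry_fwd_start[j]) > tol
    switch(mode, both = rc || qc, ref = rc, qry = qc)
  }
  best <- 0
  for (s in 0:(2^n - 1)) {
    members <- which(bitwAnd(s, 2^(0:(n - 1))) > 0)
    ok <- TRUE
    if (length(members) > 1) {
      for (i in seq_along(members)) {
        for (j in seq_len(i - 1)) {
          if (conflicts(members[i], members[j])) { ok <- FALSE; break }
        }
        if (!ok) break
      }
    }
    if (ok) best <- max(best, sum(blocks$weight[members]))
  }
  best
}

# synthetic block rows for filter tests (coordinates only)
make_block <- function(ref_start, ref_end, qry_start, qry_end, weight,
                       ref_name = "r", qry_name = "q", strand = "+",
                       qry_len = 1e6) {
  tibble::tibble(
    ref_name = ref_name, qry_name = qry_name, strand = strand,
    ref_start = ref_start, ref_end = ref_end,
    qry_start = qry_start, qry_end = qry_end,
    qry_fwd_start = qry_start, qry_fwd_end = qry_end, qry_len = qry_len,
    weight = weight, cigar = paste0(ref_end - ref_start, "="),
    n_match = ref_end - ref_start, n_mismatch = 0L, n_gapcols = 0L,
    identity = 1, score = weight, block_id = NA_integer_,
    cluster_id = NA_integer_
  )
}

# exhaustive two-sided rank-sum p by label enumeration
oracle_rank_sum <- function(x, y) {
  n1 <- length(x)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  subs <- utils::combn(length(r), n1)
  ws <- apply(subs, 2, function(s) sum(r[s]))
  min(1, 2 * min(mean(ws <= w + 1e-9), mean(ws >= w - 1e-9)))
}

# a small mutated genome pair with known edits, for alignment-layer tests
mutated_pair <- function(n = 4000, seed = 11) {
  withr::with_seed(seed, {
    ref <- random_seq(n)
    qry <- ref
    snp_at <- as.integer(n * 0.3)
    substr(qry, snp_at, snp_at) <-
      setdiff(c("A", "C", "G", "T"), substr(qry, snp_at, snp_at))[1]
    list(ref = c(r = ref), qry = c(q = qry), snp_at = snp_at - 1L)
  })
}
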