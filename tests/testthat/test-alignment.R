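test_that("align_global matches the full dynamic-programming oracle", {
  withr::with_seed(31, {
    for (i in seq_len(60)) {
      n <- sample(10:500, 1)
      a <- random_seq(n)
      b <- a
      for (p in sample(nchar(b), sample(0:8, 1))) {
        substr(b, p, p) <- sample(c("A", "C", "G", "T"), 1)
      }
      if (runif(1) < 0.5) { # small indel
        cut <- sort(sample(nchar(b), 2))
        if (cut[2] - cut[1] < 40) {
          b <- paste0(substr(b, 1, cut[1]), substr(b, cut[2], nchar(b)))
        }
      }
      if (nchar(b) < 1) next
      expect_equal(align_global(a, b)$score, oracle_align_score(a, b),
                   tolerance = 1e-9)
    }
  })
})

test_that("align_global cigar is consistent with its inputs", {
  a <- "ACGTACGT"; b <- "ACGTTACGT"
  res <- align_global(a, b)
  st <- svmap:::cigar_stats(res$cigar)
  expect_equal(st$ref_span, nchar(a))
  expect_equal(st$qry_span, nchar(b))
})

test_that("fill_cluster_alignment resolves identity and single-SNP cases", {
  withr::with_seed(32, {
    s <- random_seq(1000)
    m <- find_mems(c(r = s), c(q = s), min_len = 20)
    cl <- cluster_matches(m)
    blk <- fill_cluster_alignment(cl[1, ], c(r = s), c(q = s))
    expect_equal(blk$n_mismatch, 0L)
    expect_equal(blk$n_gapcols, 0L)
    expect_equal(blk$cigar, "1000=")

    pair <- mutated_pair(2000, seed = 33)
    m2 <- find_mems(pair$ref, pair$qry, min_len = 20)
    cl2 <- cluster_matches(m2)
    blk2 <- fill_cluster_alignment(cl2[1, ], pair$ref, pair$qry)
    expect_equal(blk2$n_mismatch, 1L)
    expect_equal(blk2$n_gapcols, 0L)
  })
})

test_that("fill_cluster_alignment score equals unconstrained DP on interval pairs", {
  withr::with_seed(34, {
    for (i in seq_len(50)) {
      n <- sample(120:500, 1)
      ref <- random_seq(n)
      qry <- ref
      for (p in sample(nchar(qry), sample(1:4, 1))) {
        substr(qry, p, p) <- sample(c("A", "C", "G", "T"), 1)
      }
      if (runif(1) < 0.4) {
        at <- sample(seq(30, n - 30), 1)
        qry <- paste0(substr(qry, 1, at), random_seq(sample(1:10, 1)),
                      substr(qry, at + 1, nchar(qry)))
      }
      m <- find_mems(c(r = ref), c(q = qry), min_len = 15)
      cl <- cluster_matches(m, l = 50)
      if (nrow(cl) != 1 || cl$ref_start != 0 || cl$ref_end != n) next
      blk <- fill_cluster_alignment(cl[1, ], c(r = ref), c(q = qry))
      if (blk$qry_start != 0 || blk$qry_end != nchar(qry)) next
      expect_equal(blk$score, oracle_align_score(ref, qry), tolerance = 1e-9)
    }
  })
})

test_that("ungapped projection of a filled alignment reproduces both substrings", {
  withr::with_seed(35, {
    pair <- mutated_pair(3000, seed = 35)
    qry <- pair$qry
    qry[["q"]] <- paste0(substr(qry[["q"]], 1, 1200), random_seq(40),
                         substr(qry[["q"]], 1221, nchar(qry[["q"]])))
    m <- find_mems(pair$ref, qry, min_len = 20)
    blocks <- fill_clusters(cluster_matches(m), pair$ref, qry)
    for (i in seq_len(nrow(blocks))) {
      blk <- blocks[i, ]
      runs <- svmap:::cigar_runs(blk$cigar)
      rpos <- blk$ref_start; qpos <- blk$qry_start
      rparts <- character(0); qparts <- character(0)
      for (k in seq_len(nrow(runs))) {
        if (runs$op[k] %in% c("=", "X")) {
          rparts <- c(rparts, substr(pair$ref[["r"]], rpos + 1,
                                     rpos + runs$len[k]))
          qparts <- c(qparts, substr(qry[["q"]], qpos + 1,
                                     qpos + runs$len[k]))
          rpos <- rpos + runs$len[k]; qpos <- qpos + runs$len[k]
        } else if (runs$op[k] == "D") {
          rparts <- c(rparts, substr(pair$ref[["r"]], rpos + 1,
                                     rpos + runs$len[k]))
          rpos <- rpos + runs$len[k]
        } else {
          qparts <- c(qparts, substr(qry[["q"]], qpos + 1,
                                     qpos + runs$len[k]))
          qpos <- qpos + runs$len[k]
        }
      }
      expect_equal(paste(rparts, collapse = ""),
                   substr(pair$ref[["r"]], blk$ref_start + 1, blk$ref_end))
      expect_equal(paste(qparts, collapse = ""),
                   substr(qry[["q"]], blk$qry_start + 1, blk$qry_end))
    }
  })
})

test_that("filter_mutual_best keeps non-overlapping blocks unchanged and empty input empty", {
  b <- dplyr::bind_rows(make_block(0, 100, 0, 100, 100),
                        make_block(200, 300, 200, 300, 100))
  expect_equal(nrow(filter_mutual_best(b)), 2)
  expect_equal(nrow(filter_mutual_best(b[0, ])), 0)
})

test_that("filter_mutual_best picks the heavier of two conflicting blocks", {
  b <- dplyr::bind_rows(make_block(0, 500, 0, 500, 500),
                        make_block(100, 400, 5000, 5300, 300))
  out <- filter_mutual_best(b)
  expect_equal(nrow(out), 1)
  expect_equal(out$weight, 500)
})

test_that("filter_mutual_best matches brute-force selection on random block sets", {
  withr::with_seed(36, {
    contained_same_diag <- function(b) {
      for (i in seq_len(nrow(b))) {
        for (j in seq_len(nrow(b))) {
          if (i == j) next
          if (b$ref_start[i] >= b$ref_start[j] - 50 &&
              b$ref_end[i] <= b$ref_end[j] + 50 &&
              b$qry_start[i] >= b$qry_start[j] - 50 &&
              b$qry_end[i] <= b$qry_end[j] + 50 &&
              abs((b$qry_start[i] - b$ref_start[i]) -
                    (b$qry_start[j] - b$ref_start[j])) <= 100) return(TRUE)
        }
      }
      FALSE
    }
    for (case in seq_len(40)) {
      n <- sample(3:10, 1)
      repeat {
        blocks <- purrr::map_dfr(seq_len(n), function(i) {
          rs <- sample(0:2000, 1); qs <- sample(0:2000, 1)
          len <- sample(100:800, 1)
          make_block(rs, rs + len, qs, qs + sample(100:800, 1),
                     weight = sample(50:1000, 1))
        })
        # distinct placements only: a fragment of the same homology on the
        # same diagonal is deduplicated, not a competing placement
        if (!contained_same_diag(blocks)) break
      }
      mode <- sample(c("both", "ref", "qry"), 1)
      got <- filter_mutual_best(blocks, mode)
      expect_equal(sum(got$weight), oracle_block_weight(blocks, mode = mode))
    }
  })
})

test_that("stitching restores base-level continuity across sub-SV gaps", {
  withr::with_seed(37, {
    ref <- random_seq(3000)
    # 30-bp deletion at 1000 and 12-bp insertion at 2000
    qry <- paste0(substr(ref, 1, 1000), substr(ref, 1031, 2000),
                  random_seq(12), substr(ref, 2001, 3000))
    m <- find_mems(c(r = ref), c(q = qry), min_len = 20)
    bl <- fill_clusters(cluster_matches(m), c(r = ref), c(q = qry))
    st <- stitch_blocks(filter_mutual_best(bl), c(r = ref), c(q = qry))
    expect_equal(nrow(st), 1)
    expect_equal(st$ref_start, 0L)
    expect_equal(st$ref_end, 3000)
    expect_equal(st$n_gapcols, 42L)
  })
})
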