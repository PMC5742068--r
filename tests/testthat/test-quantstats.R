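test_that("Fisher's method matches closed forms and stays monotone", {
  # k = 1: combined p equals the input
  expect_equal(fisher_combine(0.37)$p_value, 0.37, tolerance = 1e-12)
  # k = 2, both 0.5: chi-square tail oracle by numerical integration
  f <- fisher_combine(c(0.5, 0.5))
  oracle <- stats::integrate(function(t) stats::dchisq(t, 4), f$statistic,
                             Inf)$value
  expect_equal(f$p_value, oracle, tolerance = 1e-8)
  # monotone: decreasing any input p never increases the combined p
  withr::with_seed(91, {
    for (i in 1:20) {
      p <- runif(4)
      j <- sample(4, 1)
      p2 <- p; p2[j] <- p2[j] * runif(1)
      expect_lte(fisher_combine(p2)$p_value, fisher_combine(p)$p_value)
    }
  })
  expect_error(fisher_combine(c(0.5, 0)), "0, 1")
  expect_s3_class(tidy(fisher_combine(0.1)), "tbl_df")
})

test_that("the six replicate rank-sum p-values combine far below 1e-16", {
  p6 <- c(2.12e-10, 6.76e-10, 1.89e-6, 9.21e-14, 1.96e-6, 1.25e-24)
  f <- fisher_combine(p6)
  expect_lt(f$p_value, 1e-16)
})

test_that("exact rank-sum p equals the label-enumeration oracle", {
  # strictly separated 4 vs 4: p = 2 / C(8,4)
  expect_equal(rank_sum_test(1:4, 11:14)$p_value, 2 / choose(8, 4),
               tolerance = 1e-12)
  withr::with_seed(92, {
    for (i in seq_len(150)) {
      n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
      x <- sample(1:10, n1, TRUE); y <- sample(1:10, n2, TRUE)
      expect_equal(rank_sum_test(x, y)$p_value, oracle_rank_sum(x, y),
                   tolerance = 1e-12)
    }
  })
})

test_that("rank-sum test is symmetric and its approximation tracks wilcox.test", {
  withr::with_seed(93, {
    x <- rnorm(20); y <- rnorm(25, 0.5)
    expect_equal(rank_sum_test(x, y)$p_value, rank_sum_test(y, x)$p_value,
                 tolerance = 1e-12)
    ours <- rank_sum_test(x, y)
    ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
    expect_equal(ours$method, "normal")
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  })
})

test_that("temperature interpolation reproduces the calibration line", {
  flat <- tibble::tibble(position = c(0, 10, 20, 30), temperature = 22)
  expect_equal(positions_to_temperatures(flat, c(3, 17))$temperature,
               c(22, 22))
  calib <- tibble::tibble(position = seq(0, 40, 4),
                          temperature = seq(9, 30, length.out = 11))
  expect_equal(positions_to_temperatures(calib, 20)$temperature, 19.5)
  expect_equal(positions_to_temperatures(calib, 8)$temperature,
               calib$temperature[3], tolerance = 1e-9)
  expect_error(positions_to_temperatures(
    tibble::tibble(position = 1, temperature = 20), 1))
})

test_that("FPKM follows the effective-length formula", {
  q <- tibble::tibble(copy = "proximal", count = 100, transcript_len = 1509,
                      uncovered_len = 310, total_mapped = 1e7)
  out <- paralog_fpkm(q)
  expect_equal(out$effective_len, 1199)
  expect_equal(out$fpkm, 100 / (1.199 * 10))
  # linearity in the count
  out2 <- paralog_fpkm(dplyr::mutate(q, count = 200))
  expect_equal(out2$fpkm, 2 * out$fpkm)
  expect_error(paralog_fpkm(dplyr::mutate(q, uncovered_len = 1509)),
               "indistinguishable")
})

test_that("divergent-pair calling recovers presence and frequency", {
  sim <- sim_pair_records(20, 8)
  res <- divergent_pair_duplication_call(sim$records, sim$candidate,
                                         sim$samples, min_cov = 5e5)
  # all carriers detected
  expect_true(all(res$samples$present[1:8]))
  # frequency inside the exact binomial 95% CI of 0.4 at n = 20
  ci <- stats::binom.test(8, 20)$conf.int
  expect_gte(res$frequency$frequency, ci[1])
  expect_lte(res$frequency$frequency, ci[2])
  # a sample with zero divergent pairs is absent
  clean <- sim$records[sim$records$sample_id == "s15", ]
  clean$proper <- TRUE
  res2 <- divergent_pair_duplication_call(
    clean, sim$candidate,
    sim$samples[sim$samples$sample_id == "s15", ], min_cov = 5e5,
    min_pop = 1)
  expect_false(res2$samples$present)
})

test_that("exclusion rules drop low-coverage, IBD and small populations", {
  sim <- sim_pair_records(12, 5)
  sams <- sim$samples
  sams$aligned_bp[1] <- 1e4 # low coverage
  ibd <- tibble::tibble(sample_a = "s02", sample_b = "s03")
  res <- divergent_pair_duplication_call(sim$records, sim$candidate, sams,
                                         ibd = ibd, min_cov = 5e5,
                                         min_pop = 10)
  expect_equal(res$samples$exclusion[1], "low_coverage")
  expect_equal(res$samples$exclusion[res$samples$sample_id == "s03"], "ibd")
  expect_equal(sum(res$samples$retained), 10)
  expect_equal(res$frequency$retained, 10L)
  # population smaller than min_pop disappears from the frequency table
  res2 <- divergent_pair_duplication_call(sim$records, sim$candidate, sams,
                                          ibd = ibd, min_cov = 5e5,
                                          min_pop = 11)
  expect_equal(nrow(res2$frequency), 0)
  expect_error(divergent_pair_duplication_call(
    sim$records, sim$candidate,
    dplyr::mutate(sim$samples, aligned_bp = 0), min_cov = 5e5),
    "no samples retained")
})

test_that("the frequency estimate ignores sample order", {
  sim <- sim_pair_records(12, 5)
  res1 <- divergent_pair_duplication_call(sim$records, sim$candidate,
                                          sim$samples, min_cov = 5e5,
                                          min_pop = 5)
  shuf <- sim$records[sample(nrow(sim$records)), ]
  res2 <- divergent_pair_duplication_call(shuf, sim$candidate,
                                          sim$samples[sample(12), ],
                                          min_cov = 5e5, min_pop = 5)
  expect_equal(res1$frequency$frequency, res2$frequency$frequency)
})
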