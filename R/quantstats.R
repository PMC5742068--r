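#' Combine p-values with Fisher's method
#'
#' Computes `X = -2 * sum(log(p))` and refers it to a chi-square
#' distribution with `2k` degrees of freedom.
#'
#' @param pvals Numeric vector of p-values in (0, 1].
#' @return A `fisher_meta` object (list with `statistic`, `df`,
#'   `p_value`, `log10_p`, `k`).
#' @export
fisher_combine <- function(pvals) {
  if (length(pvals) < 1 || any(!is.finite(pvals)) || any(pvals <= 0) ||
      any(pvals > 1))
    stop("p-values must lie in (0, 1]")
  x <- -2 * sum(log(pvals))
  df <- 2L * length(pvals)
  structure(list(statistic = x, df = df,
                 p_value = pchisq(x, df, lower.tail = FALSE),
                 log10_p = pchisq(x, df, lower.tail = FALSE,
                                  log.p = TRUE) / log(10),
                 k = length(pvals)),
            class = "fisher_meta")
}

#' @export
print.fisher_meta <- function(x, ...) {
  cat(sprintf("Fisher's method: X = %.4g on %d df, combined p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' @rdname fisher_combine
#' @param x A `fisher_meta` object.
#' @param ... Unused.
#' @export
tidy.fisher_meta <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
         log10_p = x$log10_p)
}

#' @rdname fisher_combine
#' @export
glance.fisher_meta <- function(x, ...) tidy(x)

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration of the rank-sum distribution (ties handled by average
#' ranks) when the combined sample size is at most `exact_max`; normal
#' approximation with tie correction and continuity correction otherwise.
#' The two-sided p-value is twice the smaller tail, capped at 1.
#'
#' @param x,y Numeric samples.
#' @param exact_max Combined-size cutoff for the exact distribution.
#' @return One-row tibble: `statistic` (rank sum of `x`), `p_value`,
#'   `method`.
#' @export
rank_sum_test <- function(x, y, exact_max = 12) {
  stopifnot(length(x) > 0, length(y) > 0)
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  if (n <= exact_max) {
    # exact distribution of the rank sum over all C(n, n1) assignments,
    # by dynamic programming over doubled (integer) ranks
    r2 <- as.integer(round(2 * r))
    smax <- sum(sort(r2, decreasing = TRUE)[seq_len(n1)])
    # dp[k+1, s+1] = number of k-subsets of r2 with sum s
    dp <- matrix(0, nrow = n1 + 1, ncol = smax + 1)
    dp[1, 1] <- 1
    for (v in r2) {
      for (k in min(n1, n1):1) {
        # shift row k-1 by v
        upto <- smax + 1 - v
        dp[k + 1, (v + 1):(smax + 1)] <-
          dp[k + 1, (v + 1):(smax + 1)] + dp[k, 1:upto]
      }
    }
    counts <- dp[n1 + 1, ]
    total <- sum(counts)
    w2 <- as.integer(round(2 * w))
    p_low <- sum(counts[seq_len(w2 + 1)]) / total
    p_high <- sum(counts[(w2 + 1):(smax + 1)]) / total
    p <- min(1, 2 * min(p_low, p_high))
    tibble(statistic = w, p_value = p, method = "exact")
  } else {
    mu <- n1 * (n + 1) / 2
    ties <- table(r)
    sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * pnorm(-abs(z)))
    tibble(statistic = w, p_value = p, method = "normal")
  }
}

#' Interpolate temperatures from probe calibration
#'
#' Fits a least-squares line to probe (position, temperature) readings and
#' predicts the temperature at each observed position along the gradient.
#'
#' @param calib Tibble/data frame with `position` (cm) and `temperature`
#'   (degrees C); at least two distinct positions.
#' @param positions Positions (cm) to interpolate.
#' @return Tibble: `position`, `temperature`.
#' @export
positions_to_temperatures <- function(calib, positions) {
  stopifnot(all(c("position", "temperature") %in% names(calib)),
            length(unique(calib$position)) >= 2)
  fit <- lm(temperature ~ position, data = calib)
  tibble(position = positions,
         temperature = unname(predict(fit,
                                      tibble(position = positions))))
}

#' Paralog-specific FPKM with effective transcript length
#'
#' Computes FPKM from copy-specific read counts over the effective
#' transcript length (transcript length minus the regions no
#' copy-distinguishing read can cover):
#' `FPKM = count / ((effective_len/1e3) * (total_mapped/1e6))`.
#'
#' @param quants Tibble with `count`, `transcript_len`, `uncovered_len`,
#'   `total_mapped` (and any id columns, carried through).
#' @return `quants` with `effective_len` and `fpkm` added.
#' @export
paralog_fpkm <- function(quants) {
  stopifnot(all(c("count", "transcript_len", "uncovered_len",
                  "total_mapped") %in% names(quants)))
  out <- mutate(as_tibble(quants),
                effective_len = .data$transcript_len - .data$uncovered_len)
  if (any(out$effective_len <= 0))
    stop("effective transcript length <= 0: copy is indistinguishable")
  if (any(out$total_mapped <= 0)) stop("total mapped reads must be > 0")
  mutate(out, fpkm = .data$count /
           ((.data$effective_len / 1e3) * (.data$total_mapped / 1e6)))
}

#' Call duplication presence and allele frequency from divergent read
#' pairs
#'
#' Divergent pairs are the complement of properly oriented pairs.  A
#' sample carries the duplication when the count of divergent pairs
#' anchored within `w` bp of a candidate breakpoint reaches `k_min` and
#' exceeds `r_min` times the background divergent-pair level.  Samples
#' with low aligned coverage on the chromosome or identical by descent to
#' an earlier sample over the region are excluded; populations with fewer
#' than `min_pop` retained samples are excluded.  The allele frequency is
#' carriers over retained samples per population.
#'
#' @param records Pair-orientation tibble: `sample_id`, `chrom`, `pos1`,
#'   `strand1`, `pos2`, `strand2`, `proper`.
#' @param candidate List/one-row tibble with `chrom`, `start`, `end` (the
#'   duplication breakpoints on the reference, 0-based half-open).
#' @param samples Sample metadata: `sample_id`, `population`,
#'   `aligned_bp` (aligned bases on the candidate chromosome).
#' @param ibd Optional IBD table (`sample_a`, `sample_b`); the second
#'   member of each pair is excluded.
#' @param w Breakpoint window (bp).
#' @param k_min Minimum divergent pairs at the peak.
#' @param r_min Minimum peak-to-background ratio.
#' @param min_cov Minimum aligned bp on the chromosome.
#' @param min_pop Minimum retained samples per population.
#' @return List: `samples` (per-sample presence and retention),
#'   `frequency` (per-population carriers, retained, frequency).
#' @export
divergent_pair_duplication_call <- function(records, candidate, samples,
                                            ibd = NULL, w = 500, k_min = 3,
                                            r_min = 5, min_cov = 1e7,
                                            min_pop = 10) {
  samples <- as_tibble(samples)
  samples$retained <- samples$aligned_bp >= min_cov
  samples$exclusion <- ifelse(samples$retained, NA_character_, "low_coverage")
  if (!is.null(ibd) && nrow(ibd) > 0) {
    drop <- unique(ibd$sample_b)
    hit <- samples$sample_id %in% drop & samples$retained
    samples$retained[hit] <- FALSE
    samples$exclusion[hit] <- "ibd"
  }
  if (!any(samples$retained)) stop("no samples retained; frequency undefined")

  bps <- c(candidate$start, candidate$end)
  samples$present <- NA
  samples$peak <- NA_integer_
  samples$background <- NA_real_
  for (i in seq_len(nrow(samples))) {
    if (!samples$retained[i]) next
    rr <- records[records$sample_id == samples$sample_id[i] &
                    records$chrom == candidate$chrom, , drop = FALSE]
    div <- rr[!rr$proper, , drop = FALSE]
    near <- rep(FALSE, nrow(div))
    for (bp in bps) {
      near <- near | abs(div$pos1 - bp) <= w | abs(div$pos2 - bp) <= w
    }
    peak <- sum(near)
    span <- if (nrow(rr) > 0) diff(range(c(rr$pos1, rr$pos2))) else 0
    bg_bp <- max(span - 4 * w, 1)
    bg <- (nrow(div) - peak) / bg_bp * (2 * w)
    samples$peak[i] <- peak
    samples$background[i] <- bg
    samples$present[i] <- peak >= k_min && peak >= r_min * max(bg, 0.5)
  }

  freq <- samples |>
    filter(.data$retained) |>
    group_by(.data$population) |>
    summarise(carriers = sum(.data$present), retained = n(),
              .groups = "drop") |>
    filter(.data$retained >= min_pop) |>
    mutate(frequency = .data$carriers / .data$retained)
  list(samples = samples, frequency = freq)
}
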