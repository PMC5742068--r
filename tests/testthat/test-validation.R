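# constructed alignment records exercise the spanning/threshold rules
mk_record <- function(t_start, t_end, p_aligned = 1, r_gaps = 0,
                      read_id = "r1") {
  tibble::tibble(read_id = read_id, read_len = t_end - t_start,
                 target = "chr", t_start = t_start, t_end = t_end,
                 strand = "+", q_start = 0L, q_end = t_end - t_start,
                 aligned_bases = round(p_aligned * (t_end - t_start)),
                 gap_cols = round(r_gaps * (t_end - t_start)),
                 p_aligned = p_aligned, r_gaps = r_gaps,
                 cigar = paste0(t_end - t_start, "="))
}
sv <- list(chrom = "chr", start = 5000L, end = 6000L)

test_that("span classes follow the 250-bp anchor rule", {
  full <- collect_spanning_evidence(sv, mk_record(4700L, 6300L))
  expect_equal(full$span_class, "FULL")
  left <- collect_spanning_evidence(sv, mk_record(4600L, 5500L))
  expect_equal(left$span_class, "OVERLAP_LEFT")
  right <- collect_spanning_evidence(sv, mk_record(5500L, 6400L))
  expect_equal(right$span_class, "OVERLAP_RIGHT")
  none <- collect_spanning_evidence(sv, mk_record(4800L, 5500L)) # 200-bp flank
  expect_equal(none$span_class, "NONE")
})

test_that("verdicts follow the stringent/standard thresholds", {
  two_full <- function(p, g) dplyr::bind_rows(
    collect_spanning_evidence(sv, mk_record(4700L, 6300L, p, g, "a")),
    collect_spanning_evidence(sv, mk_record(4600L, 6400L, p, g, "b")))
  expect_equal(classify_validation(two_full(0.997, 0.003))$verdict,
               "STRINGENT")
  expect_equal(classify_validation(two_full(0.980, 0.020))$verdict,
               "STANDARD")
  expect_equal(classify_validation(two_full(0.970, 0.020))$verdict,
               "UNVALIDATED")
  expect_equal(classify_validation(two_full(0.980, 0.030))$verdict,
               "UNVALIDATED")
  # a single high-quality full read is not enough
  one <- collect_spanning_evidence(sv, mk_record(4700L, 6300L, 0.999, 0.001))
  expect_equal(classify_validation(one)$verdict, "UNVALIDATED")
  # two overlap reads per side at stringent quality reach STANDARD
  ev <- dplyr::bind_rows(
    collect_spanning_evidence(sv, mk_record(4600L, 5500L, 0.997, 0.003, "l1")),
    collect_spanning_evidence(sv, mk_record(4500L, 5400L, 0.997, 0.003, "l2")),
    collect_spanning_evidence(sv, mk_record(5500L, 6400L, 0.997, 0.003, "r1")),
    collect_spanning_evidence(sv, mk_record(5600L, 6500L, 0.997, 0.003, "r2")))
  expect_equal(classify_validation(ev)$verdict, "STANDARD")
})

test_that("anchored read mapping recovers error-free and noisy reads", {
  withr::with_seed(61, {
    genome <- c(chr = random_seq(20000))
    reads0 <- simulate_long_reads(genome, coverage = 2, meanlog = log(3000),
                                  error_rate = 0, seed = 3)
    rec0 <- map_long_reads(reads0, genome)
    expect_equal(nrow(rec0), nrow(reads0))
    expect_true(all(rec0$p_aligned == 1))
    expect_true(all(rec0$r_gaps == 0))
    expect_equal(rec0$t_start, reads0$start[match(rec0$read_id, reads0$name)])

    reads1 <- simulate_long_reads(genome, coverage = 2, meanlog = log(3000),
                                  error_rate = 0.01, seed = 4)
    rec1 <- map_long_reads(reads1, genome)
    expect_true(all(rec1$p_aligned > 0.9))
    expect_true(median(rec1$r_gaps) < 0.02)
  })
})

test_that("true SVs validate and wrong-assembly decoys do not", {
  withr::with_seed(62, {
    cfg <- sim_config(seed = 62, genome_length = 1.2e5, n_ancestral_te = 8,
                      n_te_ins = 4, n_ins = 3, n_del = 4, n_dup = 3,
                      n_dup_spacer = 2, n_inv = 2)
    anc <- simulate_ancestral_genome(cfg)
    der <- apply_variants(anc, cfg)
    reads <- simulate_long_reads(der$genome, coverage = 20, seed = 63)
    rec_der <- map_long_reads(reads, der$genome)
    svs <- der$truth[!der$truth$class %in%
                       c("snp", "small_insertion", "small_deletion"), ]
    tv <- validate_svs(tibble::tibble(
      sv_id = paste0(svs$class, "_", svs$anc_start), chrom = svs$chrom,
      start = svs$der_start, end = pmax(svs$der_end, svs$der_start + 1L)),
      rec_der)
    expect_gte(mean(tv$verdict %in% c("STANDARD", "STRINGENT")), 0.95)

    # decoys: the same breakpoints on the assembly lacking the variants
    rec_anc <- map_long_reads(reads, anc$genome)
    dv <- validate_svs(tibble::tibble(
      sv_id = paste0(svs$class, "_", svs$anc_start), chrom = svs$chrom,
      start = svs$anc_start, end = pmax(svs$anc_end, svs$anc_start + 1L)),
      rec_anc)
    expect_gte(mean(dv$verdict == "UNVALIDATED"), 0.95)
  })
})

test_that("raising the read error rate never adds stringent verdicts", {
  withr::with_seed(64, {
    genome <- c(chr = random_seq(30000))
    sv1 <- tibble::tibble(sv_id = "s1", chrom = "chr", start = 12000L,
                          end = 13000L)
    n_stringent <- vapply(c(0, 0.005, 0.02), function(err) {
      reads <- simulate_long_reads(genome, coverage = 10,
                                   meanlog = log(5000), error_rate = err,
                                   seed = 65)
      rec <- map_long_reads(reads, genome)
      sum(validate_svs(sv1, rec)$verdict == "STRINGENT")
    }, numeric(1))
    expect_true(all(diff(n_stringent) <= 0))
    expect_equal(n_stringent[1], 1) # error-free reads validate stringently
  })
})

test_that("SAM input yields the same record metrics as internal mapping", {
  skip_if_not_installed("Rsamtools")
  withr::with_seed(66, {
    genome <- c(chr = random_seq(4000))
    read <- substr(genome[[1]], 1001, 3000) # error-free 2-kb read
    sam <- tempfile(fileext = ".sam")
    writeLines(c(
      "@HD\tVN:1.6\tSO:coordinate",
      "@SQ\tSN:chr\tLN:4000",
      paste("r1", 0, "chr", 1001, 60, "2000M", "*", 0, 0, read,
            strrep("I", 2000), sep = "\t"),
      paste("r2", 16, "chr", 1501, 60, "900M10D1100M", "*", 0, 0,
            substr(read, 1, 2000), strrep("I", 2000), sep = "\t")
    ), sam)
    rec <- read_alignment_records(sam)
    expect_equal(nrow(rec), 2)
    r1 <- rec[rec$read_id == "r1", ]
    expect_equal(r1$t_start, 1000L)
    expect_equal(r1$t_end, 3000L)
    expect_equal(r1$p_aligned, 1)
    expect_equal(r1$r_gaps, 0)
    r2 <- rec[rec$read_id == "r2", ]
    expect_equal(r2$strand, "-")
    expect_equal(r2$gap_cols, 10)
    expect_equal(r2$t_end - r2$t_start, 2010)
  })
})
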