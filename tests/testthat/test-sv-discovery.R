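# constructed genomes with known edits drive each calling rule

test_that("a tandem duplication yields one gain over the duplicated unit", {
  withr::with_seed(41, {
    a <- random_seq(4000); s <- random_seq(2000); b <- random_seq(4000)
    ref <- c(chr = paste0(a, s, b))
    qry <- c(chr = paste0(a, s, s, b))
    cl <- cluster_matches(find_mems(ref, qry, 20))
    dups <- call_duplications(cl)
    expect_equal(nrow(dups), 1)
    expect_lt(abs(dups$ref_start - 4000), 20)
    expect_lt(abs(dups$ref_end - 6000), 20)
    expect_true(is.na(dups$spacer_start))
    # identical genomes: no duplication
    expect_equal(nrow(call_duplications(
      cluster_matches(find_mems(ref, ref, 20)))), 0)
  })
})

test_that("a spacer between the copies is recorded (Cyp28d1 geometry)", {
  withr::with_seed(42, {
    a <- random_seq(4000); s <- random_seq(3755); b <- random_seq(4000)
    spacer <- random_seq(1500)
    ref <- c(chr = paste0(a, s, b))
    qry <- c(chr = paste0(a, s, spacer, s, b))
    dups <- call_duplications(cluster_matches(find_mems(ref, qry, 20)))
    expect_equal(nrow(dups), 1)
    expect_false(is.na(dups$spacer_start))
    expect_lt(abs((dups$spacer_end - dups$spacer_start) - 1500), 25)
    expect_lt(abs(dups$ref_start - 4000), 20)
    expect_lt(abs(dups$ref_end - 7755), 20)
  })
})

test_that("copy-number verification counts copies and rejects equal counts", {
  withr::with_seed(43, {
    cand <- random_seq(1500)
    flank1 <- random_seq(2000); flank2 <- random_seq(2000)
    ref <- c(chr = paste0(flank1, cand, flank2))
    qry1 <- ref
    rep1 <- verify_copy_number(cand, ref, qry1)
    expect_equal(rep1$copies_ref, 1L)
    expect_equal(rep1$copies_qry, 1L)
    expect_false(rep1$accepted)

    qry2 <- c(chr = paste0(flank1, cand, cand, flank2))
    rep2 <- verify_copy_number(cand, ref, qry2)
    expect_equal(unlist(rep2[, c("copies_ref", "copies_qry")]),
                 c(copies_ref = 1L, copies_qry = 2L))
    expect_true(rep2$accepted)

    # a 5-kb interruption inside the second copy is below qco
    qry3 <- c(chr = paste0(flank1, cand, substr(cand, 1, 700),
                           random_seq(5000), substr(cand, 701, 1500),
                           flank2))
    rep3 <- verify_copy_number(cand, ref, qry3)
    expect_equal(rep3$copies_qry, 2L)
    # but interrupted beyond qco the second copy no longer counts
    qry4 <- c(chr = paste0(flank1, cand, substr(cand, 1, 700),
                           random_seq(11000), substr(cand, 701, 1500),
                           flank2))
    rep4 <- verify_copy_number(cand, ref, qry4)
    expect_equal(rep4$copies_qry, 1L)
  })
})

test_that("indel calls follow the gap/reciprocal-gap rule", {
  withr::with_seed(44, {
    left <- random_seq(3000); right <- random_seq(3000)
    mk_blocks <- function(qry) {
      ref <- c(chr = paste0(left, right))
      m <- find_mems(ref, qry, 20)
      stitch_blocks(filter_mutual_best(
        fill_clusters(cluster_matches(m), ref, qry)), ref, qry)
    }
    # implanted 500-bp insertion
    ins <- mk_blocks(c(chr = paste0(left, random_seq(500), right)))
    calls <- call_indels(ins)
    expect_equal(calls$sv_type, "INS_QRY")
    expect_equal(calls$length, 500L)
    expect_lt(abs(calls$ref_start - 3000), 20)

    # an 80-bp gap is below the length threshold: stitched, no call
    small <- mk_blocks(c(chr = paste0(left, random_seq(80), right)))
    expect_equal(nrow(call_indels(small)), 0)

    # qry gap 500 vs ref gap 400: divergent region, not an indel
    b <- dplyr::bind_rows(
      make_block(0, 3000, 0, 3000, 3000),
      make_block(3400, 6000, 3500, 6100, 2600))
    dv <- call_indels(b)
    expect_equal(dv$sv_type, "DIVERGENT")
  })
})

test_that("inversions are called from reverse blocks and TE copies removed", {
  withr::with_seed(45, {
    a <- random_seq(3000); s <- random_seq(2000); b <- random_seq(3000)
    ref <- c(chr = paste0(a, s, b))
    qry <- c(chr = paste0(a, revcomp(s), b))
    blocks <- filter_mutual_best(fill_clusters(
      cluster_matches(find_mems(ref, qry, 20)), ref, qry))
    invs <- call_inversions(blocks)
    expect_equal(nrow(invs), 1)
    expect_lt(abs(invs$ref_start - 3000), 20)
    expect_lt(abs(invs$ref_end - 5000), 20)

    # no reverse blocks: no inversions
    blocks_f <- filter_mutual_best(fill_clusters(
      cluster_matches(find_mems(ref, ref, 20)), ref, ref))
    expect_equal(nrow(call_inversions(blocks_f)), 0)

    # the reversed segment is an annotated TE copy: filtered out
    te_ann <- tibble::tibble(seqname = "chr", start = 3000L, end = 5000L,
                             label = "roo")
    expect_equal(nrow(call_inversions(blocks, repeats = te_ann)), 0)
  })
})

test_that("SNPs and small indels are recovered exactly in unique sequence", {
  withr::with_seed(46, {
    ref_seq <- random_seq(20000)
    qry_seq <- ref_seq
    snp_pos <- seq(1000, 10000, by = 1000) # 1-based
    for (p in snp_pos) {
      substr(qry_seq, p, p) <-
        setdiff(c("A", "C", "G", "T"), substr(qry_seq, p, p))[1]
    }
    # implant 3 small indels right-to-left so positions stay valid
    qry_seq <- paste0(substr(qry_seq, 1, 17000), random_seq(25),
                      substr(qry_seq, 17001, 20000))
    qry_seq <- paste0(substr(qry_seq, 1, 14000), substr(qry_seq, 14061, nchar(qry_seq)))
    qry_seq <- paste0(substr(qry_seq, 1, 12000), random_seq(5),
                      substr(qry_seq, 12001, nchar(qry_seq)))
    ref <- c(chr = ref_seq); qry <- c(chr = qry_seq)
    blocks <- stitch_blocks(filter_mutual_best(fill_clusters(
      cluster_matches(find_mems(ref, qry, 20)), ref, qry)), ref, qry)
    small <- call_snps_small_indels(blocks, ref, qry)
    snps <- small[small$kind == "SNP", ]
    expect_equal(sort(snps$ref_pos), as.integer(snp_pos - 1))
    expect_equal(sum(small$kind == "INS"), 2)
    expect_equal(sum(small$kind == "DEL"), 1)
    expect_equal(small$length[small$kind == "DEL"], 60L)

    # identical genomes: nothing
    blocks0 <- stitch_blocks(filter_mutual_best(fill_clusters(
      cluster_matches(find_mems(ref, ref, 20)), ref, ref)), ref, ref)
    expect_equal(nrow(call_snps_small_indels(blocks0, ref, ref)), 0)
  })
})

test_that("a 150-bp deletion is structural, not a small variant", {
  withr::with_seed(47, {
    ref_seq <- random_seq(8000)
    qry_seq <- paste0(substr(ref_seq, 1, 4000), substr(ref_seq, 4151, 8000))
    ref <- c(chr = ref_seq); qry <- c(chr = qry_seq)
    blocks <- stitch_blocks(filter_mutual_best(fill_clusters(
      cluster_matches(find_mems(ref, qry, 20)), ref, qry)), ref, qry)
    small <- call_snps_small_indels(blocks, ref, qry)
    expect_equal(nrow(small[small$kind %in% c("INS", "DEL"), ]), 0)
    dels <- call_indels(blocks)
    expect_equal(dels$sv_type, "DEL_QRY")
    expect_equal(dels$length, 150L)
  })
})

test_that("complex-event merging follows the 2-kb rule", {
  mk_call <- function(s, e) tibble::tibble(
    sv_type = "CNV_GAIN_QRY", ref_name = "chr", ref_start = s, ref_end = e,
    qry_name = "chr", qry_start = s, qry_end = e, length = e - s,
    te_status = "non-TE", spacer_start = NA_integer_,
    spacer_end = NA_integer_, copies_ref = NA_integer_,
    copies_qry = NA_integer_, evidence = "x")
  # 1.5 kb apart: merged into one event, affected bp from unmerged calls
  two_near <- dplyr::bind_rows(mk_call(1000L, 2000L), mk_call(3500L, 4000L))
  m1 <- merge_complex_events(two_near)
  expect_equal(nrow(m1$events), 1)
  expect_true(m1$events$complex)
  expect_equal(m1$counts$n_events, 1L)
  expect_equal(m1$affected_bp$affected_bp, 1500)
  # single call unchanged
  m2 <- merge_complex_events(mk_call(1000L, 2000L))
  expect_equal(nrow(m2$events), 1)
  expect_false(m2$events$complex)
  # 2.5 kb apart: separate events
  m3 <- merge_complex_events(dplyr::bind_rows(mk_call(1000L, 2000L),
                                              mk_call(4500L, 5000L)))
  expect_equal(nrow(m3$events), 2)
})

test_that("TE status uses the coverage threshold with inclusive boundary", {
  mk_call <- function() tibble::tibble(
    sv_type = "DEL_QRY", ref_name = "chr", ref_start = 1000L,
    ref_end = 2000L, qry_name = "chr", qry_start = 1000L, qry_end = 1000L,
    length = 1000L, te_status = NA_character_, spacer_start = NA_integer_,
    spacer_end = NA_integer_, copies_ref = NA_integer_,
    copies_qry = NA_integer_, evidence = "x")
  ann <- function(s, e) tibble::tibble(seqname = "chr", start = s, end = e,
                                       label = "ltr")
  expect_equal(annotate_te_status(mk_call(), ann(5000L, 6000L))$te_status,
               "non-TE")
  expect_equal(annotate_te_status(mk_call(), ann(1000L, 1900L))$te_status,
               "TE")
  expect_equal(annotate_te_status(mk_call(), ann(1000L, 1800L))$te_status,
               "TE") # exactly 80%: boundary inclusive
  expect_equal(annotate_te_status(mk_call(), ann(1000L, 1799L))$te_status,
               "non-TE")
  expect_warning(out <- annotate_te_status(mk_call()), "missing repeat")
  expect_equal(out$te_status, "non-TE")
})

test_that("swapping the genomes swaps insertion and deletion polarity", {
  withr::with_seed(48, {
    left <- random_seq(3000); right <- random_seq(3000)
    ins_seq <- random_seq(400)
    g1 <- c(chr = paste0(left, right))
    g2 <- c(chr = paste0(left, ins_seq, right))
    fwd <- suppressWarnings(sv_call(g1, g2, verify = FALSE))
    rev <- suppressWarnings(sv_call(g2, g1, verify = FALSE))
    expect_equal(fwd$calls$sv_type, "INS_QRY")
    expect_equal(rev$calls$sv_type, "DEL_QRY")
    expect_equal(fwd$calls$length, rev$calls$length)
    expect_lt(abs(fwd$calls$ref_start - rev$calls$qry_start), 21)
  })
})

test_that("no structural call is shorter than the minimum SV length", {
  withr::with_seed(49, {
    cfg <- sim_config(seed = 49, genome_length = 1e5, n_ancestral_te = 8,
                      n_te_ins = 3, n_ins = 3, n_del = 3, n_dup = 2,
                      n_dup_spacer = 1, n_inv = 2)
    anc <- simulate_ancestral_genome(cfg)
    der <- apply_variants(anc, cfg)
    ct <- sv_call(anc$genome, der$genome, repeats_ref = anc$repeats,
                  repeats_qry = der$repeats)
    expect_true(all(ct$calls$length >= 100))
    expect_true(all(ct$small_variants$length < 100))
  })
})
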