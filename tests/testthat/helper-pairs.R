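# shared simulator for divergent-read-pair tests
sim_pair_records <- function(n_samples, carriers, seed = 99,
                             region = 50000L, unit = c(20000L, 23755L),
                             spacer = 1500L, coverage = 15) {
  withr::with_seed(seed, {
    ref_seq <- random_seq(region)
    u <- substr(ref_seq, unit[1] + 1, unit[2])
    sp <- random_seq(spacer)
    carrier_seq <- paste0(substr(ref_seq, 1, unit[1]), u, sp, u,
                          substr(ref_seq, unit[2] + 1, region))
    dup <- list(ref_start = unit[1], ref_end = unit[2], spacer_len = spacer)
    recs <- list(); meta <- list()
    for (i in seq_len(n_samples)) {
      carries <- i <= carriers
      g <- if (carries) c(chr = carrier_seq) else c(chr = ref_seq)
      pr <- simulate_paired_end_reads(g, coverage = coverage,
                                      seed = seed + i)
      rec <- project_pairs_to_reference(pr, dup = if (carries) dup,
                                        seed = seed + 500 + i)
      rec$sample_id <- sprintf("s%02d", i)
      recs[[i]] <- rec
      meta[[i]] <- tibble::tibble(sample_id = sprintf("s%02d", i),
                                  population = "popA",
                                  aligned_bp = 200 * nrow(pr))
    }
    list(records = dplyr::bind_rows(recs), samples = dplyr::bind_rows(meta),
         candidate = list(chrom = "chr", start = unit[1], end = unit[2]))
  })
}

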