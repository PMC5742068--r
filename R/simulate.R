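#' Simulation configuration
#'
#' Bundles every knob of the synthetic genome/variant/read generator.  The
#' defaults describe the desk-scale study condition used throughout the
#' package: a 500-kb repeat-bearing ancestral chromosome and a derived
#' chromosome carrying 20 transposable-element (TE) insertions, 10 other
#' insertions, 20 deletions, 10 tandem duplications (5 of them separated by
#' an LTR-fragment spacer, echoing the Cyp28d1 geometry), 5 inversions,
#' SNPs at 0.5% and small indels at 0.05%.  Long reads default to the
#' corrected-long-read regime: ~8-kb median length, 1% indel-dominant
#' error.  One seed fixes every stochastic choice.
#'
#' @param seed Integer seed; all randomness flows from it.
#' @param genome_length Background (non-TE) length of the ancestral
#'   chromosome in bp.
#' @param gc GC fraction of background sequence.
#' @param chrom_name Chromosome name.
#' @param n_ancestral_te Number of ancestral TE copies inserted into the
#'   background (present in both genomes).
#' @param te_divergence Per-base substitution divergence of ancestral TE
#'   copies from their family consensus.
#' @param n_te_ins,n_ins,n_del,n_dup,n_dup_spacer,n_inv Variant counts:
#'   derived-genome TE insertions, non-TE insertions, deletions, tandem
#'   duplications (of which `n_dup_spacer` carry a spacer), inversions.
#' @param ins_len,del_len,dup_len,spacer_len,inv_len Length ranges (bp).
#' @param snp_rate,small_indel_rate Per-base rates of SNPs and small
#'   (<100 bp) indels.
#' @param small_indel_len Small-indel length range (bp).
#' @param long_read_coverage,long_read_meanlog,long_read_sdlog,long_read_min
#'   Long-read coverage and log-normal length distribution (bp).
#' @param long_read_error Long-read total error rate.
#' @param error_mix Split of the error budget over insertion, deletion and
#'   substitution errors.
#' @param pe_coverage,insert_mu,insert_sd,pe_read_len Paired-end read
#'   parameters (bp).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       genome_length = 5e5,
                       gc = 0.42,
                       chrom_name = "chr_1",
                       n_ancestral_te = 40,
                       te_divergence = 0.08,
                       n_te_ins = 20,
                       n_ins = 10, ins_len = c(200, 800),
                       n_del = 20, del_len = c(200, 800),
                       n_dup = 10, dup_len = c(300, 3000),
                       n_dup_spacer = 5, spacer_len = c(200, 1500),
                       n_inv = 5, inv_len = c(500, 3000),
                       snp_rate = 0.005,
                       small_indel_rate = 5e-4, small_indel_len = c(1, 30),
                       long_read_coverage = 20,
                       long_read_meanlog = log(8000),
                       long_read_sdlog = 0.4,
                       long_read_min = 500,
                       long_read_error = 0.01,
                       error_mix = c(ins = 0.60, del = 0.25, sub = 0.15),
                       pe_coverage = 30, insert_mu = 400, insert_sd = 40,
                       pe_read_len = 100) {
  cfg <- as.list(environment())
  stopifnot(cfg$seed == as.integer(cfg$seed),
            cfg$genome_length > 0, cfg$gc > 0, cfg$gc < 1,
            all(unlist(cfg[grep("^n_", names(cfg))]) >= 0),
            cfg$snp_rate >= 0, cfg$small_indel_rate >= 0,
            abs(sum(cfg$error_mix) - 1) < 1e-6)
  structure(cfg, class = "sim_config")
}

# run expr under a deterministic RNG state, restoring the caller's state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

random_dna <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, TRUE, prob = p), collapse = "")
}

mutate_dna <- function(seq, rate) {
  if (rate <= 0 || nchar(seq) == 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  n_mut <- rbinom(1, length(chars), rate)
  if (n_mut == 0) return(seq)
  pos <- sample.int(length(chars), n_mut)
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}

# default TE library: six families, one LTR retrotransposon-like family
# whose 300-bp terminal repeat also donates duplication spacers
default_te_library <- function(gc) {
  lens <- c(ltr_fam = 5000, fam_b = 3000, fam_c = 1500, fam_d = 800,
            fam_e = 4000, fam_f = 1200)
  lib <- vapply(lens, function(L) random_dna(L, gc), character(1))
  # give the LTR family identical terminal repeats
  ltr <- substr(lib[["ltr_fam"]], 1, 300)
  lib[["ltr_fam"]] <- paste0(ltr, substr(lib[["ltr_fam"]], 301,
                                         lens[["ltr_fam"]] - 300), ltr)
  lib
}

#' Simulate a repeat-bearing ancestral genome
#'
#' Generates random background sequence at the requested GC and implants
#' mutated copies of a TE family library at recorded positions.  Returns
#' the genome, the repeat annotation (0-based half-open BED-style tibble)
#' and the TE consensus library.
#'
#' @param cfg A [sim_config()].
#' @return List with `genome` (named character), `repeats` (tibble:
#'   `seqname`, `start`, `end`, `label`), `te_library` (named character).
#' @export
simulate_ancestral_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    lib <- default_te_library(cfg$gc)
    if (sum(nchar(lib)) * cfg$n_ancestral_te / length(lib) >
        cfg$genome_length)
      stop("infeasible packing: TE bp exceeds genome length")
    bg <- random_dna(cfg$genome_length, cfg$gc)
    n_te <- cfg$n_ancestral_te
    repeats <- tibble(seqname = character(), start = integer(),
                      end = integer(), label = character())
    if (n_te > 0) {
      fam <- sample(names(lib), n_te, TRUE)
      # insertion points in background coordinates, well separated
      pts <- sort(sample(seq(2000L, cfg$genome_length - 2000L), n_te))
      while (any(diff(pts) < 300)) {
        pts <- sort(sample(seq(2000L, cfg$genome_length - 2000L), n_te))
      }
      copies <- vapply(fam, function(f) mutate_dna(lib[[f]],
                                                   cfg$te_divergence),
                       character(1))
      pieces <- character(0)
      cur <- 0L
      offset <- 0L
      starts <- integer(n_te)
      for (i in seq_len(n_te)) {
        pieces <- c(pieces, substr(bg, cur + 1L, pts[i]), copies[i])
        starts[i] <- pts[i] + offset
        offset <- offset + nchar(copies[i])
        cur <- pts[i]
      }
      pieces <- c(pieces, substr(bg, cur + 1L, cfg$genome_length))
      genome <- paste(pieces, collapse = "")
      repeats <- tibble(seqname = cfg$chrom_name, start = starts,
                        end = starts + nchar(copies), label = fam)
    } else {
      genome <- bg
    }
    list(genome = setNames(genome, cfg$chrom_name), repeats = repeats,
         te_library = lib)
  })
}

# sample `n` non-overlapping intervals of lengths `lens` avoiding
# `forbidden` (tibble start/end) with `clear` bp clearance; returns starts
place_intervals <- function(lens, glen, forbidden, clear = 300,
                            max_try = 10000) {
  occ <- forbidden
  starts <- integer(length(lens))
  for (i in seq_along(lens)) {
    ok <- FALSE
    for (t in seq_len(max_try)) {
      s <- sample.int(glen - lens[i] - 2000L, 1) + 1000L
      e <- s + lens[i]
      clash <- any(occ$start - clear < e & occ$end + clear > s)
      if (!clash) { ok <- TRUE; break }
    }
    if (!ok) stop("could not place variant intervals; genome too crowded")
    starts[i] <- s
    occ <- bind_rows(occ, tibble(start = s, end = e))
  }
  starts
}

#' Implant variants into an ancestral genome
#'
#' Draws variant positions and payloads per the configuration, applies them
#' and returns the derived genome together with an exact truth catalog in
#' both coordinate systems.  Structural variant footprints are placed in
#' unique (non-repeat) sequence with 300-bp mutual clearance; SNPs and
#' small indels are placed in unique sequence at least 50 bp from any other
#' event, so that every implanted variant is recoverable in principle.
#' Applying the truth records to the ancestral genome reproduces the
#' derived genome exactly ([apply_truth()]).
#'
#' @param ancestral Output of [simulate_ancestral_genome()], or a list with
#'   `genome`, `repeats`, `te_library`.
#' @param cfg A [sim_config()].
#' @return List with `genome` (derived, named character), `truth` (tibble),
#'   `repeats` (derived-coordinate repeat annotation including new TE
#'   copies and duplication spacers), `coord_map` (tibble of aligned
#'   segments for coordinate lifting).
#' @export
apply_variants <- function(ancestral, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  genome <- as_genome(ancestral$genome)
  chrom <- names(genome)[1]
  seq <- genome[[chrom]]
  glen <- nchar(seq)
  lib <- ancestral$te_library
  repeats <- ancestral$repeats

  with_seed(cfg$seed + 1L, {
    rint <- function(rng, n) if (n == 0) integer(0) else
      sample(seq(rng[1], rng[2]), n, TRUE)

    sv <- bind_rows(
      tibble(class = "te_insertion",
             len = 0L,
             payload = if (cfg$n_te_ins > 0)
               vapply(sample(names(lib), cfg$n_te_ins, TRUE),
                      function(f) mutate_dna(lib[[f]], 0.02), character(1))
             else character(0)),
      tibble(class = "insertion", len = 0L,
             payload = vapply(rint(cfg$ins_len, cfg$n_ins),
                              function(L) random_dna(L, cfg$gc), character(1))),
      tibble(class = "deletion", len = rint(cfg$del_len, cfg$n_del),
             payload = NA_character_),
      tibble(class = "duplication", len = rint(cfg$dup_len, cfg$n_dup),
             payload = NA_character_),
      tibble(class = "inversion", len = rint(cfg$inv_len, cfg$n_inv),
             payload = NA_character_)
    )
    if (nrow(sv) > 0) {
      # duplication spacers: 5' LTR fragment of the LTR family
      is_dup <- which(sv$class == "duplication")
      spacered <- head(is_dup, cfg$n_dup_spacer)
      sv$spacer <- NA_character_
      if (length(spacered) > 0) {
        sp_len <- rint(cfg$spacer_len, length(spacered))
        sv$spacer[spacered] <- vapply(sp_len, function(L) {
          mutate_dna(substr(lib[["ltr_fam"]], 1, L), 0.02)
        }, character(1))
      }
      foot <- ifelse(sv$class %in% c("te_insertion", "insertion"), 1L, sv$len)
      forb <- bind_rows(tibble(start = repeats$start, end = repeats$end))
      starts <- place_intervals(foot, glen, forb, clear = 300)
      sv$anc_start <- starts
      sv$anc_end <- starts + ifelse(sv$class %in% c("te_insertion",
                                                    "insertion"), 0L, sv$len)
    } else {
      sv$spacer <- character(0)
      sv$anc_start <- integer(0)
      sv$anc_end <- integer(0)
    }

    # SNPs and small indels in unique sequence, clear of everything else
    n_snp <- rbinom(1, glen, cfg$snp_rate)
    n_sid <- rbinom(1, glen, cfg$small_indel_rate)
    occupied <- bind_rows(
      tibble(start = repeats$start, end = repeats$end),
      tibble(start = sv$anc_start, end = sv$anc_end)
    )
    # small indels break anchor chains, so they need enough exact context
    # around them to re-anchor (>= the cluster length threshold); SNPs do
    # not break chains and only need modest spacing
    pick_positions <- function(n, clear, from) {
      if (n == 0) return(integer(0))
      cand <- sort(unique(sample.int(glen - 2000L, n * 6, TRUE) + 1000L))
      ok <- !purrr::map_lgl(cand, function(p) {
        any(from$start - clear < p + 35 & from$end + clear > p)
      })
      cand <- cand[ok]
      for (pass in 1:2) cand <- cand[c(TRUE, diff(cand) >= clear)]
      if (length(cand) > n) sort(sample(cand, n)) else cand
    }
    sid_pos <- pick_positions(n_sid, 200, occupied)
    n_sid <- length(sid_pos)
    occupied2 <- bind_rows(occupied, tibble(start = sid_pos,
                                            end = sid_pos + 35L))
    snp_pos <- pick_positions(n_snp, 50, occupied2)
    n_snp <- length(snp_pos)
    small <- tibble(class = character(0), anc_start = integer(0),
                    anc_end = integer(0), payload = character(0))
    if (n_snp > 0) {
      p <- snp_pos
      small <- bind_rows(small, tibble(
        class = "snp", anc_start = p, anc_end = p + 1L,
        payload = vapply(p, function(i) {
          sample(setdiff(c("A", "C", "G", "T"), substr(seq, i + 1, i + 1)), 1)
        }, character(1))))
    }
    if (n_sid > 0) {
      p <- sid_pos
      is_ins <- runif(n_sid) < 0.5
      L <- rint(cfg$small_indel_len, n_sid)
      small <- bind_rows(small, tibble(
        class = ifelse(is_ins, "small_insertion", "small_deletion"),
        anc_start = p,
        anc_end = ifelse(is_ins, p, p + L),
        payload = ifelse(is_ins,
                         vapply(L, function(x) random_dna(x, cfg$gc),
                                character(1)),
                         NA_character_)))
    }

    truth <- bind_rows(
      select(sv, "class", "anc_start", "anc_end", "payload", "spacer"),
      mutate(small, spacer = NA_character_)
    ) |>
      mutate(chrom = chrom) |>
      arrange(.data$anc_start) |>
      select("chrom", "class", "anc_start", "anc_end", "payload", "spacer")

    applied <- apply_truth(genome, truth)
    derived_repeats <- lift_repeats(repeats, applied$truth, chrom)
    list(genome = applied$genome, truth = applied$truth,
         repeats = derived_repeats, coord_map = applied$coord_map)
  })
}

#' Apply truth records to a genome
#'
#' Deterministically replays a truth catalog against an (ancestral) genome,
#' returning the derived genome, the truth annotated with derived
#' coordinates, and a map of aligned segments between the two coordinate
#' systems.  This is the round-trip contract: the derived genome emitted by
#' [apply_variants()] equals `apply_truth(ancestral, truth)$genome` exactly.
#'
#' @param genome Named character vector (one chromosome per element).
#' @param truth Truth tibble (`chrom`, `class`, `anc_start`, `anc_end`,
#'   `payload`, `spacer`), 0-based half-open ancestral coordinates,
#'   non-overlapping.
#' @return List with `genome`, `truth` (plus `der_start`, `der_end`,
#'   `len`), and `coord_map` (`chrom`, `anc_start`, `anc_end`, `der_start`,
#'   `der_end`, `orientation`).
#' @export
apply_truth <- function(genome, truth) {
  genome <- as_genome(genome)
  out_genome <- genome
  truth$der_start <- NA_integer_
  truth$der_end <- NA_integer_
  maps <- list()
  for (chrom in names(genome)) {
    seqc <- genome[[chrom]]
    ev_idx <- which(truth$chrom == chrom)
    ev_idx <- ev_idx[order(truth$anc_start[ev_idx])]
    pieces <- character(0)
    segs <- list()
    cur <- 0L
    der <- 0L
    push_identity <- function(a0, a1, d0) {
      if (a1 > a0) segs[[length(segs) + 1]] <<-
          tibble(chrom = chrom, anc_start = a0, anc_end = a1,
                 der_start = d0, der_end = d0 + (a1 - a0),
                 orientation = "+")
    }
    for (i in ev_idx) {
      s <- truth$anc_start[i]; e <- truth$anc_end[i]
      stopifnot(s >= cur)
      pre <- substr(seqc, cur + 1L, s)
      push_identity(cur, s, der)
      pieces <- c(pieces, pre)
      der <- der + nchar(pre)
      cls <- truth$class[i]
      emitted <- switch(
        cls,
        snp = truth$payload[i],
        small_insertion = ,
        insertion = ,
        te_insertion = truth$payload[i],
        small_deletion = ,
        deletion = "",
        duplication = {
          unit <- substr(seqc, s + 1L, e)
          sp <- truth$spacer[i]
          paste0(unit, if (is.na(sp)) "" else sp, unit)
        },
        inversion = reverse_complement(substr(seqc, s + 1L, e)),
        stop("unknown truth class: ", cls)
      )
      if (cls == "snp")  # substitution keeps coordinates aligned
        segs[[length(segs) + 1]] <- tibble(
          chrom = chrom, anc_start = s, anc_end = e, der_start = der,
          der_end = der + 1L, orientation = "+")
      if (cls == "inversion")
        segs[[length(segs) + 1]] <- tibble(
          chrom = chrom, anc_start = s, anc_end = e, der_start = der,
          der_end = der + (e - s), orientation = "-")
      truth$der_start[i] <- der
      truth$der_end[i] <- der + nchar(emitted)
      pieces <- c(pieces, emitted)
      der <- der + nchar(emitted)
      cur <- e
    }
    push_identity(cur, nchar(seqc), der)
    pieces <- c(pieces, substr(seqc, cur + 1L, nchar(seqc)))
    out_genome[[chrom]] <- paste(pieces, collapse = "")
    maps <- c(maps, segs)
  }
  truth$len <- pmax(truth$anc_end - truth$anc_start,
                    truth$der_end - truth$der_start)
  list(genome = out_genome, truth = truth, coord_map = bind_rows(maps))
}

# lift ancestral repeat intervals to derived coordinates and add the new
# TE copies / duplication spacers created by the variants
lift_repeats <- function(repeats, truth, chrom) {
  cmap <- NULL # identity segments are reconstructable from truth offsets
  shift_at <- function(pos) {
    prior <- truth[truth$anc_end <= pos, ]
    sum(prior$der_end - prior$der_start) - sum(prior$anc_end - prior$anc_start)
  }
  out <- repeats
  if (nrow(out) > 0) {
    out$start <- out$start + vapply(out$start, shift_at, numeric(1))
    out$end <- out$end + vapply(out$end, shift_at, numeric(1))
  }
  te <- truth[truth$class == "te_insertion", ]
  if (nrow(te) > 0)
    out <- bind_rows(out, tibble(seqname = chrom, start = te$der_start,
                                 end = te$der_end, label = "te_insertion"))
  dup <- truth[truth$class == "duplication" & !is.na(truth$spacer), ]
  if (nrow(dup) > 0) {
    unit <- dup$anc_end - dup$anc_start
    out <- bind_rows(out, tibble(
      seqname = chrom,
      start = dup$der_start + unit,
      end = dup$der_end - unit,
      label = "ltr_spacer"))
  }
  arrange(out, .data$start)
}

#' Map positions between ancestral and derived coordinates
#'
#' @param coord_map Segment map from [apply_truth()].
#' @param pos Positions (0-based).
#' @param chrom Chromosome name.
#' @param from `"ancestral"` or `"derived"`.
#' @return Integer positions in the other coordinate system (`NA` where the
#'   position falls in sequence absent from the other genome).
#' @export
map_coords <- function(coord_map, pos, chrom, from = c("ancestral", "derived")) {
  from <- match.arg(from)
  m <- coord_map[coord_map$chrom == chrom, ]
  if (from == "ancestral") {
    a0 <- m$anc_start; a1 <- m$anc_end; b0 <- m$der_start; b1 <- m$der_end
  } else {
    a0 <- m$der_start; a1 <- m$der_end; b0 <- m$anc_start; b1 <- m$anc_end
  }
  vapply(pos, function(p) {
    i <- which(a0 <= p & p < a1)
    if (length(i) == 0) return(NA_integer_)
    i <- i[1]
    if (m$orientation[i] == "+") as.integer(b0[i] + (p - a0[i]))
    else as.integer(b1[i] - 1L - (p - a0[i]))
  }, integer(1))
}
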