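#' Simulate error-bearing long reads
#'
#' Draws read substrings from the genome at the configured coverage with a
#' log-normal length distribution and applies indel-dominant errors (the
#' corrected-long-read regime).  The true source interval and strand are
#' recorded in each read name as `id|chrom|start|end|strand` (0-based
#' half-open, forward-strand coordinates).
#'
#' @param genome Named character vector / FASTA path / `DNAStringSet`.
#' @param coverage Target mean coverage.
#' @param meanlog,sdlog,min_len Log-normal read-length parameters (bp).
#' @param error_rate Total per-base error rate.
#' @param error_mix Named fractions `ins`, `del`, `sub` summing to 1.
#' @param seed Integer seed.
#' @return Tibble with `name`, `seq`, `chrom`, `start`, `end`, `strand`.
#' @export
simulate_long_reads <- function(genome, coverage = 20, meanlog = log(8000),
                                sdlog = 0.4, min_len = 500,
                                error_rate = 0.01,
                                error_mix = c(ins = 0.60, del = 0.25,
                                              sub = 0.15),
                                seed = 1) {
  stopifnot(coverage > 0)
  genome <- as_genome(genome)
  with_seed(seed, {
    glens <- nchar(genome)
    total_bp <- coverage * sum(glens)
    mean_len <- exp(meanlog + sdlog^2 / 2)
    n_reads <- max(1L, round(total_bp / mean_len))
    lens <- pmax(min_len, round(stats::rlnorm(n_reads, meanlog, sdlog)))
    chroms <- sample(names(genome), n_reads, TRUE, prob = glens / sum(glens))
    lens <- pmin(lens, glens[chroms])
    starts <- vapply(seq_len(n_reads), function(i) {
      sample.int(glens[[chroms[i]]] - lens[i] + 1L, 1) - 1L
    }, integer(1))
    strands <- sample(c("+", "-"), n_reads, TRUE)
    seqs <- substring(genome[chroms], starts + 1L, starts + lens)
    flip <- strands == "-"
    seqs[flip] <- reverse_complement(seqs[flip])
    seqs <- vapply(seqs, apply_read_errors, character(1),
                   error_rate = error_rate, error_mix = error_mix,
                   USE.NAMES = FALSE)
    tibble(
      name = sprintf("rd%06d|%s|%d|%d|%s", seq_len(n_reads), chroms,
                     starts, starts + lens, strands),
      seq = seqs, chrom = chroms, start = as.integer(starts),
      end = as.integer(starts + lens), strand = strands
    )
  })
}

apply_read_errors <- function(seq, error_rate, error_mix) {
  if (error_rate <= 0) return(seq)
  n <- nchar(seq)
  n_err <- rbinom(1, n, error_rate)
  if (n_err == 0) return(seq)
  pos <- sort(sample.int(n, n_err))  # 1-based error sites, left to right
  kind <- sample(names(error_mix), n_err, TRUE, prob = error_mix)
  bases <- c("A", "C", "G", "T")
  pieces <- character(2 * n_err + 1)
  cur <- 1L
  for (i in seq_len(n_err)) {
    p <- pos[i]
    pieces[2 * i - 1] <- substr(seq, cur, p - 1L)
    pieces[2 * i] <- switch(kind[i],
      sub = sample(setdiff(bases, substr(seq, p, p)), 1),
      ins = paste0(substr(seq, p, p), sample(bases, 1)),
      del = ""
    )
    cur <- p + 1L
  }
  pieces[2 * n_err + 1] <- substr(seq, cur, n)
  paste(pieces, collapse = "")
}

#' Simulate paired-end reads
#'
#' Proper-orientation (forward/reverse) pairs with normally distributed
#' insert sizes.  True fragment coordinates are recorded in the pair name.
#'
#' @param genome Genome (see [as_genome()]).
#' @param coverage Target sequence coverage (both mates combined).
#' @param insert_mu,insert_sd Insert-size mean and standard deviation (bp);
#'   `insert_mu` must exceed twice the read length.
#' @param read_len Read length (bp).
#' @param error_rate Per-base substitution error rate.
#' @param seed Integer seed.
#' @return Tibble with `name`, `chrom`, `frag_start`, `frag_end`, `insert`,
#'   `seq1`, `seq2`.
#' @export
simulate_paired_end_reads <- function(genome, coverage = 30, insert_mu = 400,
                                      insert_sd = 40, read_len = 100,
                                      error_rate = 0.001, seed = 1) {
  stopifnot(insert_mu > 2 * read_len)
  genome <- as_genome(genome)
  with_seed(seed, {
    glens <- nchar(genome)
    n_pairs <- max(1L, round(coverage * sum(glens) / (2 * read_len)))
    chroms <- sample(names(genome), n_pairs, TRUE, prob = glens / sum(glens))
    ins <- pmax(2 * read_len + 10,
                round(rnorm(n_pairs, insert_mu, insert_sd)))
    ins <- pmin(ins, glens[chroms])
    starts <- vapply(seq_len(n_pairs), function(i) {
      sample.int(glens[[chroms[i]]] - ins[i] + 1L, 1) - 1L
    }, integer(1))
    s1 <- substring(genome[chroms], starts + 1L, starts + read_len)
    s2 <- reverse_complement(substring(genome[chroms], starts + ins - read_len + 1L,
                                       starts + ins))
    if (error_rate > 0) {
      s1 <- vapply(s1, mutate_dna, character(1), rate = error_rate,
                   USE.NAMES = FALSE)
      s2 <- vapply(s2, mutate_dna, character(1), rate = error_rate,
                   USE.NAMES = FALSE)
    }
    tibble(
      name = sprintf("pr%06d|%s|%d|%d", seq_len(n_pairs), chroms, starts,
                     starts + ins),
      chrom = chroms, frag_start = as.integer(starts),
      frag_end = as.integer(starts + ins), insert = as.integer(ins),
      seq1 = s1, seq2 = s2
    )
  })
}

#' Write reads to FASTQ
#'
#' @param reads Tibble with `name` and `seq` (long reads), or `seq1`/`seq2`
#'   columns (pairs; use `mate`).
#' @param path Output path.
#' @param mate For paired tibbles, which mate to write (1 or 2).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, mate = NULL) {
  if (!is.null(mate)) {
    seqs <- reads[[paste0("seq", mate)]]
    names <- paste0(reads$name, "/", mate)
  } else {
    seqs <- reads$seq
    names <- reads$name
  }
  qual <- vapply(nchar(seqs), function(n) strrep("I", n), character(1))
  readr::write_lines(as.vector(rbind(paste0("@", names), seqs, "+", qual)),
                     path)
  invisible(path)
}

#' Project simulated read pairs onto a reference carrying one copy of a
#' tandem duplication
#'
#' Emulates the proper-pair flagging of a short-read aligner for pairs
#' drawn from a donor genome that may carry a tandem duplication absent
#' from the reference.  Both duplicate copies map onto the single reference
#' unit; pairs straddling the copy-copy junction (or anchored in a spacer
#' that does not exist in the reference) become divergently mapped.  A
#' small chimera rate marks random pairs divergent as background noise.
#'
#' @param pairs Tibble from [simulate_paired_end_reads()] (donor
#'   coordinates).
#' @param dup `NULL` for a non-carrier donor, otherwise a list with
#'   `ref_start`, `ref_end` (unit interval on the reference, 0-based
#'   half-open) and `spacer_len` (donor-genome spacer between the copies).
#' @param read_len Read length used for the pairs.
#' @param chimera_rate Background rate of randomly divergent pairs.
#' @param seed Integer seed for the background noise.
#' @return Tibble of pair-orientation records: `name`, `chrom`, `pos1`,
#'   `strand1`, `pos2`, `strand2`, `proper`.
#' @export
project_pairs_to_reference <- function(pairs, dup = NULL, read_len = 100,
                                       chimera_rate = 0.005, seed = 1) {
  n <- nrow(pairs)
  pos1 <- pairs$frag_start
  pos2 <- pairs$frag_end - read_len
  proper <- rep(TRUE, n)
  if (!is.null(dup)) {
    s <- dup$ref_start; e <- dup$ref_end
    L <- e - s; sp <- dup$spacer_len
    # donor layout: [0,s) identity | copy1 [s,s+L) | spacer | copy2 | tail
    map1 <- function(p) { # map a donor read start; NA when not contiguous
      if (p + read_len <= s) return(p)
      if (p >= s && p + read_len <= s + L) return(p)                # copy1
      if (p >= s + L + sp && p + read_len <= s + 2 * L + sp)
        return(p - L - sp)                                          # copy2
      if (p >= s + 2 * L + sp) return(p - L - sp)                   # tail
      NA_integer_ # crosses a junction or sits in the spacer
    }
    pos1 <- vapply(pairs$frag_start, map1, numeric(1))
    pos2 <- vapply(pairs$frag_end - read_len, map1, numeric(1))
    ins_ref <- pos2 + read_len - pos1
    proper <- !is.na(pos1) & !is.na(pos2) & ins_ref > 0 & ins_ref < 2000
    # divergent pairs anchor at the junction: place unmapped mates there
    pos1[is.na(pos1)] <- e - read_len
    pos2[is.na(pos2)] <- s
  }
  out <- tibble(
    name = pairs$name, chrom = pairs$chrom,
    pos1 = as.integer(pos1), strand1 = "+",
    pos2 = as.integer(pos2), strand2 = "-",
    proper = proper
  )
  if (chimera_rate > 0) {
    with_seed(seed, {
      noise <- runif(n) < chimera_rate
      out$proper[noise] <- FALSE
    })
  }
  out
}
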