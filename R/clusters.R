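#' Chain maximal exact matches into collinear clusters
#'
#' Matches are grouped per (reference sequence, query sequence, strand) and
#' chained by dynamic programming into collinear clusters that maximise
#' total matched length.  Two consecutive matches may be chained when their
#' separation `max(ref_gap, qry_gap)` is at most `s` and their diagonal
#' drift `|ref_gap - qry_gap|` is at most `f * separation`.  Matches may
#' overlap a chain neighbour by at most `max_overlap` bp (tandem-duplication
#' copies therefore stay in separate clusters).  Chains whose total matched
#' length falls below `l` are discarded.
#'
#' @param matches Match tibble from [find_mems()].
#' @param s Maximum separation between consecutive matches (bp).
#' @param f Maximum diagonal drift as a fraction of the separation.
#' @param l Minimum total matched length of a cluster (bp).
#' @param max_overlap Maximum overlap between chained matches (bp).
#' @return Tibble with one row per cluster: coordinates on both genomes
#'   (query coordinates both strand-local and forward), `n_matches`,
#'   `total_match_len` and a `matches` list-column holding the member
#'   matches unchanged.
#' @export
cluster_matches <- function(matches, s = 200, f = 0.12, l = 100,
                            max_overlap = 20) {
  empty <- tibble(
    cluster_id = integer(), ref_name = character(), qry_name = character(),
    strand = character(), ref_start = integer(), ref_end = integer(),
    qry_start = integer(), qry_end = integer(),
    qry_fwd_start = integer(), qry_fwd_end = integer(), qry_len = integer(),
    n_matches = integer(), total_match_len = numeric(), matches = list()
  )
  if (is.null(matches) || nrow(matches) == 0) return(empty)

  grouped <- matches |>
    arrange(.data$ref_name, .data$qry_name, .data$strand,
            .data$ref_start, .data$qry_start) |>
    group_by(.data$ref_name, .data$qry_name, .data$strand)

  keys <- group_keys(grouped)
  parts <- group_split(grouped)
  out <- vector("list", length(parts))
  for (g in seq_along(parts)) {
    m <- parts[[g]]
    cid <- .chain_matches_cpp(m$ref_start, m$qry_start, m$length,
                              s, f, as.integer(max_overlap), l)
    keep <- cid > 0
    if (!any(keep)) next
    m <- m[keep, , drop = FALSE]
    m$.cid <- cid[keep]
    out[[g]] <- m |>
      group_by(.data$.cid) |>
      summarise(
        matches = list(pick("ref_start", "qry_start", "length")),
        ref_name = first(.data$ref_name),
        qry_name = first(.data$qry_name),
        strand = first(.data$strand),
        ref_end = max(.data$ref_start + .data$length),
        ref_start = min(.data$ref_start),
        qry_end = max(.data$qry_start + .data$length),
        qry_start = min(.data$qry_start),
        qry_len = first(.data$qry_len),
        n_matches = n(),
        total_match_len = sum(.data$length),
        .groups = "drop"
      ) |>
      select(-".cid")
  }
  res <- bind_rows(out)
  if (is.null(res) || nrow(res) == 0) return(empty)
  res <- select(res, "ref_name", "qry_name", "strand", "ref_start", "ref_end",
                "qry_start", "qry_end", "qry_len", "n_matches",
                "total_match_len", "matches")
  fwd <- strand_to_forward(res$qry_start, res$qry_end, res$strand, res$qry_len)
  res$qry_fwd_start <- fwd$start
  res$qry_fwd_end <- fwd$end
  res <- arrange(res, .data$ref_name, .data$ref_start, .data$qry_name,
                 .data$qry_start)
  res$cluster_id <- seq_len(nrow(res))
  select(res, "cluster_id", everything())
}
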