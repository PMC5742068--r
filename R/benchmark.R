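#' Score structural calls against a simulation truth catalog
#'
#' Matches calls to truth records per variant class at a breakpoint
#' tolerance and reports recall and precision.  Class mapping: TE
#' insertions and other insertions are `INS_QRY` calls split by TE status;
#' deletions are `DEL_QRY`; tandem duplications are `CNV_GAIN_QRY` (matched
#' on the duplicated reference unit); inversions are `INV`.
#'
#' @param catalog An `sv_catalog` (or its `calls` tibble).
#' @param truth Truth tibble from [apply_variants()] (ancestral = reference
#'   genome, derived = query genome).
#' @param tol Breakpoint tolerance (bp).
#' @return Tibble: `class`, `n_truth`, `n_calls`, `n_matched_truth`,
#'   `n_matched_calls`, `recall`, `precision`.
#' @export
score_sv_calls <- function(catalog, truth, tol = 20) {
  calls <- if (inherits(catalog, "sv_catalog")) catalog$calls else catalog
  specs <- list(
    te_insertion = list(truth_class = "te_insertion",
                        call_filter = function(d)
                          d$sv_type == "INS_QRY" & d$te_status == "TE",
                        point = TRUE),
    insertion = list(truth_class = "insertion",
                     call_filter = function(d)
                       d$sv_type == "INS_QRY" & d$te_status != "TE",
                     point = TRUE),
    deletion = list(truth_class = "deletion",
                    call_filter = function(d) d$sv_type == "DEL_QRY",
                    point = FALSE),
    duplication = list(truth_class = "duplication",
                       call_filter = function(d) d$sv_type == "CNV_GAIN_QRY",
                       point = FALSE),
    inversion = list(truth_class = "inversion",
                     call_filter = function(d) d$sv_type == "INV",
                     point = FALSE)
  )
  purrr::map_dfr(names(specs), function(cls) {
    sp <- specs[[cls]]
    tt <- truth[truth$class == sp$truth_class, , drop = FALSE]
    cc <- calls[sp$call_filter(calls), , drop = FALSE]
    matched_t <- logical(nrow(tt))
    matched_c <- logical(nrow(cc))
    for (i in seq_len(nrow(tt))) {
      for (j in seq_len(nrow(cc))) {
        hit <- if (sp$point) {
          abs(cc$ref_start[j] - tt$anc_start[i]) <= tol &&
            abs(cc$length[j] - tt$len[i]) <= max(tol, 0.1 * tt$len[i])
        } else {
          abs(cc$ref_start[j] - tt$anc_start[i]) <= tol &&
            abs(cc$ref_end[j] - tt$anc_end[i]) <= tol
        }
        if (hit) { matched_t[i] <- TRUE; matched_c[j] <- TRUE }
      }
    }
    tibble(class = cls, n_truth = nrow(tt), n_calls = nrow(cc),
           n_matched_truth = sum(matched_t),
           n_matched_calls = sum(matched_c),
           recall = ifelse(nrow(tt) > 0, sum(matched_t) / nrow(tt), NA_real_),
           precision = ifelse(nrow(cc) > 0, sum(matched_c) / nrow(cc),
                              NA_real_))
  })
}

#' Score SNP and small-indel calls against simulation truth
#'
#' Truth indels are left-aligned against the ancestral sequence with the
#' same normalisation as the caller, then positions and alleles are
#' compared exactly.  Truth records inside or within `margin` bp of repeat
#' annotation are excluded: anchoring is not expected to resolve variants
#' that close to repeats, and the exactness contract applies to unique
#' sequence.
#'
#' @param small Small-variant tibble from [call_snps_small_indels()].
#' @param truth Truth tibble.
#' @param ancestral Ancestral (reference) genome.
#' @param repeats Ancestral repeat annotation (or `NULL`).
#' @param margin Exclusion margin around repeats (bp).
#' @return List: `n_truth`, `n_calls`, `false_negatives`,
#'   `false_positives`, and the unmatched records.
#' @export
score_small_variants <- function(small, truth, ancestral, repeats = NULL,
                                 margin = 50) {
  ancestral <- as_genome(ancestral)
  tt <- truth[truth$class %in% c("snp", "small_insertion", "small_deletion"), ]
  if (!is.null(repeats) && nrow(tt) > 0) {
    ann <- read_annotation(repeats)
    near_rep <- vapply(seq_len(nrow(tt)), function(i) {
      any(ann$seqname == tt$chrom[i] & ann$start - margin < tt$anc_end[i] &
            ann$end + margin > tt$anc_start[i])
    }, logical(1))
    tt <- tt[!near_rep, , drop = FALSE]
  }
  # canonical keys for truth records
  tkey <- vapply(seq_len(nrow(tt)), function(i) {
    seqc <- ancestral[[tt$chrom[i]]]
    switch(tt$class[i],
      snp = paste("SNP", tt$chrom[i], tt$anc_start[i],
                  substr(seqc, tt$anc_start[i] + 1, tt$anc_start[i] + 1),
                  tt$payload[i]),
      small_insertion = {
        la <- left_align_insertion(seqc, tt$anc_start[i], tt$payload[i])
        paste("INS", tt$chrom[i], la$pos, "", la$allele)
      },
      small_deletion = {
        la <- left_align_deletion(seqc, tt$anc_start[i],
                                  tt$anc_end[i] - tt$anc_start[i])
        paste("DEL", tt$chrom[i], la$pos, la$allele, "")
      })
  }, character(1))
  ckey <- if (nrow(small) > 0) {
    paste(small$kind, small$ref_name, small$ref_pos, small$ref_allele,
          small$qry_allele)
  } else character(0)
  fn <- setdiff(tkey, ckey)
  fp <- setdiff(ckey, tkey)
  list(n_truth = nrow(tt), n_calls = length(ckey),
       false_negatives = length(fn), false_positives = length(fp),
       fn_keys = fn, fp_keys = fp)
}
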