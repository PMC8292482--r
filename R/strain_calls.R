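# Per-strain best-call summaries.
#
# For each strain the "best call" is the genotype of the maximum-GQ
# non-missing platform call; GQ ties are broken by a fixed platform
# priority (ILLUMINA > LINKEDREAD > IONTORRENT). A non-missing call with
# absent GQ ranks at quality 0 (it can still be the best call when no
# other platform calls the site).

strain_matrices <- function(variants, strain, field) {
  cols <- paste0(field, "_", sample_id(strain, PLATFORMS))
  sapply(cols, function(cl) variants[[cl]], simplify = "array")
}

#' Append per-strain best-call summary columns
#'
#' Adds, for each strain `S` in `WLI`/`WMI`: `best_gt_S`, `best_gq_S`,
#' `concordant_S` (all three platform calls non-missing and identical),
#' `n_missing_S`, and `disputed_q30_S` (another platform of the same strain
#' makes a different non-missing call with GQ at or above `cfg$q_high`).
#'
#' @param variants A `joint_variants` tibble.
#' @param cfg A [filter_config()].
#' @return `variants` with the summary columns appended (recomputed if
#'   already present).
#' @export
best_call_per_strain <- function(variants, cfg = filter_config()) {
  n <- nrow(variants)
  for (strain in STRAINS) {
    if (n == 0) {
      variants[[paste0("best_gt_", strain)]] <- character(0)
      variants[[paste0("best_gq_", strain)]] <- integer(0)
      variants[[paste0("concordant_", strain)]] <- logical(0)
      variants[[paste0("n_missing_", strain)]] <- integer(0)
      variants[[paste0("disputed_q30_", strain)]] <- logical(0)
      next
    }
    gt <- matrix(strain_matrices(variants, strain, "gt"), nrow = n)
    gq <- matrix(strain_matrices(variants, strain, "gq"), nrow = n)
    missing <- matrix(gt_is_missing(gt), nrow = n)
    rank_gq <- ifelse(missing, -Inf, ifelse(is.na(gq), 0, gq))
    best_idx <- max.col(rank_gq, ties.method = "first")
    all_missing <- rowSums(!missing) == 0
    pick <- cbind(seq_len(n), best_idx)
    best_gt <- gt[pick]
    best_gt[all_missing] <- "./."
    best_gq <- as.integer(gq[pick])
    best_gq[all_missing] <- NA_integer_
    concordant <- rowSums(missing) == 0 &
      gt[, 1] == gt[, 2] & gt[, 2] == gt[, 3]
    gq0 <- ifelse(is.na(gq), 0, gq)
    disputed <- rowSums(!missing & gt != best_gt & gq0 >= cfg$q_high) > 0
    disputed[all_missing] <- FALSE

    variants[[paste0("best_gt_", strain)]] <- best_gt
    variants[[paste0("best_gq_", strain)]] <- best_gq
    variants[[paste0("concordant_", strain)]] <- concordant
    variants[[paste0("n_missing_", strain)]] <- as.integer(rowSums(missing))
    variants[[paste0("disputed_q30_", strain)]] <- as.logical(disputed)
  }
  variants
}

#' Long-format strain call summaries
#'
#' One row per variant x strain, mirroring the per-strain summary used by
#' the cascade (best call, best quality, concordance, missing count,
#' Q30 dispute flag).
#'
#' @inheritParams best_call_per_strain
#' @return A tibble with columns `chrom`, `pos`, `strain`, `best_gt`,
#'   `best_gq`, `concordant`, `n_missing`, `disputed_q30`.
#' @export
strain_call_summary <- function(variants, cfg = filter_config()) {
  variants <- best_call_per_strain(variants, cfg)
  bind_rows(lapply(STRAINS, function(strain) {
    tibble(
      chrom = variants$chrom,
      pos = variants$pos,
      strain = strain,
      best_gt = variants[[paste0("best_gt_", strain)]],
      best_gq = variants[[paste0("best_gq_", strain)]],
      concordant = variants[[paste0("concordant_", strain)]],
      n_missing = variants[[paste0("n_missing_", strain)]],
      disputed_q30 = variants[[paste0("disputed_q30_", strain)]]
    )
  }))
}

#' Flag within-strain cross-technology concordance
#'
#' Non-destructive: marks variants whose three platform calls agree
#' (non-missing, identical) in at least one strain. These records are the
#' "stored for further analysis" side channel of the cascade; nothing is
#' removed here.
#'
#' @inheritParams best_call_per_strain
#' @return `variants` with `concordant_WLI`, `concordant_WMI` and a
#'   combined `stored` flag.
#' @export
flag_within_strain_concordance <- function(variants, cfg = filter_config()) {
  variants <- best_call_per_strain(variants, cfg)
  variants$stored <- variants$concordant_WLI | variants$concordant_WMI
  variants
}
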