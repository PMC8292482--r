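# The individual filter steps of the consensus cascade.
#
# Every step takes a joint_variants tibble plus a filter_config and
# returns list(kept = ..., removed = ...); the two tibbles partition the
# input rows. Steps that depend on per-strain best calls recompute the
# summary columns via best_call_per_strain(), so they can be called in
# isolation.

step_result <- function(variants, removed_mask) {
  list(kept = variants[!removed_mask, , drop = FALSE],
       removed = variants[removed_mask, , drop = FALSE])
}

#' Depth bounds: too little total or too much single-sample coverage
#'
#' Removes sites whose summed read depth over the six samples is below
#' `cfg$min_total_depth`, or where any single sample exceeds
#' `cfg$max_single_depth`. Absent depth counts as 0 (after the AD-sum
#' fallback).
#'
#' @param variants A `joint_variants` tibble.
#' @param cfg A [filter_config()].
#' @return `list(kept, removed)`.
#' @export
step_depth <- function(variants, cfg = filter_config()) {
  depth <- effective_depth(variants)
  max_single <- do.call(pmax, as.data.frame(depth))
  if (length(max_single) == 0) max_single <- integer(0)
  removed <- rowSums(depth) < cfg$min_total_depth |
    max_single > cfg$max_single_depth
  step_result(variants, removed)
}

#' Equal best calls in both strains
#'
#' Removes sites where the two strains' best calls are the same
#' allele-resolved genotype and both are non-missing: such sites are
#' shared relative to the reference, not strain differences.
#'
#' @inheritParams step_depth
#' @return `list(kept, removed)`.
#' @export
step_equal_best <- function(variants, cfg = filter_config()) {
  variants <- best_call_per_strain(variants, cfg)
  removed <- !gt_is_missing(variants$best_gt_WLI) &
    !gt_is_missing(variants$best_gt_WMI) &
    variants$best_gt_WLI == variants$best_gt_WMI
  step_result(variants, removed)
}

#' Mostly-uncertain sites
#'
#' Removes sites with at least `cfg$max_uncertain` missing (`./.`)
#' genotypes out of six.
#'
#' @inheritParams step_depth
#' @return `list(kept, removed)`.
#' @export
step_uncertain <- function(variants, cfg = filter_config()) {
  variants <- best_call_per_strain(variants, cfg)
  n_missing <- variants$n_missing_WLI + variants$n_missing_WMI
  step_result(variants, n_missing >= cfg$max_uncertain)
}

#' Five identical calls opposed only by one low-quality call
#'
#' Removes sites where exactly five non-missing calls share one genotype
#' and the sixth is non-missing, different, and has GQ below `cfg$q_low`:
#' the lone discordant call is too weak to represent a real difference.
#'
#' @inheritParams step_depth
#' @return `list(kept, removed)`.
#' @export
step_low_quality_discordant <- function(variants, cfg = filter_config()) {
  n <- nrow(variants)
  if (n == 0) return(step_result(variants, logical(0)))
  gt_all <- sapply(call_cols("gt"), function(cl) variants[[cl]])
  gq_all <- sapply(call_cols("gq"), function(cl) variants[[cl]])
  gt_all <- matrix(gt_all, nrow = n)
  gq_all <- matrix(gq_all, nrow = n)
  removed <- vapply(seq_len(n), function(i) {
    gts <- gt_all[i, ]
    if (any(gt_is_missing(gts))) return(FALSE)
    tab <- table(gts)
    if (length(tab) != 2 || max(tab) != 5) return(FALSE)
    odd <- which(gts == names(tab)[which.min(tab)])
    gq <- gq_all[i, odd]
    if (is.na(gq)) gq <- 0
    gq < cfg$q_low
  }, logical(1))
  step_result(variants, removed)
}

#' Pooled allele-balance: one allele dominates reads shared by both strains
#'
#' Pools the per-allele read support (AD) over all six samples. A site is
#' removed when one allele carries more than `cfg$allele_majority` of the
#' pooled reads and each strain contributes at least `cfg$strain_share` of
#' them: the variant is then effectively present in both strains and
#' cannot distinguish them. Sites with no AD evidence are never removed
#' here (depth handling is [step_depth()]'s job).
#'
#' @inheritParams step_depth
#' @return `list(kept, removed)`.
#' @export
step_allele_balance <- function(variants, cfg = filter_config()) {
  n <- nrow(variants)
  if (n == 0) return(step_result(variants, logical(0)))
  ad_cols <- call_cols("ad")
  wli_cols <- paste0("ad_", sample_id("WLI", PLATFORMS))
  removed <- vapply(seq_len(n), function(i) {
    ads <- lapply(ad_cols, function(cl) variants[[cl]][[i]])
    len <- max(c(1L, lengths(ads)))
    pooled <- rep(0, len)
    wli_reads <- 0
    for (j in seq_along(ads)) {
      a <- ads[[j]]
      if (length(a) == 0) next
      a[is.na(a)] <- 0
      pooled[seq_along(a)] <- pooled[seq_along(a)] + a
      if (ad_cols[j] %in% wli_cols) wli_reads <- wli_reads + sum(a)
    }
    total <- sum(pooled)
    if (total == 0) return(FALSE)
    wmi_reads <- total - wli_reads
    max(pooled) > cfg$allele_majority * total &&
      wli_reads >= cfg$strain_share * total &&
      wmi_reads >= cfg$strain_share * total
  }, logical(1))
  step_result(variants, removed)
}

#' High-quality within-strain dispute across platforms
#'
#' Removes sites where, within a strain whose best call is non-reference
#' (the strain carrying the putative difference), another platform makes a
#' different non-missing call with GQ at or above `cfg$q_high`.
#'
#' @inheritParams step_depth
#' @return `list(kept, removed)`.
#' @export
step_cross_platform_dispute <- function(variants, cfg = filter_config()) {
  variants <- best_call_per_strain(variants, cfg)
  removed <- rep(FALSE, nrow(variants))
  for (strain in STRAINS) {
    best <- variants[[paste0("best_gt_", strain)]]
    carries <- !gt_is_missing(best) & !gt_is_homref(best)
    removed <- removed |
      (carries & variants[[paste0("disputed_q30_", strain)]])
  }
  step_result(variants, removed)
}

#' Require a reference-anchored strain difference
#'
#' Keeps sites where the strains' best calls differ, neither is missing,
#' and exactly one strain is homozygous reference (0/0). The other strain
#' becomes the carrier; its best call sets the zygosity (`hom`/`het`).
#' Kept rows gain `carrier_strain`, `carrier_gt`, `carrier_gq` and
#' `zygosity` columns.
#'
#' @inheritParams step_depth
#' @return `list(kept, removed)`.
#' @export
step_require_difference <- function(variants, cfg = filter_config()) {
  variants <- best_call_per_strain(variants, cfg)
  wli <- variants$best_gt_WLI
  wmi <- variants$best_gt_WMI
  differ <- !gt_is_missing(wli) & !gt_is_missing(wmi) & wli != wmi
  one_ref <- xor(gt_is_homref(wli), gt_is_homref(wmi))
  keep <- differ & one_ref
  variants$carrier_strain <- ifelse(gt_is_homref(wli), "WMI", "WLI")
  variants$carrier_strain[!keep] <- NA_character_
  carrier_gt <- ifelse(variants$carrier_strain == "WMI", wmi, wli)
  variants$carrier_gt <- ifelse(keep, carrier_gt, NA_character_)
  variants$carrier_gq <- ifelse(variants$carrier_strain == "WMI",
                                variants$best_gq_WMI, variants$best_gq_WLI)
  variants$carrier_gq[!keep] <- NA_integer_
  variants$zygosity <- ifelse(keep, gt_zygosity(variants$carrier_gt), NA_character_)
  step_result(variants, !keep)
}

#' Final quality tier: one Q30 call, unopposed at Q10
#'
#' Applied after [step_require_difference()] (rows must carry
#' `carrier_strain`). Keeps sites where the carrier strain supports its
#' best call with GQ at or above `cfg$q_high` and no sample in either
#' strain makes a different non-missing call with GQ at or above
#' `cfg$q_low` — except the opposite strain's homozygous-reference calls,
#' which are the required other half of a strain difference, not
#' opposition.
#'
#' @inheritParams step_depth
#' @return `list(kept, removed)`.
#' @export
step_quality_tier <- function(variants, cfg = filter_config()) {
  n <- nrow(variants)
  if (n == 0) return(step_result(variants, logical(0)))
  if (!"carrier_strain" %in% names(variants)) {
    abort("step_quality_tier requires carrier assignment (run step_require_difference first)")
  }
  removed <- vapply(seq_len(n), function(i) {
    carrier <- variants$carrier_strain[i]
    carrier_gt <- variants$carrier_gt[i]
    carrier_gq <- variants$carrier_gq[i]
    if (is.na(carrier)) return(TRUE)
    if (is.na(carrier_gq) || carrier_gq < cfg$q_high) return(TRUE)
    opposite <- setdiff(STRAINS, carrier)
    for (strain in STRAINS) {
      for (platform in PLATFORMS) {
        key <- sample_id(strain, platform)
        gt <- variants[[paste0("gt_", key)]][i]
        if (gt_is_missing(gt) || gt == carrier_gt) next
        if (strain == opposite && gt_is_homref(gt)) next
        gq <- variants[[paste0("gq_", key)]][i]
        if (!is.na(gq) && gq >= cfg$q_low) return(TRUE)
      }
    }
    FALSE
  }, logical(1))
  step_result(variants, removed)
}

#' Unsupported deletions in homopolymer context
#'
#' Applied to carrier-assigned rows. Removes sites where the carrier's
#' called allele is a deletion lying entirely within a homopolymer run
#' ([homopolymer_context()]) and fewer than
#' `cfg$min_supporting_platforms` platforms of the carrier strain call
#' that deletion with GQ at or above `cfg$q_low` — the signature of a
#' single-platform homopolymer base-calling artifact.
#'
#' @inheritParams step_depth
#' @param ref A `DNAStringSet` reference (see [read_reference()]).
#' @return `list(kept, removed)`.
#' @export
step_homopolymer_deletions <- function(variants, ref, cfg = filter_config()) {
  n <- nrow(variants)
  if (n == 0) return(step_result(variants, logical(0)))
  if (!"carrier_strain" %in% names(variants)) {
    abort("step_homopolymer_deletions requires carrier assignment")
  }
  alts_list <- str_split(variants$alt, ",")
  removed <- vapply(seq_len(n), function(i) {
    carrier <- variants$carrier_strain[i]
    if (is.na(carrier)) return(FALSE)
    gt <- variants$carrier_gt[i]
    alt_idx <- gt_alt_indices(gt)[[1]]
    alts <- alts_list[[i]]
    ref_allele <- variants$ref[i]
    for (k in alt_idx) {
      alt_allele <- alts[k]
      is_del <- nchar(alt_allele) < nchar(ref_allele) &&
        substr(ref_allele, 1, nchar(alt_allele)) == alt_allele
      if (!is_del) next
      in_run <- homopolymer_context(ref, variants$chrom[i], variants$pos[i],
                                    ref_allele, alt_allele,
                                    min_run = cfg$homopolymer_min_run)
      if (!in_run) next
      support <- 0L
      for (platform in PLATFORMS) {
        key <- sample_id(carrier, platform)
        pgt <- variants[[paste0("gt_", key)]][i]
        if (gt_is_missing(pgt) || !(k %in% gt_alt_indices(pgt)[[1]])) next
        gq <- variants[[paste0("gq_", key)]][i]
        if (!is.na(gq) && gq >= cfg$q_low) support <- support + 1L
      }
      if (support < cfg$min_supporting_platforms) return(TRUE)
    }
    FALSE
  }, logical(1))
  step_result(variants, removed)
}
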