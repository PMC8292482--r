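# Builders for hand-crafted joint call sets and independent brute-force
# oracles used across the suite.

SAMPLE_KEYS <- as.vector(outer(c("WLI", "WMI"),
                               c("ILLUMINA", "LINKEDREAD", "IONTORRENT"),
                               function(s, p) paste(s, p, sep = "_")))

# One per-sample call. ad defaults follow the genotype: hom-ref (dp, 0),
# hom-alt (0, dp), het an even split, missing empty.
cs <- function(gt = "./.", gq = NA_integer_, dp = 0L, ad = NULL) {
  if (is.null(ad)) {
    ad <- if (gt == "./.") integer(0)
    else if (gt == "0/0") c(dp, 0L)
    else if (gt %in% c("1/1", "2/2")) c(0L, dp)
    else c(floor(dp / 2), ceiling(dp / 2))
  }
  list(gt = gt, gq = as.integer(gq), dp = as.integer(dp), ad = as.integer(ad))
}

# Build a one-row joint_variants tibble; unspecified samples are missing.
jv <- function(calls = list(), chrom = "1", pos = 100L, ref = "A", alt = "T",
               ann = NULL) {
  row <- tibble::tibble(chrom = chrom, pos = as.integer(pos),
                        ref = ref, alt = alt)
  if (!is.null(ann)) row$ann <- ann
  for (key in SAMPLE_KEYS) {
    call <- if (key %in% names(calls)) calls[[key]] else cs()
    row[[paste0("gt_", key)]] <- call$gt
    row[[paste0("gq_", key)]] <- call$gq
    row[[paste0("dp_", key)]] <- call$dp
    row[[paste0("ad_", key)]] <- list(call$ad)
  }
  row
}

jv_bind <- function(...) dplyr::bind_rows(...)

# A clean planted strain difference: carrier hom-alt on all platforms
# (one call >= Q31), opposite strain hom-ref.
jv_true_diff <- function(pos = 100L, carrier = "WLI", gq = c(45L, 20L, 15L),
                         ref = "A", alt = "T", zyg = "1/1") {
  opp <- setdiff(c("WLI", "WMI"), carrier)
  calls <- list()
  plats <- c("ILLUMINA", "LINKEDREAD", "IONTORRENT")
  for (i in 1:3) {
    calls[[paste(carrier, plats[i], sep = "_")]] <- cs(zyg, gq[i], 40L)
    calls[[paste(opp, plats[i], sep = "_")]] <- cs("0/0", 50L, 40L)
  }
  jv(calls, pos = pos, ref = ref, alt = alt)
}

# ---- independent oracles -------------------------------------------------

# Best call among three platforms given in priority order.
oracle_best_call <- function(gts, gqs) {
  stopifnot(length(gts) == 3, length(gqs) == 3)
  rank <- ifelse(gts == "./.", -Inf, ifelse(is.na(gqs), 0, gqs))
  if (all(rank == -Inf)) return(list(gt = "./.", gq = NA_integer_))
  best <- which(rank == max(rank))[1]
  list(gt = gts[best], gq = as.integer(gqs[best]))
}

# Base-by-base run expansion for a single-base deletion at del_pos.
oracle_homopolymer <- function(chars, del_pos, min_run = 2) {
  b <- chars[del_pos]
  run <- 1
  i <- del_pos - 1
  while (i >= 1 && chars[i] == b) { run <- run + 1; i <- i - 1 }
  i <- del_pos + 1
  while (i <= length(chars) && chars[i] == b) { run <- run + 1; i <- i + 1 }
  run >= min_run
}

# Quadratic window scan: does any window of width w hold >= k positions,
# and what is the max window count?
oracle_cluster_scan <- function(pos, w, k) {
  pos <- sort(pos)
  best <- 0L
  for (p in pos) {
    cnt <- sum(pos >= p & pos < p + w)
    best <- max(best, cnt)
  }
  list(any_hit = best >= k, max_count = best)
}

oracle_bin_counts <- function(pos, bin) {
  table(factor((pos - 1) %/% bin, levels = 0:max((pos - 1) %/% bin)))
}

oracle_confirm <- function(target_gts, opposite_gts, min_homalt = 3) {
  n_t <- sum(target_gts == "hom_alt")
  n_o <- sum(opposite_gts == "hom_alt")
  if (n_t >= min_homalt && n_o == 0) "confirmed" else "failed"
}

# Long-format genotype rows for one validation target (4 + 4 rats).
val_rows <- function(target_id, predicted, target_gts, opposite_gts,
                     amplified = TRUE) {
  opp <- setdiff(c("WLI", "WMI"), predicted)
  tibble::tibble(
    target_id = target_id,
    predicted_strain = predicted,
    rat_id = c(paste0(predicted, "_r", 1:4), paste0(opp, "_r", 1:4)),
    rat_strain = c(rep(predicted, 4), rep(opp, 4)),
    genotype = c(target_gts, opposite_gts),
    amplified = amplified
  )
}

default_class_counts <- function(scale = 1) {
  round(c(TRUE_DIFF_HOM = 50, TRUE_DIFF_HET = 30, SHARED_VARIANT = 30,
          HOMOPOLYMER_ARTIFACT = 24, COLLAPSED_PSEUDO_HET = 20,
          LOW_DEPTH = 12, HIGH_DEPTH = 12, UNCERTAIN_CALLS = 12,
          LOW_Q_DISCORDANT = 10) * scale)
}
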