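cfg <- filter_config()

with_dps <- function(dps) {
  calls <- list()
  for (i in seq_along(SAMPLE_KEYS)) {
    calls[[SAMPLE_KEYS[i]]] <- cs("0/0", 20L, dps[i])
  }
  jv(calls)
}

test_that("depth step enforces the 10-total / 300-single bounds exactly", {
  v <- jv_bind(
    with_dps(c(1, 2, 1, 2, 1, 2)),     # total 9 -> removed
    with_dps(c(2, 2, 2, 2, 1, 1)),     # total 10 -> kept
    with_dps(c(20, 20, 20, 20, 20, 301)),  # single 301 -> removed
    with_dps(c(20, 20, 20, 20, 20, 300))   # single 300 -> kept
  )
  res <- step_depth(v, cfg)
  expect_equal(res$kept$dp_WLI_ILLUMINA, c(2L, 20L))
  expect_equal(nrow(res$removed), 2)
})

test_that("absent DP falls back to sum(AD) and then to zero", {
  v <- jv(list(WLI_ILLUMINA = list(gt = "1/1", gq = 40L, dp = NA_integer_,
                                   ad = c(0L, 12L))))
  depth <- isofilter:::effective_depth(v)
  expect_equal(unname(depth[1, "WLI_ILLUMINA"]), 12L)
  expect_equal(sum(depth), 12)
  expect_equal(nrow(step_depth(v, cfg)$kept), 1)
})

test_that("best call per strain takes the max-GQ call with platform priority ties", {
  v <- jv(list(WLI_ILLUMINA = cs("1/1", 40L, 30L),
               WLI_LINKEDREAD = cs("1/1", 12L, 30L),
               WMI_ILLUMINA = cs("0/0", 50L, 30L),
               WMI_LINKEDREAD = cs("0/0", 50L, 30L),
               WMI_IONTORRENT = cs("0/0", 50L, 30L)))
  out <- best_call_per_strain(v, cfg)
  expect_equal(out$best_gt_WLI, "1/1")
  expect_equal(out$best_gq_WLI, 40L)
  expect_false(out$concordant_WLI)  # a missing call breaks concordance
  expect_true(out$concordant_WMI)
  expect_equal(out$n_missing_WLI, 1L)

  # GQ tie between platforms resolves by ILLUMINA > LINKEDREAD > IONTORRENT
  tie <- jv(list(WLI_LINKEDREAD = cs("0/1", 30L, 30L),
                 WLI_IONTORRENT = cs("1/1", 30L, 30L)))
  expect_equal(best_call_per_strain(tie, cfg)$best_gt_WLI, "0/1")

  none <- jv()
  out0 <- best_call_per_strain(none, cfg)
  expect_equal(out0$best_gt_WLI, "./.")
  expect_true(is.na(out0$best_gq_WLI))
})

test_that("best call matches a brute-force oracle on random call tables", {
  set.seed(101)
  plats <- c("ILLUMINA", "LINKEDREAD", "IONTORRENT")
  for (rep in 1:200) {
    gts <- sample(c("0/0", "0/1", "1/1", "./."), 3, replace = TRUE)
    gqs <- ifelse(gts == "./.", NA_integer_, sample(0:60, 3, replace = TRUE))
    calls <- list()
    for (i in 1:3) {
      calls[[paste0("WLI_", plats[i])]] <-
        cs(gts[i], gqs[i], if (gts[i] == "./.") 0L else 25L)
    }
    out <- best_call_per_strain(jv(calls), cfg)
    exp <- oracle_best_call(gts, gqs)
    expect_equal(out$best_gt_WLI, exp$gt)
    expect_equal(out$best_gq_WLI, exp$gq)
  }
})

test_that("equal best calls are removed only when allele-resolved identical", {
  both_11 <- jv(list(WLI_ILLUMINA = cs("1/1", 40L, 30L),
                     WMI_ILLUMINA = cs("1/1", 45L, 30L)))
  diff_gt <- jv(list(WLI_ILLUMINA = cs("1/1", 40L, 30L),
                     WMI_ILLUMINA = cs("0/0", 45L, 30L)))
  multiallelic <- jv(list(WLI_ILLUMINA = cs("1/1", 40L, 30L, c(0L, 30L, 0L)),
                          WMI_ILLUMINA = cs("2/2", 45L, 30L, c(0L, 0L, 30L))),
                     alt = "T,G")
  one_missing <- jv(list(WLI_ILLUMINA = cs("1/1", 40L, 30L)))
  v <- jv_bind(both_11, diff_gt, multiallelic, one_missing)
  res <- step_equal_best(v, cfg)
  expect_equal(nrow(res$removed), 1)
  expect_equal(res$removed$gt_WMI_ILLUMINA, "1/1")
  expect_equal(nrow(res$kept), 3)
})

test_that("within-strain concordance is a non-destructive stored flag", {
  conc <- jv(list(WMI_ILLUMINA = cs("1/1", 40L, 30L),
                  WMI_LINKEDREAD = cs("1/1", 22L, 30L),
                  WMI_IONTORRENT = cs("1/1", 31L, 30L)))
  part <- jv(list(WMI_ILLUMINA = cs("1/1", 40L, 30L),
                  WMI_LINKEDREAD = cs("1/1", 22L, 30L)))
  out <- flag_within_strain_concordance(jv_bind(conc, part), cfg)
  expect_equal(out$stored, c(TRUE, FALSE))
  expect_equal(nrow(out), 2)
})

test_that("uncertain-call step removes sites with 5 or 6 missing genotypes", {
  five <- jv(list(WLI_ILLUMINA = cs("1/1", 40L, 30L)))
  four <- jv(list(WLI_ILLUMINA = cs("1/1", 40L, 30L),
                  WMI_ILLUMINA = cs("1/1", 35L, 30L)))
  six <- jv()
  res <- step_uncertain(jv_bind(five, four, six), cfg)
  expect_equal(nrow(res$removed), 2)
  expect_equal(res$kept$gt_WMI_ILLUMINA, "1/1")
})

test_that("a lone sub-Q10 discordant call against five identical calls is removed", {
  base <- function(odd_gq, odd_gt = "1/1", n_ref = 5) {
    calls <- list()
    for (i in seq_len(n_ref)) calls[[SAMPLE_KEYS[i]]] <- cs("0/0", 30L, 20L)
    calls[[SAMPLE_KEYS[6]]] <- cs(odd_gt, odd_gq, 20L)
    if (n_ref == 4) calls[[SAMPLE_KEYS[5]]] <- cs("0/1", 25L, 20L)
    jv(calls)
  }
  res <- step_low_quality_discordant(
    jv_bind(base(7L), base(10L), base(3L, n_ref = 4)), cfg)
  expect_equal(nrow(res$removed), 1)
  expect_equal(res$removed$gq_WMI_IONTORRENT, 7L)
})

test_that("allele balance removes dominated sites only when both strains share reads", {
  ab <- function(wli_ads, wmi_ads) {
    calls <- list()
    plats <- c("ILLUMINA", "LINKEDREAD", "IONTORRENT")
    for (i in 1:3) {
      calls[[paste0("WLI_", plats[i])]] <-
        cs("0/1", 30L, sum(wli_ads[[i]]), wli_ads[[i]])
      calls[[paste0("WMI_", plats[i])]] <-
        cs("1/1", 35L, sum(wmi_ads[[i]]), wmi_ads[[i]])
    }
    jv(calls)
  }
  # alt pooled 95/100, strains split 50/50 -> removed
  dominated <- ab(list(c(3, 44), c(1, 1), c(1, 0)),
                  list(c(0, 30), c(0, 10), c(0, 10)))
  # alt 95/100 but strain split 80/20 -> kept
  skewed <- ab(list(c(4, 74), c(1, 1), c(0, 0)),
               list(c(0, 10), c(0, 10), c(0, 0)))
  # alt 85/100, split 50/50 -> kept
  balanced <- ab(list(c(10, 39), c(1, 0), c(0, 0)),
                 list(c(5, 45), c(0, 0), c(0, 0)))
  res <- step_allele_balance(jv_bind(dominated, skewed, balanced), cfg)
  expect_equal(nrow(res$removed), 1)
  expect_equal(nrow(res$kept), 2)
})

test_that("no AD evidence never triggers the allele-balance removal", {
  v <- jv(list(WLI_ILLUMINA = list(gt = "1/1", gq = 40L, dp = 30L,
                                   ad = integer(0))))
  expect_equal(nrow(step_allele_balance(v, cfg)$removed), 0)
})

test_that("cross-platform dispute at Q30 removes the carried difference", {
  disputed <- jv(list(WMI_ILLUMINA = cs("1/1", 50L, 30L),
                      WMI_LINKEDREAD = cs("0/0", 35L, 30L),
                      WLI_ILLUMINA = cs("0/0", 50L, 30L)))
  weak <- jv(list(WMI_ILLUMINA = cs("1/1", 50L, 30L),
                  WMI_LINKEDREAD = cs("0/0", 29L, 30L),
                  WLI_ILLUMINA = cs("0/0", 50L, 30L)))
  res <- step_cross_platform_dispute(jv_bind(disputed, weak), cfg)
  expect_equal(nrow(res$removed), 1)
  expect_equal(res$removed$gq_WMI_LINKEDREAD, 35L)
})

test_that("requiring a reference-anchored difference assigns carrier and zygosity", {
  hom <- jv(list(WLI_ILLUMINA = cs("0/0", 50L, 30L),
                 WMI_ILLUMINA = cs("1/1", 45L, 30L)))
  het <- jv(list(WLI_ILLUMINA = cs("0/0", 50L, 30L),
                 WMI_ILLUMINA = cs("0/1", 45L, 30L)))
  no_ref <- jv(list(WLI_ILLUMINA = cs("0/1", 50L, 30L),
                    WMI_ILLUMINA = cs("1/1", 45L, 30L)))
  res <- step_require_difference(jv_bind(hom, het, no_ref), cfg)
  expect_equal(nrow(res$removed), 1)
  expect_equal(res$kept$carrier_strain, c("WMI", "WMI"))
  expect_equal(res$kept$zygosity, c("hom", "het"))
  expect_equal(res$kept$carrier_gq, c(45L, 45L))
})

test_that("quality tier needs one Q30 supporting call, unopposed at Q10", {
  mk <- function(carrier_gq, extra = NULL) {
    calls <- list(WLI_ILLUMINA = cs("1/1", carrier_gq, 30L),
                  WMI_ILLUMINA = cs("0/0", 50L, 30L),
                  WMI_LINKEDREAD = cs("0/0", 50L, 30L))
    if (!is.null(extra)) calls <- c(calls, extra)
    jv(calls)
  }
  ok <- mk(31L)
  weak <- mk(29L)
  opposed <- mk(45L, list(WLI_LINKEDREAD = cs("0/1", 12L, 30L)))
  opposed_weakly <- mk(45L, list(WLI_LINKEDREAD = cs("0/1", 9L, 30L)))
  v <- jv_bind(ok, weak, opposed, opposed_weakly)
  assigned <- step_require_difference(v, cfg)$kept
  expect_equal(nrow(assigned), 4)
  res <- step_quality_tier(assigned, cfg)
  expect_equal(res$kept$gq_WLI_ILLUMINA, c(31L, 45L))
  expect_equal(nrow(res$removed), 2)
})

test_that("opposite-strain hom-ref calls count as required evidence, not opposition", {
  v <- jv(list(WLI_ILLUMINA = cs("1/1", 45L, 30L),
               WMI_ILLUMINA = cs("0/0", 60L, 30L),
               WMI_LINKEDREAD = cs("0/0", 60L, 30L),
               WMI_IONTORRENT = cs("0/0", 60L, 30L)))
  assigned <- step_require_difference(v, cfg)$kept
  expect_equal(nrow(step_quality_tier(assigned, cfg)$kept), 1)
})

test_that("single-platform homopolymer deletions are removed, supported ones kept", {
  ref <- Biostrings::DNAStringSet(c(`1` = "ACGATTTCAGACGACTACGT"))
  # deletion of one T of TTT at pos 4 (anchor A), ref "AT" alt "A"
  one_platform <- jv(list(WMI_IONTORRENT = cs("1/1", 40L, 30L),
                          WLI_ILLUMINA = cs("0/0", 50L, 30L)),
                     pos = 4L, ref = "AT", alt = "A")
  two_platform <- jv(list(WMI_IONTORRENT = cs("1/1", 40L, 30L),
                          WMI_ILLUMINA = cs("1/1", 22L, 30L),
                          WLI_ILLUMINA = cs("0/0", 50L, 30L)),
                     pos = 4L, ref = "AT", alt = "A")
  # same deletion shape in non-homopolymeric context (pos 9 deletes the
  # lone G at position 10, flanked by two As)
  clean_ctx <- jv(list(WMI_IONTORRENT = cs("1/1", 40L, 30L),
                       WLI_ILLUMINA = cs("0/0", 50L, 30L)),
                  pos = 9L, ref = "AG", alt = "A")
  v <- step_require_difference(jv_bind(one_platform, two_platform, clean_ctx))$kept
  expect_equal(nrow(v), 3)
  res <- step_homopolymer_deletions(v, ref, cfg)
  expect_equal(nrow(res$removed), 1)
  expect_equal(res$removed$pos, 4L)
  expect_equal(sort(res$kept$pos), c(4L, 9L))
})

test_that("every step partitions its input", {
  gen <- generate_reference(50000, 0.3, seed = 9)
  p <- plant_variants(gen, default_class_counts(0.5), seed = 10)
  v <- p$variants
  steps <- list(step_depth, step_equal_best, step_uncertain,
                step_low_quality_discordant, step_allele_balance,
                step_cross_platform_dispute, step_require_difference)
  for (f in steps) {
    res <- f(v, cfg)
    expect_equal(nrow(res$kept) + nrow(res$removed), nrow(v))
  }
})
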