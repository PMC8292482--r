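test_that("reference generation hits the requested homopolymer fraction", {
  gen <- generate_reference(10000, 0.3, seed = 7)
  frac <- sum(gen$runs$length) / 10000
  expect_lt(abs(frac - 0.3), 0.05)
  # the run index is exactly the rle of the emitted sequence
  chars <- strsplit(as.character(gen$ref[[1]]), "")[[1]]
  r <- rle(chars)
  expect_equal(sum(r$lengths[r$lengths >= 2]), sum(gen$runs$length))
})

test_that("zero homopolymer fraction yields no runs at all", {
  gen <- generate_reference(5000, 0, seed = 3)
  expect_equal(nrow(gen$runs), 0)
})

test_that("generators are byte-deterministic per seed", {
  g1 <- generate_reference(5000, 0.3, seed = 11)
  g2 <- generate_reference(5000, 0.3, seed = 11)
  expect_identical(as.character(g1$ref), as.character(g2$ref))
  p1 <- plant_variants(g1, c(TRUE_DIFF_HOM = 10, SHARED_VARIANT = 5), seed = 12)
  p2 <- plant_variants(g2, c(TRUE_DIFF_HOM = 10, SHARED_VARIANT = 5), seed = 12)
  expect_identical(p1$variants, p2$variants)
  expect_identical(p1$truth, p2$truth)
  v1 <- generate_validation_matrix(30, 0.8, seed = 13)
  v2 <- generate_validation_matrix(30, 0.8, seed = 13)
  expect_identical(v1$genotypes, v2$genotypes)
  # generators do not disturb the caller's RNG stream
  set.seed(99); a <- runif(1)
  set.seed(99); invisible(generate_reference(1000, 0.2, seed = 5)); b <- runif(1)
  expect_identical(a, b)
})

test_that("planted variants sit 10+ bp apart and each appears once", {
  gen <- generate_reference(60000, 0.3, seed = 14)
  p <- plant_variants(gen, default_class_counts(0.5), seed = 15)
  expect_false(any(duplicated(p$variants$pos)))
  expect_true(all(diff(sort(p$variants$pos)) >= 10))
  expect_equal(nrow(p$variants), nrow(p$truth))
})

test_that("class-defining constraints hold for every planted record", {
  gen <- generate_reference(100000, 0.3, seed = 16)
  p <- plant_variants(gen, default_class_counts(), seed = 17)
  v <- dplyr::inner_join(p$variants, p$truth, by = c("chrom", "pos", "ref", "alt"))
  depth <- isofilter:::effective_depth(v)
  low <- v$planted_class == "LOW_DEPTH"
  expect_true(all(rowSums(depth[low, , drop = FALSE]) < 10))
  high <- v$planted_class == "HIGH_DEPTH"
  expect_true(all(apply(depth[high, , drop = FALSE], 1, max) > 300))
  hp <- v[v$planted_class == "HOMOPOLYMER_ARTIFACT", ]
  expect_true(all(nchar(hp$ref) > nchar(hp$alt)))
  for (i in seq_len(nrow(hp))) {
    expect_true(homopolymer_context(gen$ref, hp$chrom[i], hp$pos[i],
                                    hp$ref[i], hp$alt[i]))
  }
  unc <- v[v$planted_class == "UNCERTAIN_CALLS", ]
  gts <- as.matrix(unc[, paste0("gt_", SAMPLE_KEYS)])
  expect_true(all(rowSums(gts == "./.") == 5))
})

test_that("running the cascade on generated data reproduces the truth table", {
  gen <- generate_reference(100000, 0.3, seed = 18)
  p <- plant_variants(gen, default_class_counts(0.8), seed = 19)
  run <- run_pipeline(p$variants, gen$ref)
  merged <- dplyr::inner_join(tidy(run), p$truth, by = c("chrom", "pos"))
  expect_equal(mean(merged$step == merged$expected_fate), 1)
  finals <- dplyr::inner_join(run$finals, p$truth, by = c("chrom", "pos"))
  expect_equal(finals$zygosity, finals$expected_zygosity)
  expect_equal(finals$carrier_strain.x, finals$carrier_strain.y)
})

test_that("infeasible plant requests fail loudly", {
  gen <- generate_reference(1500, 0.3, seed = 20)
  expect_error(plant_variants(gen, c(TRUE_DIFF_HOM = 5000), seed = 1), "too")
  expect_error(plant_variants(gen, c(NOT_A_CLASS = 5), seed = 1), "unknown")
  expect_error(generate_reference(500, 0.3, seed = 1), "1000")
  expect_error(generate_reference(5000, 0.95, seed = 1), "fraction")
})

test_that("validation matrices realize extreme and intermediate planted rates", {
  all_good <- generate_validation_matrix(40, 1, seed = 21)
  expect_equal(positive_rate(all_good$genotypes)$positive_rate, 100)
  all_bad <- generate_validation_matrix(40, 0, seed = 22)
  expect_equal(positive_rate(all_bad$genotypes)$positive_rate, 0)
  # intermediate rate within a binomial 95% interval
  vm <- generate_validation_matrix(1000, 0.858, seed = 11)
  obs <- positive_rate(vm$genotypes)$positive_rate
  ci_half <- 100 * 1.96 * sqrt(0.858 * 0.142 / 1000)
  expect_lt(abs(obs - 85.8), ci_half + 0.05)
  # scored status equals intended status target by target
  st <- confirm_targets(vm$genotypes)
  merged <- dplyr::inner_join(st, vm$truth, by = c("target_id", "predicted_strain"))
  expect_equal(merged$status, merged$intended_status)
})

test_that("annotated fixtures keep planted category counts", {
  gen <- generate_reference(40000, 0.3, seed = 23)
  p <- plant_variants(gen, c(TRUE_DIFF_HOM = 30), seed = 24)
  run <- run_pipeline(p$variants, gen$ref)
  fx <- generate_annotated_fixture(run$finals, seed = 25)
  tab <- tabulate_effects(parse_ann(fx$variants))
  planted <- table(isofilter:::effect_label(
    vapply(strsplit(fx$truth$effect, "&", fixed = TRUE), `[`, "", 1)))
  for (eff in names(planted)) {
    got <- sum(tab$WLI[tab$effect == eff], tab$WMI[tab$effect == eff])
    expect_equal(got, unname(planted[[eff]]), info = eff)
  }
  expect_error(generate_annotated_fixture(run$finals[0, ]), "non-empty")
  expect_error(
    generate_annotated_fixture(run$finals,
                               impact_counts = list(WLI = c(HIGH = 1e4))),
    "not enough")
})
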