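ann_variant <- function(ann, pos = 100L, strain = "WLI", alt = "T") {
  tibble::tibble(chrom = "1", pos = as.integer(pos), ref = "A", alt = alt,
                 strain = strain, ann = ann)
}

test_that("ANN entries parse into effect, impact and gene fields", {
  v <- ann_variant(
    "T|missense_variant|MODERATE|Gnat2|ENSRNOG00000019296|transcript|x.1")
  rec <- parse_ann(v)
  expect_equal(rec$primary_label, "Missense variant")
  expect_equal(rec$impact, "MODERATE")
  expect_equal(rec$gene_name, "Gnat2")
  expect_equal(rec$gene_id, "ENSRNOG00000019296")
})

test_that("compound '&' effects keep the full string but use first-listed primary", {
  v <- ann_variant(
    "A|splice_donor_variant&intron_variant|HIGH|Pou6f2|ENSRNOG00000013237|t|x")
  rec <- parse_ann(v)
  expect_equal(rec$primary_effect, "splice_donor_variant")
  expect_equal(rec$primary_label, "Splice donor variant")
  expect_equal(rec$effect_label, "Splice donor variant & intron variant")
})

test_that("multi-entry ANN strings yield one record each; malformed entries warn", {
  v <- ann_variant(paste(
    "T|intron_variant|MODIFIER|G1|ID1|t|x",
    "T|upstream_gene_variant|MODIFIER|G2|ID2|t|x", sep = ","))
  expect_equal(nrow(parse_ann(v)), 2)
  bad <- ann_variant("T|broken")
  expect_warning(out <- parse_ann(bad), "malformed")
  expect_equal(nrow(out), 0)
})

test_that("synthetic ANN strings round-trip field-exactly through the parser", {
  gen <- generate_reference(40000, 0.3, seed = 71)
  p <- plant_variants(gen, c(TRUE_DIFF_HOM = 30), seed = 72)
  run <- run_pipeline(p$variants, gen$ref)
  fx <- generate_annotated_fixture(run$finals,
                                   impact_counts = list(WLI = c(HIGH = 3, MODERATE = 4),
                                                        WMI = c(HIGH = 2, MODERATE = 2)),
                                   seed = 73)
  rec <- parse_ann(fx$variants)
  merged <- dplyr::inner_join(rec, fx$truth, by = c("chrom", "pos"),
                              suffix = c("", ".truth"))
  expect_equal(nrow(merged), nrow(fx$truth))
  expect_equal(merged$effect, merged$effect.truth)
  expect_equal(merged$impact, merged$impact.truth)
  expect_equal(merged$gene_name, merged$gene_name.truth)
})

test_that("effect tabulation counts unique variant-category assignments per strain", {
  v <- dplyr::bind_rows(
    ann_variant("T|intron_variant|MODIFIER|G1|ID1|t|x", 1, "WLI"),
    ann_variant("T|intron_variant|MODIFIER|G2|ID2|t|x", 2, "WLI"),
    ann_variant("T|intergenic_region|MODIFIER|G3|ID3|t|x", 3, "WMI"),
    # two categories on one WMI variant -> two assignments
    ann_variant(paste("T|intron_variant|MODIFIER|G4|ID4|t|x",
                      "T|upstream_gene_variant|MODIFIER|G4|ID4|t|x", sep = ","),
                4, "WMI")
  )
  tab <- tabulate_effects(parse_ann(v))
  expect_equal(tab$WLI[tab$effect == "Intron variant"], 2L)
  expect_equal(tab$WMI[tab$effect == "Intron variant"], 1L)
  expect_equal(tab$WLI[tab$effect == "Total"], 2L)
  expect_equal(tab$WMI[tab$effect == "Total"], 3L)
})

test_that("planted impact mixes come back from extract_high_moderate exactly", {
  gen <- generate_reference(60000, 0.3, seed = 74)
  p <- plant_variants(gen, c(TRUE_DIFF_HOM = 40), seed = 75)
  run <- run_pipeline(p$variants, gen$ref)
  fx <- generate_annotated_fixture(run$finals,
                                   impact_counts = list(WLI = c(HIGH = 5, MODERATE = 6),
                                                        WMI = c(HIGH = 4, MODERATE = 5)),
                                   seed = 76)
  hm <- extract_high_moderate(parse_ann(fx$variants))
  expect_equal(sum(hm$strain == "WLI"), 11)
  expect_equal(sum(hm$strain == "WMI"), 9)
  expect_false(any(!hm$impact %in% c("HIGH", "MODERATE")))
  # sorted by strain then position
  expect_equal(hm$strain, sort(hm$strain))
})

test_that("modifier-only annotation sets yield no impact rows", {
  v <- ann_variant("T|intron_variant|MODIFIER|G1|ID1|t|x")
  expect_equal(nrow(extract_high_moderate(parse_ann(v))), 0)
})

test_that("the highest impact wins when a variant has both HIGH and MODERATE", {
  v <- ann_variant(paste("T|missense_variant|MODERATE|G1|ID1|t|x",
                         "T|stop_lost|HIGH|G1|ID1|t|x", sep = ","))
  hm <- extract_high_moderate(parse_ann(v))
  expect_equal(nrow(hm), 1)
  expect_equal(hm$impact, "HIGH")
  expect_equal(hm$modification, "Stop lost")
})

test_that("gene set summaries satisfy inclusion-exclusion on random sets", {
  set.seed(81)
  for (rep in 1:50) {
    n_wli <- sample(1:40, 1); n_wmi <- sample(1:40, 1)
    genes <- paste0("G", 1:60)
    df <- tibble::tibble(
      strain = c(rep("WLI", n_wli), rep("WMI", n_wmi)),
      gene_id = c(sample(genes, n_wli, replace = TRUE),
                  sample(genes, n_wmi, replace = TRUE))
    )
    gs <- gene_set_summary(df)
    wli <- unique(df$gene_id[df$strain == "WLI"])
    wmi <- unique(df$gene_id[df$strain == "WMI"])
    expect_equal(gs$union_size, length(union(wli, wmi)))
    expect_equal(gs$shared, length(intersect(wli, wmi)))
    expect_equal(gs$union_size,
                 gs$n_per_strain[["WLI"]] + gs$n_per_strain[["WMI"]] - gs$shared)
  }
})

test_that("gene-list overlap counts only listed genes, by category", {
  v <- dplyr::bind_rows(
    ann_variant("T|intron_variant|MODIFIER|Prlr|ID1|t|x", 1),
    ann_variant("T|intergenic_region|MODIFIER|Prlr|ID1|t|x", 2),
    ann_variant("T|intron_variant|MODIFIER|Unlisted|ID9|t|x", 3)
  )
  rec <- parse_ann(v)
  out <- overlap_with_gene_list(rec, c("Prlr"))
  expect_equal(out$n[out$effect == "Total"], 2L)
  expect_equal(out$n[out$effect == "Intron variant"], 1L)
  empty <- overlap_with_gene_list(rec, c("Nothere"))
  expect_equal(empty$n[empty$effect == "Total"], 0L)
  # gene lists can come from a one-symbol-per-line file
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("Prlr", ""), f)
  expect_equal(overlap_with_gene_list(rec, f)$n[[which(out$effect == "Total")]], 2L)
})
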