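# Seeded generators for every pipeline input: reference sequences with
# controlled homopolymer content, joint six-sample VCF call sets with
# planted variant classes and a machine-readable truth table, annotated
# fixtures, and validation genotype matrices.
#
# Each planted class realizes one observed behaviour of the real joint
# call set, and its expected pipeline fate is fixed by construction:
#   TRUE_DIFF_HOM / TRUE_DIFF_HET  survive (hom / het finals)
#   SHARED_VARIANT                 equal best calls -> equal_best
#   COLLAPSED_PSEUDO_HET           het in both strains at ~2x depth
#                                  (collapsed-duplication signature)
#                                  -> equal_best
#   HOMOPOLYMER_ARTIFACT           single-platform deletion inside a
#                                  homopolymer run -> homopolymer_deletions
#   LOW_DEPTH / HIGH_DEPTH         depth bounds -> depth
#   UNCERTAIN_CALLS                5 of 6 missing -> uncertain
#   LOW_Q_DISCORDANT               5 identical calls + 1 weak discordant
#                                  -> low_quality_discordant

PLANT_CLASSES <- c("TRUE_DIFF_HOM", "TRUE_DIFF_HET", "SHARED_VARIANT",
                   "COLLAPSED_PSEUDO_HET", "HOMOPOLYMER_ARTIFACT",
                   "LOW_DEPTH", "HIGH_DEPTH", "UNCERTAIN_CALLS",
                   "LOW_Q_DISCORDANT")

CLASS_FATES <- c(
  TRUE_DIFF_HOM = "survived", TRUE_DIFF_HET = "survived",
  SHARED_VARIANT = "equal_best", COLLAPSED_PSEUDO_HET = "equal_best",
  HOMOPOLYMER_ARTIFACT = "homopolymer_deletions",
  LOW_DEPTH = "depth", HIGH_DEPTH = "depth",
  UNCERTAIN_CALLS = "uncertain", LOW_Q_DISCORDANT = "low_quality_discordant"
)

BASES <- c("A", "C", "G", "T")

# Evaluate code under a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Noise model for the synthetic joint call set
#'
#' Stylized per-platform sequencing parameters: mean depths follow the
#' reference workflow's platform coverages (Illumina 43, linked-read 27,
#' IonTorrent 41), homopolymer deletion artifacts are concentrated on
#' IonTorrent, and collapsed pseudo-heterozygous sites carry about
#' two-fold depth.
#'
#' @param depth_mean Named mean depths per platform.
#' @param artifact_platform Platform carrying homopolymer deletion errors.
#' @param pseudo_het_depth_mult Depth multiplier at collapsed sites.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(depth_mean = c(ILLUMINA = 43, LINKEDREAD = 27,
                                       IONTORRENT = 41),
                        artifact_platform = "IONTORRENT",
                        pseudo_het_depth_mult = 2) {
  stopifnot(all(PLATFORMS %in% names(depth_mean)), all(depth_mean > 0),
            artifact_platform %in% PLATFORMS, pseudo_het_depth_mult > 0)
  structure(list(depth_mean = depth_mean,
                 artifact_platform = artifact_platform,
                 pseudo_het_depth_mult = pseudo_het_depth_mult),
            class = "noise_model")
}

#' Generate a random reference sequence with controlled homopolymer content
#'
#' Builds the sequence from blocks: with the probability implied by
#' `homopolymer_fraction`, a run of 2-4 identical bases; otherwise a
#' single base differing from its left neighbour. `homopolymer_fraction`
#' is the target fraction of positions lying inside runs of two or more
#' identical bases; `0` yields a sequence with no such run.
#'
#' @param length_bp Sequence length (>= 1000; the block construction may
#'   overshoot by a few bases and is trimmed).
#' @param homopolymer_fraction Target in `[0, 0.9]`.
#' @param seed Integer seed; identical seeds give identical output.
#' @param chrom Chromosome name for the single emitted sequence.
#' @return List with `ref` (a one-sequence `DNAStringSet`) and `runs`
#'   (the [homopolymer_runs()] index of the emitted sequence).
#' @export
generate_reference <- function(length_bp, homopolymer_fraction = 0.3,
                               seed = 1, chrom = "1") {
  if (length_bp < 1000) abort("length_bp must be at least 1000")
  if (homopolymer_fraction < 0 || homopolymer_fraction > 0.9) {
    abort("homopolymer_fraction must lie in [0, 0.9]")
  }
  seq <- with_seed(seed, {
    # mean run length is 3, so P(run block) solves f = 3p / (3p + (1-p))
    f <- homopolymer_fraction
    p_run <- f / (3 - 2 * f)
    n_blocks <- length_bp  # upper bound: every block has length >= 1
    is_run <- runif(n_blocks) < p_run
    lens <- ifelse(is_run, sample(2:4, n_blocks, replace = TRUE), 1L)
    # each block's base differs from its predecessor: walk the 4-letter
    # alphabet by a random offset in 1..3
    offsets <- sample(1:3, n_blocks - 1, replace = TRUE)
    idx <- (cumsum(c(sample(0:3, 1), offsets)) %% 4) + 1
    need <- which(cumsum(lens) >= length_bp)[1]
    chars <- rep(BASES[idx[seq_len(need)]], lens[seq_len(need)])
    paste(chars[seq_len(length_bp)], collapse = "")
  })
  ref <- Biostrings::DNAStringSet(setNames(seq, chrom))
  list(ref = ref, runs = homopolymer_runs(ref))
}

draw_dp <- function(platform, noise, mult = 1) {
  dp <- rpois(1, noise$depth_mean[[platform]] * mult)
  as.integer(min(max(dp, 5L), 250L))
}

# Allele strings for one planted variant; kind in snp/ins/del.
draw_alleles <- function(kind, pos, chars) {
  base <- chars[pos]
  if (kind == "snp") {
    list(ref = base, alt = sample(setdiff(BASES, base), 1))
  } else if (kind == "ins") {
    list(ref = base,
         alt = paste0(base, paste(sample(BASES, sample(1:3, 1), replace = TRUE),
                                  collapse = "")))
  } else {
    list(ref = paste0(base, chars[pos + 1L]), alt = base)
  }
}

empty_call <- function() list(gt = "./.", gq = NA_integer_, dp = 0L,
                              ad = integer(0))

homref_call <- function(platform, noise, gq_range = c(12L, 60L)) {
  dp <- draw_dp(platform, noise)
  list(gt = "0/0", gq = sample(gq_range[1]:gq_range[2], 1), dp = dp,
       ad = c(dp, 0L))
}

homalt_call <- function(platform, noise, gq, mult = 1) {
  dp <- draw_dp(platform, noise, mult)
  list(gt = "1/1", gq = as.integer(gq), dp = dp, ad = c(0L, dp))
}

het_call <- function(platform, noise, gq, mult = 1) {
  dp <- draw_dp(platform, noise, mult)
  n_alt <- min(max(rbinom(1, dp, 0.5), 1L), dp - 1L)
  list(gt = "0/1", gq = as.integer(gq), dp = dp,
       ad = c(dp - n_alt, n_alt))
}

# One planted record: build the six calls by class, return a one-row list.
plant_one <- function(class, pos, chars, noise) {
  kind <- switch(class,
    HOMOPOLYMER_ARTIFACT = "del",
    sample(c("snp", "ins", "del"), 1, prob = c(0.45, 0.35, 0.2))
  )
  al <- draw_alleles(kind, pos, chars)
  carrier <- sample(STRAINS, 1)
  opposite <- setdiff(STRAINS, carrier)
  calls <- setNames(vector("list", 6),
                    as.vector(outer(STRAINS, PLATFORMS, sample_id)))
  set_call <- function(strain, platform, call) {
    calls[[sample_id(strain, platform)]] <<- call
  }
  fill_strain <- function(strain, f) for (p in PLATFORMS) set_call(strain, p, f(p))

  zygosity <- NA_character_
  if (class == "TRUE_DIFF_HOM" || class == "TRUE_DIFF_HET") {
    best_platform <- sample(PLATFORMS, 1)
    maker <- if (class == "TRUE_DIFF_HOM") homalt_call else het_call
    fill_strain(carrier, function(p) {
      gq <- if (p == best_platform) sample(31:60, 1) else sample(10:60, 1)
      maker(p, noise, gq)
    })
    fill_strain(opposite, function(p) homref_call(p, noise))
    zygosity <- if (class == "TRUE_DIFF_HOM") "hom" else "het"
  } else if (class == "SHARED_VARIANT") {
    for (s in STRAINS) fill_strain(s, function(p)
      homalt_call(p, noise, sample(31:60, 1)))
    carrier <- NA_character_
  } else if (class == "COLLAPSED_PSEUDO_HET") {
    for (s in STRAINS) fill_strain(s, function(p)
      het_call(p, noise, sample(31:60, 1), mult = noise$pseudo_het_depth_mult))
    carrier <- NA_character_
  } else if (class == "HOMOPOLYMER_ARTIFACT") {
    fill_strain(carrier, function(p) {
      if (p == noise$artifact_platform) homalt_call(p, noise, sample(31:60, 1))
      else empty_call()
    })
    fill_strain(opposite, function(p) homref_call(p, noise))
  } else if (class == "LOW_DEPTH") {
    dps <- sample(rep(c(2L, 1L), 3))  # sums to 9 < minimum total depth
    i <- 0
    alt_platform <- sample(PLATFORMS, 1)
    for (s in STRAINS) for (p in PLATFORMS) {
      i <- i + 1
      dp <- dps[i]
      if (s == carrier && p == alt_platform) {
        set_call(s, p, list(gt = "1/1", gq = sample(20:40, 1), dp = dp,
                            ad = c(0L, dp)))
      } else {
        set_call(s, p, list(gt = "0/0", gq = sample(5:15, 1), dp = dp,
                            ad = c(dp, 0L)))
      }
    }
  } else if (class == "HIGH_DEPTH") {
    best_platform <- sample(PLATFORMS, 1)
    fill_strain(carrier, function(p) {
      gq <- if (p == best_platform) sample(31:60, 1) else sample(10:60, 1)
      homalt_call(p, noise, gq)
    })
    fill_strain(opposite, function(p) homref_call(p, noise))
    blown <- calls[[sample_id(carrier, best_platform)]]
    blown$dp <- sample(301:400, 1)
    blown$ad <- c(0L, blown$dp)
    set_call(carrier, best_platform, blown)
  } else if (class == "UNCERTAIN_CALLS") {
    called_platform <- sample(PLATFORMS, 1)
    fill_strain(carrier, function(p) {
      if (p == called_platform) {
        cl <- homalt_call(p, noise, sample(31:60, 1))
        cl$dp <- max(cl$dp, 10L)  # the lone call must clear the depth gate
        cl$ad <- c(0L, cl$dp)
        cl
      } else empty_call()
    })
    fill_strain(opposite, function(p) empty_call())
  } else if (class == "LOW_Q_DISCORDANT") {
    disc_platform <- sample(PLATFORMS, 1)
    disc_gq <- sample(5:9, 1)
    fill_strain(opposite, function(p) homref_call(p, noise))
    fill_strain(carrier, function(p) {
      if (p == disc_platform) homalt_call(p, noise, disc_gq)
      else {
        dp <- draw_dp(p, noise)
        list(gt = "0/0", gq = sample(1:(disc_gq - 1), 1), dp = dp,
             ad = c(dp, 0L))
      }
    })
  }

  row <- list(pos = as.integer(pos), ref = al$ref, alt = al$alt,
              planted_class = class, carrier = carrier,
              zygosity = zygosity)
  for (key in names(calls)) {
    cl <- calls[[key]]
    row[[paste0("gt_", key)]] <- cl$gt
    row[[paste0("gq_", key)]] <- cl$gq
    row[[paste0("dp_", key)]] <- cl$dp
    row[[paste0("ad_", key)]] <- list(cl$ad)
  }
  row
}

#' Plant classed variants into a synthetic joint call set
#'
#' Emits a six-sample joint call set realizing the requested number of
#' variants per planted class (see the class table at the top of this
#' file), paired with a truth table recording each record's class,
#' carrier strain and expected pipeline fate. Plants never overlap and
#' keep at least 10 bp of spacing, so the homopolymer context of one
#' plant cannot perturb another.
#'
#' @param reference Output of [generate_reference()] (list with `ref` and
#'   `runs`), or a `DNAStringSet` (runs are then indexed on the fly).
#' @param counts Named integer vector over the planted classes; classes
#'   not named get 0.
#' @param noise A [noise_model()].
#' @param seed Integer seed; identical seeds give identical output.
#' @return List with `variants` (a `joint_variants` tibble, positions
#'   shuffled then sorted by position) and `truth` (tibble `chrom`,
#'   `pos`, `ref`, `alt`, `planted_class`, `carrier_strain`,
#'   `expected_fate` in the trace vocabulary, `expected_zygosity`).
#' @export
plant_variants <- function(reference, counts, noise = noise_model(), seed = 1) {
  if (is(reference, "DNAStringSet")) {
    reference <- list(ref = reference, runs = homopolymer_runs(reference))
  }
  ref <- reference$ref
  runs <- reference$runs
  chrom <- names(ref)[1]
  chars <- strsplit(as.character(ref[[1]]), "")[[1]]
  L <- length(chars)

  counts <- counts[counts > 0]
  bad <- setdiff(names(counts), PLANT_CLASSES)
  if (length(bad) > 0) abort(paste0("unknown planted class: ", paste(bad, collapse = ", ")))
  n_hp <- if ("HOMOPOLYMER_ARTIFACT" %in% names(counts)) counts[["HOMOPOLYMER_ARTIFACT"]] else 0L
  n_other <- sum(counts) - n_hp

  with_seed(seed, {
    # homopolymer plants sit one base before a maximal run (the anchor);
    # all other plants live on a 15 bp grid kept >= 12 bp away from them
    run_anchor <- runs$start[runs$chrom == chrom & runs$start >= 12 &
                               runs$end <= L - 12] - 1L
    if (length(run_anchor) > 1) {
      keep <- c(TRUE, diff(run_anchor) >= 12)
      run_anchor <- run_anchor[keep]
    }
    if (n_hp > length(run_anchor)) {
      abort("reference has too few homopolymer runs for the requested plants")
    }
    hp_pos <- sort(sample(run_anchor, n_hp))
    grid <- seq(10L, L - 20L, by = 15L)
    if (n_hp > 0) {
      near_hp <- vapply(grid, function(g) any(abs(g - hp_pos) < 12), logical(1))
      grid <- grid[!near_hp]
    }
    if (n_other > length(grid)) {
      abort("reference too short for the requested number of plants")
    }
    other_pos <- sort(sample(grid, n_other))

    classes <- rep(names(counts), counts)
    other_classes <- sample(classes[classes != "HOMOPOLYMER_ARTIFACT"])
    rows <- c(
      lapply(seq_along(other_pos), function(i)
        plant_one(other_classes[i], other_pos[i], chars, noise)),
      lapply(hp_pos, function(p)
        plant_one("HOMOPOLYMER_ARTIFACT", p, chars, noise))
    )
    df <- bind_rows(lapply(rows, as_tibble))
    df$chrom <- chrom
    df <- df[order(df$pos), ]

    truth <- tibble(
      chrom = df$chrom, pos = df$pos, ref = df$ref, alt = df$alt,
      planted_class = df$planted_class,
      carrier_strain = df$carrier,
      expected_fate = unname(CLASS_FATES[df$planted_class]),
      expected_zygosity = df$zygosity
    )
    variants <- df |>
      select("chrom", "pos", "ref", "alt",
             dplyr::starts_with(c("gt_", "gq_", "dp_", "ad_")))
    list(variants = new_joint_variants(variants), truth = truth)
  })
}

# Effect vocabulary for annotated fixtures (SnpEff tokens with their
# typical impact level).
ANN_EFFECTS <- tibble::tibble(
  effect = c("intergenic_region", "intron_variant", "upstream_gene_variant",
             "downstream_gene_variant", "3_prime_UTR_variant",
             "5_prime_UTR_variant", "non_coding_transcript_exon_variant",
             "intragenic_variant", "synonymous_variant"),
  impact = c(rep("MODIFIER", 8), "LOW")
)
ANN_HIGH <- c("frameshift_variant", "splice_donor_variant&intron_variant",
              "stop_lost", "splice_acceptor_variant&intron_variant")
ANN_MODERATE <- c("missense_variant", "missense_variant&splice_region_variant")

#' Write SnpEff-style annotations onto a set of final variants
#'
#' Assigns each final variant one syntactically valid ANN entry. The
#' requested numbers of HIGH and MODERATE annotations per strain are
#' planted first (effects drawn from the high/moderate vocabulary); the
#' remainder get MODIFIER/LOW effects drawn from the standard category
#' vocabulary. Gene symbols are drawn per strain from `gene_pool` with
#' replacement.
#'
#' @param finals Tibble with `chrom`, `pos`, `alt` and a
#'   `carrier_strain`/`strain` column.
#' @param impact_counts Named list per strain, each
#'   `c(HIGH = n, MODERATE = m)`.
#' @param gene_pool Character vector of gene symbols to draw from.
#' @param seed Integer seed.
#' @return List with `variants` (input plus an `ann` column) and `truth`
#'   (planted effect, impact and gene per record).
#' @export
generate_annotated_fixture <- function(finals,
                                       impact_counts = list(
                                         WLI = c(HIGH = 0, MODERATE = 0),
                                         WMI = c(HIGH = 0, MODERATE = 0)),
                                       gene_pool = paste0("Gene", 1:400),
                                       seed = 1) {
  df <- as_tibble(finals)
  if (nrow(df) == 0) abort("finals must be non-empty")
  strain <- annotation_strain(df)
  with_seed(seed, {
    effect <- character(nrow(df))
    impact <- character(nrow(df))
    for (s in STRAINS) {
      idx <- which(strain == s)
      ic <- impact_counts[[s]] %||% c(HIGH = 0, MODERATE = 0)
      n_hi <- if ("HIGH" %in% names(ic)) as.integer(ic[["HIGH"]]) else 0L
      n_mod <- if ("MODERATE" %in% names(ic)) as.integer(ic[["MODERATE"]]) else 0L
      if (n_hi + n_mod > length(idx)) {
        abort(paste0("not enough ", s, " finals for the requested impact mix"))
      }
      planted <- sample(idx, n_hi + n_mod)
      hi <- planted[seq_len(n_hi)]
      mod <- setdiff(planted, hi)
      effect[hi] <- sample(ANN_HIGH, n_hi, replace = TRUE)
      impact[hi] <- "HIGH"
      effect[mod] <- sample(ANN_MODERATE, n_mod, replace = TRUE)
      impact[mod] <- "MODERATE"
      rest <- setdiff(idx, planted)
      pick <- sample(nrow(ANN_EFFECTS), length(rest), replace = TRUE)
      effect[rest] <- ANN_EFFECTS$effect[pick]
      impact[rest] <- ANN_EFFECTS$impact[pick]
    }
    gene <- sample(gene_pool, nrow(df), replace = TRUE)
    gene_id <- paste0("ENSRNOG", sprintf("%011d", match(gene, gene_pool)))
    allele <- if ("alt" %in% names(df)) map_chr(str_split(df$alt, ","), 1) else "A"
    df$ann <- paste(allele, effect, impact, gene, gene_id,
                    "transcript", paste0(gene_id, ".1"), sep = "|")
    truth <- tibble(chrom = df$chrom, pos = df$pos, strain = strain,
                    effect = effect, impact = impact, gene_name = gene,
                    gene_id = gene_id)
    list(variants = df, truth = truth)
  })
}

#' Generate a validation genotype matrix with a planted positive rate
#'
#' Emulates the 4 + 4 rat targeted re-sequencing design: for each target,
#' the intended status is drawn Bernoulli(`true_positive_rate`).
#' Confirmed targets get 3 or 4 hom-alt target-strain rats and no
#' opposite-strain hom-alt; failed targets either carry an opposite-strain
#' hom-alt rat or only 2 hom-alt target rats. A fraction of targets can
#' be marked as yielding no PCR product.
#'
#' @param n_targets Number of targets (split evenly between strains).
#' @param true_positive_rate Probability an amplified target is confirmed.
#' @param seed Integer seed.
#' @param prop_not_amplified Fraction of targets with no PCR product.
#' @return List with `genotypes` (long tibble for [positive_rate()]),
#'   `rats` (design tibble), and `truth` (intended status per target).
#' @export
generate_validation_matrix <- function(n_targets, true_positive_rate = 0.858,
                                       seed = 1, prop_not_amplified = 0) {
  stopifnot(true_positive_rate >= 0, true_positive_rate <= 1,
            prop_not_amplified >= 0, prop_not_amplified < 1)
  rats <- tibble(
    rat_id = paste0(rep(STRAINS, each = 4), "_rat", 1:4),
    rat_strain = rep(STRAINS, each = 4),
    sex = rep(c("M", "M", "F", "F"), 2)
  )
  with_seed(seed, {
    targets <- tibble(
      target_id = sprintf("T%04d", seq_len(n_targets)),
      predicted_strain = rep_len(STRAINS, n_targets)
    )
    amplified <- runif(n_targets) >= prop_not_amplified
    confirmed <- amplified & (runif(n_targets) < true_positive_rate)
    rows <- lapply(seq_len(n_targets), function(i) {
      g <- setNames(rep("hom_ref", 8), rats$rat_id)
      tgt <- rats$rat_id[rats$rat_strain == targets$predicted_strain[i]]
      opp <- setdiff(rats$rat_id, tgt)
      if (!amplified[i]) {
        g[] <- "missing"
      } else if (confirmed[i]) {
        n_hom <- sample(3:4, 1)
        hom <- sample(tgt, n_hom)
        g[hom] <- "hom_alt"
        if (n_hom == 3) g[setdiff(tgt, hom)] <- sample(c("het", "missing", "hom_ref"), 1)
        g[opp] <- sample(c("hom_ref", "het"), 4, replace = TRUE, prob = c(0.9, 0.1))
      } else if (runif(1) < 0.5) {
        # failure mode: opposite-strain hom-alt despite full target support
        g[tgt] <- "hom_alt"
        g[sample(opp, sample(1:2, 1))] <- "hom_alt"
      } else {
        # failure mode: too few hom-alt target rats
        g[sample(tgt, 2)] <- "hom_alt"
        g[setdiff(tgt, names(g)[g == "hom_alt"])] <- "het"
      }
      tibble(target_id = targets$target_id[i],
             predicted_strain = targets$predicted_strain[i],
             rat_id = rats$rat_id, rat_strain = rats$rat_strain,
             genotype = unname(g[rats$rat_id]),
             amplified = amplified[i])
    })
    truth <- targets
    truth$intended_status <- ifelse(!amplified, "not_amplified",
                                    ifelse(confirmed, "confirmed", "failed"))
    list(genotypes = bind_rows(rows), rats = rats, truth = truth)
  })
}
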