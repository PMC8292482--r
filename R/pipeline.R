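# The full consensus filtering cascade.

PIPELINE_STEPS <- c(
  "depth", "equal_best", "uncertain", "equal_best_2",
  "low_quality_discordant", "allele_balance", "cross_platform_dispute",
  "require_difference", "quality_tier", "homopolymer_deletions"
)

#' Run the consensus filter cascade
#'
#' Applies the ten-step cascade in fixed order: depth bounds, equal best
#' calls, within-strain concordance flagging (non-destructive), mostly
#' uncertain sites, equal best calls re-applied, low-quality lone
#' discordance, pooled allele balance, cross-platform dispute, the
#' reference-anchored difference requirement with the Q30/Q10 quality
#' tier, and finally homopolymer-context deletion artifacts. Every input
#' record ends in exactly one removal bucket or a final set; per-step
#' removal counts and a per-variant elimination trace are returned
#' alongside the finals.
#'
#' Records whose carrier strain has all three platforms concordant on the
#' carrier call at GQ >= `cfg$q_low` but no single call at `cfg$q_high`
#' are additionally reported as `cross_tech`: cross-technology supported,
#' but excluded from the final selection because platform qualities are
#' not summed.
#'
#' @param variants A `joint_variants` tibble, or a path to a joint VCF.
#' @param ref A `DNAStringSet` reference or a FASTA path.
#' @param cfg A [filter_config()].
#' @param sample_map Optional [sample_map()], used when `variants` is a
#'   path.
#' @return An object of class `filter_run`: a list with `finals` (tibble
#'   with `carrier_strain` and `zygosity`), `counts` (per-step removals
#'   plus survivors), `trace` (chrom, pos, step), `cross_tech`, `stored`
#'   (within-strain concordant records), and `n_input`.
#' @export
run_pipeline <- function(variants, ref, cfg = filter_config(), sample_map = NULL) {
  if (is.character(variants)) variants <- read_joint_vcf(variants, sample_map)
  if (is.character(ref)) ref <- read_reference(ref)
  variants <- as_tibble(variants)
  variants$.row_id <- seq_len(nrow(variants))

  trace <- tibble(chrom = variants$chrom, pos = variants$pos,
                  step = NA_character_)
  counts <- setNames(integer(length(PIPELINE_STEPS)), PIPELINE_STEPS)
  note_removed <- function(removed, step) {
    trace$step[removed$.row_id] <<- step
    counts[step] <<- counts[step] + nrow(removed)
  }

  res <- step_depth(variants, cfg); note_removed(res$removed, "depth")
  res <- step_equal_best(res$kept, cfg); note_removed(res$removed, "equal_best")
  kept <- flag_within_strain_concordance(res$kept, cfg)
  stored <- kept[kept$stored, , drop = FALSE]
  res <- step_uncertain(kept, cfg); note_removed(res$removed, "uncertain")
  res <- step_equal_best(res$kept, cfg); note_removed(res$removed, "equal_best_2")
  res <- step_low_quality_discordant(res$kept, cfg)
  note_removed(res$removed, "low_quality_discordant")
  res <- step_allele_balance(res$kept, cfg)
  note_removed(res$removed, "allele_balance")
  res <- step_cross_platform_dispute(res$kept, cfg)
  note_removed(res$removed, "cross_platform_dispute")
  res <- step_require_difference(res$kept, cfg)
  note_removed(res$removed, "require_difference")

  # Cross-technology side set: all three carrier platforms agree at
  # GQ >= q_low but no call reaches q_high; reported, never in finals.
  pre_tier <- res$kept
  cross_tech_mask <- cross_tech_supported(pre_tier, cfg)

  res <- step_quality_tier(pre_tier, cfg)
  note_removed(res$removed, "quality_tier")
  res <- step_homopolymer_deletions(res$kept, ref, cfg)
  note_removed(res$removed, "homopolymer_deletions")

  finals <- res$kept
  trace$step[finals$.row_id] <- "survived"
  cross_tech <- pre_tier[cross_tech_mask, , drop = FALSE]

  finals$.row_id <- NULL
  cross_tech$.row_id <- NULL
  stored$.row_id <- NULL

  structure(list(
    finals = new_joint_variants(finals),
    counts = tibble(step = c(PIPELINE_STEPS, "survived"),
                    n = c(unname(counts), nrow(finals))),
    trace = trace,
    cross_tech = new_joint_variants(cross_tech),
    stored = new_joint_variants(stored),
    n_input = nrow(variants)
  ), class = "filter_run")
}

cross_tech_supported <- function(variants, cfg) {
  n <- nrow(variants)
  if (n == 0) return(logical(0))
  vapply(seq_len(n), function(i) {
    carrier <- variants$carrier_strain[i]
    if (is.na(carrier)) return(FALSE)
    carrier_gt <- variants$carrier_gt[i]
    gq_max <- -Inf
    for (platform in PLATFORMS) {
      key <- sample_id(carrier, platform)
      gt <- variants[[paste0("gt_", key)]][i]
      if (gt_is_missing(gt) || gt != carrier_gt) return(FALSE)
      gq <- variants[[paste0("gq_", key)]][i]
      if (is.na(gq) || gq < cfg$q_low) return(FALSE)
      gq_max <- max(gq_max, gq)
    }
    gq_max < cfg$q_high
  }, logical(1))
}

#' @export
print.filter_run <- function(x, ...) {
  cat("<filter_run>", x$n_input, "input variants\n")
  print(x$counts, n = Inf)
  if (nrow(x$finals) > 0) {
    tab <- table(x$finals$carrier_strain, x$finals$zygosity)
    cat("finals by strain x zygosity:\n")
    print(tab)
  }
  invisible(x)
}

#' @describeIn run_pipeline `tidy()` returns the per-variant trace;
#'   `glance()` the per-step counts in wide form.
#' @param x A `filter_run`.
#' @param ... Unused.
#' @method tidy filter_run
#' @export
tidy.filter_run <- function(x, ...) x$trace

#' @method glance filter_run
#' @export
glance.filter_run <- function(x, ...) {
  wide <- as_tibble(as.list(setNames(x$counts$n, x$counts$step)))
  wide$n_input <- x$n_input
  wide$n_cross_tech <- nrow(x$cross_tech)
  wide
}

#' Flowchart plot of per-step removals
#'
#' @param object A `filter_run`.
#' @param ... Unused.
#' @return A ggplot bar chart of removal counts per cascade step.
#' @method autoplot filter_run
#' @export
autoplot.filter_run <- function(object, ...) {
  df <- object$counts
  df$step <- factor(df$step, levels = rev(df$step))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$step)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "variants removed (or surviving)", y = NULL,
                  title = "Filter cascade flowchart") +
    ggplot2::theme_minimal()
}
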