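# Variant classification and per-strain summary tables.

PURINES <- c("A", "G")
VARIANT_CLASSES <- c("transition_snp", "transversion_snp",
                     "insertion", "deletion", "other")

#' Classify a variant by its REF/ALT alleles
#'
#' Single-base substitutions are SNPs, split into transitions (purine to
#' purine: A<->G, or pyrimidine to pyrimidine: C<->T) and transversions
#' (all other single-base changes). Length differences are insertions
#' (ALT longer) or deletions (ALT shorter); equal-length multi-base
#' substitutions are classed `other`.
#'
#' @param ref,alt Character vectors of REF and ALT alleles (recycled to a
#'   common length).
#' @return A character vector over
#'   `c("transition_snp", "transversion_snp", "insertion", "deletion", "other")`.
#' @examples
#' classify_variant(c("C", "A", "A", "AT"), c("T", "C", "AT", "A"))
#' @export
classify_variant <- function(ref, alt) {
  n <- max(length(ref), length(alt))
  ref <- rep_len(toupper(ref), n)
  alt <- rep_len(toupper(alt), n)
  if (any(!nzchar(ref)) || any(!nzchar(alt))) abort("alleles must be non-empty")
  if (any(ref == alt)) abort("identical REF and ALT is not a variant")
  lr <- nchar(ref)
  la <- nchar(alt)
  out <- rep("other", n)
  out[la > lr] <- "insertion"
  out[la < lr] <- "deletion"
  snp <- lr == 1 & la == 1
  transition <- snp & ((ref %in% PURINES) == (alt %in% PURINES))
  out[snp & transition] <- "transition_snp"
  out[snp & !transition] <- "transversion_snp"
  out
}

# The ALT allele actually called in the carrier strain (first called ALT
# at multiallelic sites); used so each final variant gets one class.
carrier_allele <- function(variants) {
  alts <- str_split(variants$alt, ",")
  gt <- if ("carrier_gt" %in% names(variants)) variants$carrier_gt else NULL
  vapply(seq_len(nrow(variants)), function(i) {
    idx <- if (!is.null(gt) && !is.na(gt[i])) gt_alt_indices(gt[i])[[1]] else 1L
    if (length(idx) == 0) idx <- 1L
    alts[[i]][idx[1]]
  }, character(1))
}

#' Summarize final variants per strain and class
#'
#' Builds the per-strain class-count table with pooled fractions. Input is
#' either a finals tibble carrying `carrier_strain` (classes are derived
#' from REF and the carrier's called ALT allele), or a pre-classified
#' tibble with `strain` and `class` columns.
#'
#' @param variants A tibble of final variants, or of `(strain, class)`
#'   assignments.
#' @return A `variant_summary` object; see [tidy.variant_summary()] and
#'   [glance.variant_summary()].
#' @examples
#' df <- tibble::tibble(
#'   strain = c("WLI", "WLI", "WMI"),
#'   class = c("transition_snp", "insertion", "deletion")
#' )
#' glance(variant_summary(df))
#' @export
variant_summary <- function(variants) {
  df <- as_tibble(variants)
  if (!"class" %in% names(df)) {
    if (!all(c("ref", "alt") %in% names(df))) {
      abort("variant_summary needs either a class column or ref/alt alleles")
    }
    df$class <- classify_variant(df$ref, carrier_allele(df))
  }
  if (!"strain" %in% names(df)) {
    if (!"carrier_strain" %in% names(df)) {
      abort("variant_summary needs a strain or carrier_strain column")
    }
    df$strain <- df$carrier_strain
  }
  counts <- df |>
    count(.data$strain, .data$class, name = "n") |>
    tidyr::complete(strain = STRAINS,
                    class = VARIANT_CLASSES,
                    fill = list(n = 0L))

  pooled <- counts |> group_by(.data$class) |> summarise(n = sum(.data$n))
  total <- sum(pooled$n)
  get <- function(cl) sum(pooled$n[pooled$class %in% cl])
  n_snp <- get(c("transition_snp", "transversion_snp"))
  fractions <- if (total == 0) {
    tibble(quantity = character(0), percent = numeric(0))
  } else {
    tibble(
      quantity = c("insertion", "snp", "deletion", "other",
                   "transition_among_snps"),
      percent = c(
        round_half_up(100 * get("insertion") / total, 1),
        round_half_up(100 * n_snp / total, 1),
        round_half_up(100 * get("deletion") / total, 1),
        round_half_up(100 * get("other") / total, 1),
        if (n_snp > 0) round_half_up(100 * get("transition_snp") / n_snp, 1) else NA_real_
      )
    )
  }
  structure(list(counts = counts, fractions = fractions,
                 totals = counts |> group_by(.data$strain) |>
                   summarise(n = sum(.data$n)),
                 grand_total = total),
            class = "variant_summary")
}

# Half-up rounding (round() is banker's rounding; table fractions are
# reported half-up to one decimal).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @describeIn variant_summary `tidy()` returns the per-strain class
#'   counts.
#' @param x A `variant_summary`.
#' @param ... Unused.
#' @method tidy variant_summary
#' @export
tidy.variant_summary <- function(x, ...) x$counts

#' @describeIn variant_summary `glance()` returns one row of totals and
#'   pooled percentages.
#' @method glance variant_summary
#' @export
glance.variant_summary <- function(x, ...) {
  pct <- setNames(x$fractions$percent, paste0("pct_", x$fractions$quantity))
  tot <- setNames(as.list(x$totals$n), paste0("total_", x$totals$strain))
  as_tibble(c(tot, list(grand_total = x$grand_total), as.list(pct)))
}

#' @export
print.variant_summary <- function(x, ...) {
  cat("<variant_summary>\n")
  wide <- tidyr::pivot_wider(x$counts, names_from = "strain", values_from = "n")
  print(wide, n = Inf)
  cat("totals:", paste(x$totals$strain, x$totals$n, collapse = ", "),
      "| grand total", x$grand_total, "\n")
  if (nrow(x$fractions) > 0) {
    cat("pooled fractions (%):\n")
    print(x$fractions, n = Inf)
  }
  invisible(x)
}

#' @describeIn variant_summary Stacked bar chart of class counts per strain.
#' @param object A `variant_summary`.
#' @method autoplot variant_summary
#' @export
autoplot.variant_summary <- function(object, ...) {
  ggplot2::ggplot(object$counts,
                  ggplot2::aes(x = .data$strain, y = .data$n, fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "variants", fill = "class",
                  title = "Final variants by class and strain") +
    ggplot2::theme_minimal()
}
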