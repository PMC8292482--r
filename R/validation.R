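# Targeted re-sequencing concordance scoring.
#
# The validation design genotypes 8 individual rats (4 per strain, equal
# sexes) at targets predicted to be strain-specific. A target is
# confirmed when (1) at least 3 of the 4 target-strain rats are
# homozygous alternative, and (2) no rat of the opposite strain is
# homozygous alternative. Missing genotypes count toward neither
# criterion; heterozygous calls count against criterion 1 (they are not
# hom-alt) but do not trigger criterion 2.

#' Score validation targets against the two confirmation criteria
#'
#' @param genotypes Long tibble, one row per (target, rat):
#'   `target_id`, `predicted_strain` (the strain carrying the predicted
#'   variant), `rat_strain`, `genotype` in
#'   `c("hom_ref", "het", "hom_alt", "missing")`, and optionally
#'   `amplified` (per-target logical; defaults to `TRUE`).
#' @param min_target_homalt Rats of the target strain that must be
#'   hom-alt (criterion 1).
#' @return Tibble `target_id`, `predicted_strain`, `n_target_homalt`,
#'   `n_opposite_homalt`, `status` in
#'   `c("confirmed", "failed", "not_amplified")`.
#' @export
confirm_targets <- function(genotypes, min_target_homalt = 3) {
  df <- as_tibble(genotypes)
  needed <- c("target_id", "predicted_strain", "rat_strain", "genotype")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("genotypes lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  bad <- setdiff(unique(df$genotype), c("hom_ref", "het", "hom_alt", "missing"))
  if (length(bad) > 0) {
    abort(paste0("unknown genotype value(s): ", paste(bad, collapse = ", ")))
  }
  if (!"amplified" %in% names(df)) df$amplified <- TRUE
  df |>
    group_by(.data$target_id, .data$predicted_strain) |>
    summarise(
      amplified = all(.data$amplified),
      n_target_homalt = sum(.data$genotype == "hom_alt" &
                              .data$rat_strain == .data$predicted_strain),
      n_opposite_homalt = sum(.data$genotype == "hom_alt" &
                                .data$rat_strain != .data$predicted_strain),
      .groups = "drop"
    ) |>
    mutate(status = dplyr::case_when(
      !.data$amplified ~ "not_amplified",
      .data$n_target_homalt >= min_target_homalt &
        .data$n_opposite_homalt == 0 ~ "confirmed",
      TRUE ~ "failed"
    )) |>
    select(-"amplified")
}

#' Positive rate of the targeted re-sequencing validation
#'
#' Computes `100 * confirmed / amplified` (to one decimal), where
#' amplified = confirmed + failed; targets that yielded no PCR product
#' are excluded from the denominator.
#'
#' @inheritParams confirm_targets
#' @return A `validation_result` list: per-target `targets` tibble,
#'   per-strain `counts`, and `positive_rate` (percent, `NA` when nothing
#'   amplified).
#' @examples
#' g <- generate_validation_matrix(20, true_positive_rate = 1, seed = 1)
#' positive_rate(g$genotypes)$positive_rate
#' @export
positive_rate <- function(genotypes, min_target_homalt = 3) {
  targets <- confirm_targets(genotypes, min_target_homalt)
  counts <- targets |>
    count(.data$predicted_strain, .data$status, name = "n")
  n_confirmed <- sum(targets$status == "confirmed")
  n_amplified <- sum(targets$status != "not_amplified")
  rate <- if (n_amplified == 0) NA_real_ else
    round_half_up(100 * n_confirmed / n_amplified, 1)
  structure(list(targets = targets, counts = counts,
                 n_confirmed = n_confirmed, n_amplified = n_amplified,
                 positive_rate = rate),
            class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat("<validation_result>", x$n_confirmed, "confirmed of",
      x$n_amplified, "amplified targets; positive rate",
      ifelse(is.na(x$positive_rate), "NA", paste0(x$positive_rate, "%")), "\n")
  invisible(x)
}

#' @describeIn positive_rate `tidy()` returns the per-target status table.
#' @param x A `validation_result`.
#' @param ... Unused.
#' @method tidy validation_result
#' @export
tidy.validation_result <- function(x, ...) x$targets

#' @method glance validation_result
#' @export
glance.validation_result <- function(x, ...) {
  tibble(n_confirmed = x$n_confirmed, n_amplified = x$n_amplified,
         positive_rate = x$positive_rate)
}
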