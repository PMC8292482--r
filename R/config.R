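#' Filtering thresholds for the consensus cascade
#'
#' Bundles every numeric threshold used by the filter cascade. Defaults are
#' the values used throughout the package's reference workflow:
#' read-depth bounds of 10 (summed over the six samples) and 300 (on any one
#' sample), Phred genotype-quality tiers at 10/20/30, a 90% pooled
#' allele-majority with a 25% per-strain read share, a 1 kb cluster window,
#' a 5 kb upstream window for proximity annotation, a minimum homopolymer
#' run of two identical bases, and deletion support from at least two
#' platforms inside homopolymer runs.
#'
#' @param min_total_depth Minimum summed read depth across all six samples.
#' @param max_single_depth Maximum read depth tolerated on any one sample.
#' @param q_low,q_mid,q_high Phred genotype-quality tiers; `q_low` gates
#'   opposition and support, `q_high` gates the final confidence tier.
#' @param allele_majority Pooled fraction of reads above which one allele is
#'   considered to dominate the site.
#' @param strain_share Minimum fraction of pooled reads each strain must
#'   contribute for the allele-majority removal to apply.
#' @param max_uncertain Number of missing (`./.`) genotypes at which a site
#'   is discarded.
#' @param cluster_window_bp Window width for cluster detection, in bp.
#' @param upstream_window_bp Upstream proximity window used in annotation
#'   summaries, in bp.
#' @param homopolymer_min_run Minimum run of identical reference bases that
#'   counts as homopolymeric.
#' @param min_supporting_platforms Platforms (within the carrier strain)
#'   that must support a homopolymer-context deletion for it to be kept.
#'
#' @return A list of class `filter_config`.
#' @examples
#' cfg <- filter_config()
#' cfg$q_high
#' @export
filter_config <- function(min_total_depth = 10,
                          max_single_depth = 300,
                          q_low = 10,
                          q_mid = 20,
                          q_high = 30,
                          allele_majority = 0.90,
                          strain_share = 0.25,
                          max_uncertain = 5,
                          cluster_window_bp = 1000,
                          upstream_window_bp = 5000,
                          homopolymer_min_run = 2,
                          min_supporting_platforms = 2) {
  cfg <- list(
    min_total_depth = min_total_depth,
    max_single_depth = max_single_depth,
    q_low = q_low,
    q_mid = q_mid,
    q_high = q_high,
    allele_majority = allele_majority,
    strain_share = strain_share,
    max_uncertain = max_uncertain,
    cluster_window_bp = cluster_window_bp,
    upstream_window_bp = upstream_window_bp,
    homopolymer_min_run = homopolymer_min_run,
    min_supporting_platforms = min_supporting_platforms
  )
  if (!all(vapply(cfg, function(x) is.numeric(x) && length(x) == 1 && x > 0, logical(1)))) {
    abort("all filter_config thresholds must be single positive numbers")
  }
  if (!(q_low < q_mid && q_mid < q_high)) {
    abort("quality tiers must satisfy q_low < q_mid < q_high")
  }
  if (allele_majority <= 0 || allele_majority >= 1) {
    abort("allele_majority must lie strictly between 0 and 1")
  }
  if (strain_share <= 0 || strain_share > 0.5) {
    abort("strain_share must lie in (0, 0.5]")
  }
  structure(cfg, class = "filter_config")
}

#' @export
print.filter_config <- function(x, ...) {
  cat("<filter_config>\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
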