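# Genotype-string utilities.
#
# Genotypes are stored as normalized unphased strings over allele indices:
# "0/0", "0/1", "1/1", "1/2", ... with alleles sorted ascending, and "./."
# for a missing call. Any genotype containing a "." allele is treated as
# missing (a half call carries no usable evidence for the cascade).
# Equality of two calls compares these normalized strings, so at a
# multiallelic site 1/1 and 2/2 are different calls.

#' Normalize a VCF GT string
#'
#' Strips phasing, sorts alleles, and collapses anything containing a
#' missing allele to `"./."`. `NA` input is missing.
#'
#' @param gt Character vector of raw GT strings (e.g. `"0|1"`, `"./."`).
#' @return Character vector of normalized genotypes.
#' @examples
#' normalize_gt(c("1|0", "./1", NA, "2/1"))
#' @export
normalize_gt <- function(gt) {
  vapply(gt, function(g) {
    if (is.na(g) || g == "" || g == ".") return("./.")
    alleles <- strsplit(g, "[/|]")[[1]]
    if (length(alleles) == 0 || any(alleles == "." | alleles == "")) return("./.")
    paste(sort(as.integer(alleles)), collapse = "/")
  }, character(1), USE.NAMES = FALSE)
}

gt_is_missing <- function(gt) is.na(gt) | gt == "./."

gt_is_homref <- function(gt) !gt_is_missing(gt) & gt == "0/0"

gt_is_het <- function(gt) {
  out <- logical(length(gt))
  ok <- !gt_is_missing(gt)
  parts <- strsplit(gt[ok], "/", fixed = TRUE)
  out[ok] <- vapply(parts, function(a) length(unique(a)) > 1, logical(1))
  out
}

gt_is_homalt <- function(gt) {
  out <- logical(length(gt))
  ok <- !gt_is_missing(gt)
  parts <- strsplit(gt[ok], "/", fixed = TRUE)
  out[ok] <- vapply(parts, function(a) length(unique(a)) == 1 && a[1] != "0", logical(1))
  out
}

# ALT allele indices (1-based into the alts list) carried by a genotype.
gt_alt_indices <- function(gt) {
  lapply(gt, function(g) {
    if (gt_is_missing(g)) return(integer(0))
    idx <- unique(as.integer(strsplit(g, "/", fixed = TRUE)[[1]]))
    sort(idx[idx > 0])
  })
}

# Zygosity label for a non-missing, non-reference genotype.
gt_zygosity <- function(gt) {
  ifelse(gt_is_het(gt), "het", ifelse(gt_is_homalt(gt), "hom", NA_character_))
}

# Column-name helpers for the wide joint_variants layout.
sample_id <- function(strain, platform) paste(strain, platform, sep = "_")

call_cols <- function(field) {
  keys <- as.vector(outer(STRAINS, PLATFORMS, sample_id))
  paste0(field, "_", keys)
}
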