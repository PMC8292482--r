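# Joint-variant container and VCF input/output.
#
# A joint call set is a tibble of class "joint_variants" with one row per
# site and wide per-sample columns. For each of the six samples
# (<STRAIN>_<PLATFORM>) it carries:
#   gt_*  normalized genotype string ("0/0", "0/1", "1/1", "./."...)
#   gq_*  Phred-scaled genotype quality (integer, NA when absent)
#   dp_*  read depth (integer; NA means absent and is treated as 0 after
#         falling back to sum(AD) where AD is present)
#   ad_*  list-column of per-allele read counts (length 1 + n ALT alleles)
# plus chrom (with any "chr" prefix stripped), pos (1-based), ref, alt
# (comma-joined ALT alleles) and an optional ann column (raw SnpEff ANN).

#' Map VCF sample columns to strain and platform
#'
#' @param samples Character vector of VCF sample column names.
#' @param strain,platform Character vectors (recycled against `samples`)
#'   with values in `WLI`/`WMI` and `ILLUMINA`/`LINKEDREAD`/`IONTORRENT`.
#' @return A tibble with columns `sample`, `strain`, `platform`.
#' @examples
#' sample_map(c("wli_ix", "wmi_ix"), c("WLI", "WMI"), "ILLUMINA")
#' @export
sample_map <- function(samples, strain, platform) {
  map <- tibble(sample = samples,
                strain = toupper(strain),
                platform = toupper(platform))
  validate_sample_map(map)
}

validate_sample_map <- function(map) {
  map <- as_tibble(map)
  stopifnot(all(c("sample", "strain", "platform") %in% names(map)))
  bad_strain <- setdiff(unique(map$strain), STRAINS)
  bad_platform <- setdiff(unique(map$platform), PLATFORMS)
  if (length(bad_strain) > 0) {
    abort(paste0("unknown strain(s): ", paste(bad_strain, collapse = ", ")))
  }
  if (length(bad_platform) > 0) {
    abort(paste0("unknown platform(s): ", paste(bad_platform, collapse = ", ")))
  }
  key <- paste(map$strain, map$platform)
  if (anyDuplicated(key) || nrow(map) != 6) {
    abort("sample map must cover all 6 strain x platform pairs exactly once")
  }
  map
}

# Guess a sample map from names shaped like "WLI_ILLUMINA" / "wmi-iontorrent".
infer_sample_map <- function(samples) {
  parts <- str_split(toupper(samples), "[^A-Z]+")
  strain <- map_chr(parts, function(p) {
    hit <- intersect(p, STRAINS)
    if (length(hit) == 1) hit else NA_character_
  })
  platform <- map_chr(parts, function(p) {
    hit <- intersect(p, PLATFORMS)
    if (length(hit) == 1) hit else NA_character_
  })
  if (anyNA(strain) || anyNA(platform)) {
    abort(paste0(
      "cannot infer strain/platform from sample names: ",
      paste(samples[is.na(strain) | is.na(platform)], collapse = ", "),
      "; supply a sample_map"
    ))
  }
  sample_map(samples, strain, platform)
}

# Strip an optional "chr" prefix so "chr1" and "1" compare equal.
normalize_chrom <- function(chrom) sub("^chr", "", chrom, ignore.case = TRUE)

chrom_rank <- function(chrom) {
  num <- suppressWarnings(as.numeric(chrom))
  rank <- ifelse(!is.na(num), num,
                 ifelse(chrom == "X", 1e6, ifelse(chrom == "Y", 1e6 + 1, 1e6 + 2)))
  rank
}

new_joint_variants <- function(df) {
  df <- as_tibble(df)
  class(df) <- c("joint_variants", class(df))
  df
}

#' Read a jointly genotyped six-sample VCF
#'
#' Parses a VCF (plain or bgzipped) holding one sample per strain x
#' platform combination into a wide `joint_variants` tibble. GT is
#' normalized ([normalize_gt()]); absent GQ/DP/AD are recorded as `NA` /
#' empty. When DP is absent but AD is present, depth falls back to
#' `sum(AD)`; when both are absent the depth used by the cascade is 0.
#'
#' @param path Path to the VCF.
#' @param sample_map A [sample_map()] tibble, or `NULL` to infer strain and
#'   platform from sample names shaped like `"WLI_ILLUMINA"`.
#' @return A `joint_variants` tibble, one row per VCF record in file order.
#' @export
read_joint_vcf <- function(path, sample_map = NULL) {
  if (!file.exists(path)) abort(paste0("VCF not found: ", path))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(vcf@gt)[-1]
  map <- if (is.null(sample_map)) infer_sample_map(samples) else validate_sample_map(sample_map)
  missing_cols <- setdiff(samples, map$sample)
  if (length(missing_cols) > 0) {
    abort(paste0("sample column(s) not in sample_map: ",
                 paste(missing_cols, collapse = ", ")))
  }

  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  n <- nrow(fix)
  out <- tibble(
    chrom = normalize_chrom(fix$CHROM),
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT
  )
  if (any(is.na(out$pos))) {
    abort(paste0("malformed POS at VCF data line(s): ",
                 paste(which(is.na(out$pos)), collapse = ", ")))
  }
  ann <- str_extract_ann(fix$INFO)
  if (any(!is.na(ann))) out$ann <- ann

  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  gq_raw <- suppressWarnings(vcfR::extract.gt(vcf, element = "GQ", as.numeric = TRUE))
  dp_raw <- suppressWarnings(vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))
  ad_raw <- vcfR::extract.gt(vcf, element = "AD")

  for (i in seq_len(nrow(map))) {
    key <- sample_id(map$strain[i], map$platform[i])
    s <- map$sample[i]
    gt <- if (!is.null(gt_raw) && s %in% colnames(gt_raw)) gt_raw[, s] else rep(NA_character_, n)
    out[[paste0("gt_", key)]] <- normalize_gt(gt)
    gq <- if (!is.null(gq_raw) && s %in% colnames(gq_raw)) as.integer(gq_raw[, s]) else rep(NA_integer_, n)
    out[[paste0("gq_", key)]] <- gq
    dp <- if (!is.null(dp_raw) && s %in% colnames(dp_raw)) as.integer(dp_raw[, s]) else rep(NA_integer_, n)
    out[[paste0("dp_", key)]] <- dp
    ad <- if (!is.null(ad_raw) && s %in% colnames(ad_raw)) ad_raw[, s] else rep(NA_character_, n)
    out[[paste0("ad_", key)]] <- parse_ad(ad)
  }
  new_joint_variants(out)
}

str_extract_ann <- function(info) {
  if (is.null(info)) return(rep(NA_character_, 0))
  m <- regmatches(info, regexpr("ANN=[^;]+", info))
  out <- rep(NA_character_, length(info))
  has <- grepl("ANN=", info, fixed = TRUE)
  out[has] <- sub("^ANN=", "", m)
  out
}

parse_ad <- function(ad) {
  lapply(unname(ad), function(a) {
    if (is.na(a) || a == ".") return(integer(0))
    suppressWarnings(as.integer(strsplit(a, ",", fixed = TRUE)[[1]]))
  })
}

# Effective per-sample depth: DP, falling back to sum(AD), else 0.
effective_depth <- function(variants) {
  keys <- as.vector(outer(STRAINS, PLATFORMS, sample_id))
  depth <- matrix(0L, nrow = nrow(variants), ncol = length(keys),
                  dimnames = list(NULL, keys))
  for (key in keys) {
    dp <- variants[[paste0("dp_", key)]]
    ad_sum <- vapply(variants[[paste0("ad_", key)]],
                     function(a) sum(a, na.rm = TRUE), numeric(1))
    depth[, key] <- as.integer(ifelse(!is.na(dp), dp, ad_sum))
  }
  depth
}

#' Write a joint call set (optionally a strain x zygosity subset) to VCF
#'
#' Emits VCF 4.2 with the original REF/ALT and GT:GQ:DP:AD per-sample
#' fields, records sorted by chromosome and position. Output is
#' gzip-compressed; use a `.vcf.gz` path. When `strain`/`zygosity` are
#' given, the input must carry `carrier_strain` and `zygosity` columns
#' (as produced by [run_pipeline()]) and only matching records are written.
#'
#' @param variants A `joint_variants` tibble (possibly with final-call
#'   columns).
#' @param path Output path (`.vcf.gz`).
#' @param strain,zygosity Optional subset selectors (`"WLI"`/`"WMI"`,
#'   `"hom"`/`"het"`).
#' @return The path, invisibly.
#' @export
write_joint_vcf <- function(variants, path, strain = NULL, zygosity = NULL) {
  df <- as_tibble(variants)
  if (!is.null(strain)) {
    if (!"carrier_strain" %in% names(df)) abort("strain subset requires a carrier_strain column")
    df <- df[!is.na(df$carrier_strain) & df$carrier_strain == strain, ]
  }
  if (!is.null(zygosity)) {
    if (!"zygosity" %in% names(df)) abort("zygosity subset requires a zygosity column")
    df <- df[!is.na(df$zygosity) & df$zygosity == zygosity, ]
  }
  df <- df[order(chrom_rank(df$chrom), df$chrom, df$pos), ]

  keys <- as.vector(outer(STRAINS, PLATFORMS, sample_id))
  meta <- c(
    "##fileformat=VCFv4.2",
    "##source=isofilter",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##INFO=<ID=ANN,Number=.,Type=String,Description=\"Functional annotations\">"
  )
  n <- nrow(df)
  info <- rep(".", n)
  if ("ann" %in% names(df)) {
    has <- !is.na(df$ann) & df$ann != ""
    info[has] <- paste0("ANN=", df$ann[has])
  }
  fix <- matrix(".", nrow = n, ncol = 8,
                dimnames = list(NULL, c("CHROM", "POS", "ID", "REF", "ALT",
                                        "QUAL", "FILTER", "INFO")))
  fix[, "CHROM"] <- df$chrom
  fix[, "POS"] <- as.character(df$pos)
  fix[, "REF"] <- df$ref
  fix[, "ALT"] <- df$alt
  fix[, "INFO"] <- info

  gt <- matrix("", nrow = n, ncol = length(keys) + 1,
               dimnames = list(NULL, c("FORMAT", keys)))
  gt[, "FORMAT"] <- "GT:GQ:DP:AD"
  for (key in keys) {
    g <- df[[paste0("gt_", key)]]
    gq <- df[[paste0("gq_", key)]]
    dp <- df[[paste0("dp_", key)]]
    ad <- vapply(df[[paste0("ad_", key)]], function(a) {
      if (length(a) == 0) "." else paste(a, collapse = ",")
    }, character(1))
    gt[, key] <- paste(g,
                       ifelse(is.na(gq), ".", as.character(gq)),
                       ifelse(is.na(dp), ".", as.character(dp)),
                       ad, sep = ":")
  }
  out <- new("vcfR", meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(out, file = path)
  invisible(path)
}
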