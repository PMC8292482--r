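# SnpEff ANN-field parsing and annotation aggregation.
#
# The ANN INFO field holds comma-separated entries, each pipe-delimited:
# Allele | Annotation | Impact | Gene_Name | Gene_ID | ... . Compound
# effects are '&'-joined inside the Annotation sub-field; the first
# listed term is the primary category used for tabulation, while the
# full compound string is preserved for impact reports.

IMPACT_LEVELS <- c("HIGH", "MODERATE", "LOW", "MODIFIER")

# "splice_donor_variant&intron_variant" -> "Splice donor variant & intron
# variant". Only the first character is upcased so acronyms (UTR) survive.
effect_label <- function(effect) {
  s <- gsub("&", " & ", gsub("_", " ", effect), fixed = TRUE)
  paste0(toupper(substr(s, 1, 1)), substr(s, 2, nchar(s)))
}

#' Parse SnpEff annotations from a joint call set
#'
#' Expands the raw `ann` column into one row per annotation entry.
#' Malformed entries (fewer than 5 pipe-delimited sub-fields, or an
#' unknown impact level) are skipped with a warning, never silently.
#'
#' @param variants A tibble with `chrom`, `pos` and an `ann` column
#'   (raw ANN strings as read by [read_joint_vcf()]); other columns are
#'   carried through.
#' @return A tibble with one row per (variant, annotation): the input
#'   columns plus `allele`, `effect` (full, possibly '&'-joined, raw
#'   terms), `primary_effect` (first term), `effect_label` /
#'   `primary_label` (human-readable), `impact`, `gene_name`, `gene_id`.
#' @export
parse_ann <- function(variants) {
  df <- as_tibble(variants)
  if (!"ann" %in% names(df)) abort("parse_ann requires an ann column")
  entries <- str_split(ifelse(is.na(df$ann), "", df$ann), ",")
  n_bad <- 0L
  rows <- lapply(seq_len(nrow(df)), function(i) {
    ents <- entries[[i]]
    ents <- ents[nzchar(ents)]
    if (length(ents) == 0) return(NULL)
    parsed <- lapply(ents, function(e) {
      f <- strsplit(e, "|", fixed = TRUE)[[1]]
      if (length(f) < 5 || !nzchar(f[2]) || !(f[3] %in% IMPACT_LEVELS)) {
        n_bad <<- n_bad + 1L
        return(NULL)
      }
      tibble(allele = f[1], effect = f[2], impact = f[3],
             gene_name = f[4], gene_id = f[5])
    })
    parsed <- bind_rows(parsed)
    if (nrow(parsed) == 0) return(NULL)
    parsed$.variant_row <- i
    parsed
  })
  out <- bind_rows(rows)
  if (n_bad > 0) {
    warn(paste0("skipped ", n_bad, " malformed ANN entr",
                if (n_bad == 1) "y" else "ies"))
  }
  if (nrow(out) == 0) {
    return(tibble(allele = character(0), effect = character(0),
                  impact = character(0), gene_name = character(0),
                  gene_id = character(0)))
  }
  carried <- df[out$.variant_row, setdiff(names(df), "ann"), drop = FALSE]
  out$.variant_row <- NULL
  res <- bind_cols(carried, out)
  res$primary_effect <- map_chr(str_split(res$effect, "&"), 1)
  res$effect_label <- effect_label(res$effect)
  res$primary_label <- effect_label(res$primary_effect)
  res
}

annotation_strain <- function(df) {
  if ("strain" %in% names(df)) return(df$strain)
  if ("carrier_strain" %in% names(df)) return(df$carrier_strain)
  abort("annotations need a strain or carrier_strain column")
}

#' Tabulate annotation effect categories per strain
#'
#' Counts one assignment per unique (variant, primary effect category)
#' pair per strain — a variant annotated with several categories
#' contributes to each of them, so column totals can exceed the number of
#' unique variants. Unknown categories are counted under their own name
#' (the vocabulary is open).
#'
#' @param annotations Output of [parse_ann()] (or any tibble with
#'   `chrom`, `pos`, `primary_effect` / `primary_label` and a strain
#'   column).
#' @return An `effect_table`: tibble with `effect`, one count column per
#'   strain, sorted alphabetically, plus a `Total` row.
#' @export
tabulate_effects <- function(annotations) {
  df <- as_tibble(annotations)
  df$strain <- annotation_strain(df)
  label <- if ("primary_label" %in% names(df)) df$primary_label
           else effect_label(df$primary_effect)
  df$.label <- label
  counts <- df |>
    distinct(.data$strain, .data$chrom, .data$pos, .data$.label) |>
    count(.data$.label, .data$strain, name = "n") |>
    tidyr::pivot_wider(names_from = "strain", values_from = "n",
                       values_fill = 0L) |>
    rename(effect = ".label") |>
    arrange(.data$effect)
  for (s in STRAINS) if (!s %in% names(counts)) counts[[s]] <- 0L
  counts <- counts[, c("effect", STRAINS)]
  totals <- tibble(effect = "Total",
                   WLI = sum(counts$WLI), WMI = sum(counts$WMI))
  out <- bind_rows(counts, totals)
  class(out) <- c("effect_table", class(out))
  out
}

#' Extract high- and moderate-impact variants
#'
#' One row per variant carrying a HIGH or MODERATE annotation, keeping its
#' highest-impact annotation (HIGH before MODERATE; ties broken by
#' annotation order) with the full compound effect string preserved.
#' Rows are sorted by strain, then chromosome and position.
#'
#' @param annotations Output of [parse_ann()].
#' @return Tibble `strain`, `chrom`, `pos`, `alt`, `gene_name`,
#'   `gene_id`, `impact`, `modification` (readable effect string).
#' @export
extract_high_moderate <- function(annotations) {
  df <- as_tibble(annotations)
  df$strain <- annotation_strain(df)
  df <- df |> filter(.data$impact %in% c("HIGH", "MODERATE"))
  if (nrow(df) == 0) {
    return(tibble(strain = character(0), chrom = character(0),
                  pos = integer(0), alt = character(0),
                  gene_name = character(0), gene_id = character(0),
                  impact = character(0), modification = character(0)))
  }
  df$impact <- factor(df$impact, levels = c("HIGH", "MODERATE"))
  df |>
    group_by(.data$strain, .data$chrom, .data$pos) |>
    arrange(.data$impact, .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup() |>
    mutate(impact = as.character(.data$impact),
           modification = .data$effect_label) |>
    select("strain", "chrom", "pos",
           dplyr::any_of("alt"), "gene_name", "gene_id",
           "impact", "modification") |>
    arrange(.data$strain, chrom_rank(.data$chrom), .data$chrom, .data$pos)
}

#' Nearest-gene set arithmetic across strains
#'
#' @param annotations Output of [parse_ann()], or any tibble with a
#'   strain column and `gene_id` (falls back to `gene_name`).
#' @return A `gene_set_summary` list: per-strain unique gene sets and
#'   counts, `shared` (intersection size) and `union_size`
#'   (|WLI| + |WMI| - shared).
#' @export
gene_set_summary <- function(annotations) {
  df <- as_tibble(annotations)
  df$strain <- annotation_strain(df)
  key <- if ("gene_id" %in% names(df)) df$gene_id else df$gene_name
  df$.gene <- key
  df <- df |> filter(!is.na(.data$.gene) & nzchar(.data$.gene))
  sets <- lapply(setNames(STRAINS, STRAINS),
                 function(s) unique(df$.gene[df$strain == s]))
  shared <- length(intersect(sets$WLI, sets$WMI))
  structure(list(
    genes_per_strain = sets,
    n_per_strain = lengths(sets),
    shared = shared,
    union_size = length(sets$WLI) + length(sets$WMI) - shared
  ), class = "gene_set_summary")
}

#' @export
print.gene_set_summary <- function(x, ...) {
  cat("<gene_set_summary> WLI:", x$n_per_strain[["WLI"]],
      "WMI:", x$n_per_strain[["WMI"]],
      "shared:", x$shared, "union:", x$union_size, "\n")
  invisible(x)
}

#' @method glance gene_set_summary
#' @export
glance.gene_set_summary <- function(x, ...) {
  tibble(n_WLI = x$n_per_strain[["WLI"]], n_WMI = x$n_per_strain[["WMI"]],
         shared = x$shared, union_size = x$union_size)
}

#' Overlap of annotated variants with an external gene list
#'
#' Restricts annotations to variants whose annotated gene is in the
#' supplied list (symbols matched against `gene_name`, identifiers
#' against `gene_id`) and counts unique variants per primary effect
#' category. Upstream/downstream proximity is whatever window the
#' annotator used (5 kb upstream in the reference workflow); it is not
#' recomputed from coordinates.
#'
#' @param annotations Output of [parse_ann()].
#' @param gene_list Character vector of gene symbols or IDs, or a path to
#'   a one-symbol-per-line text file.
#' @return Tibble `effect`, `n`, plus a `Total` row.
#' @export
overlap_with_gene_list <- function(annotations, gene_list) {
  if (length(gene_list) == 1 && file.exists(gene_list)) {
    gene_list <- readr::read_lines(gene_list)
  }
  gene_list <- unique(gene_list[nzchar(gene_list)])
  df <- as_tibble(annotations)
  if (length(gene_list) == 0 || nrow(df) == 0) {
    return(tibble(effect = "Total", n = 0L))
  }
  hit <- df$gene_name %in% gene_list | df$gene_id %in% gene_list
  df <- df[hit, , drop = FALSE]
  label <- if ("primary_label" %in% names(df)) df$primary_label
           else effect_label(df$primary_effect)
  df$.label <- label
  counts <- df |>
    distinct(.data$chrom, .data$pos, .data$.label) |>
    count(.data$.label, name = "n") |>
    rename(effect = ".label") |>
    arrange(dplyr::desc(.data$n))
  bind_rows(counts, tibble(effect = "Total", n = sum(counts$n)))
}
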