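# Binned density tracks and sliding-window cluster detection.
#
# Positions are 1-based; bins are half-open [k*bin + 1, (k+1)*bin] in
# 1-based terms, i.e. genomic interval [k*bin, (k+1)*bin) 0-based — a
# variant at exactly a bin boundary belongs to the right-hand bin.

#' Bin variant positions into a density track
#'
#' @param variants Tibble with `chrom` and `pos` columns.
#' @param bin_size Bin width in bp.
#' @param exclude Chromosomes to drop (e.g. `"Y"`).
#' @param smooth_window Odd window width for an optional centred moving
#'   average (`NULL` for none); added as a `smoothed` column, bins at the
#'   chromosome edges average over the available bins.
#' @return A `density_track` tibble: `chrom`, `bin` (0-based index),
#'   `start`, `end` (0-based half-open), `count`, optionally `smoothed`.
#' @export
bin_density <- function(variants, bin_size = 1e6, exclude = character(0),
                        smooth_window = NULL) {
  stopifnot(bin_size > 0)
  df <- as_tibble(variants) |>
    filter(!.data$chrom %in% normalize_chrom(exclude))
  out <- df |>
    mutate(bin = (.data$pos - 1L) %/% as.integer(bin_size)) |>
    count(.data$chrom, .data$bin, name = "count") |>
    group_by(.data$chrom) |>
    dplyr::group_modify(function(d, key) {
      full <- tibble(bin = 0:max(d$bin))
      left_join(full, d, by = "bin") |>
        mutate(count = ifelse(is.na(.data$count), 0L, .data$count))
    }) |>
    ungroup() |>
    mutate(start = .data$bin * bin_size,
           end = (.data$bin + 1) * bin_size) |>
    select("chrom", "bin", "start", "end", "count") |>
    arrange(chrom_rank(.data$chrom), .data$chrom, .data$bin)
  if (!is.null(smooth_window)) {
    stopifnot(smooth_window %% 2 == 1)
    half <- (smooth_window - 1) / 2
    out <- out |>
      group_by(.data$chrom) |>
      mutate(smoothed = vapply(seq_along(.data$count), function(i) {
        lo <- max(1, i - half); hi <- min(length(.data$count), i + half)
        mean(.data$count[lo:hi])
      }, numeric(1))) |>
      ungroup()
  }
  class(out) <- c("density_track", class(out))
  attr(out, "bin_size") <- bin_size
  out
}

#' Find dense variant clusters with a sliding window
#'
#' Slides a `window_bp`-wide window over each chromosome; every window
#' holding at least `min_count` variants is a hit, and overlapping hits
#' are merged into one region reporting the maximum window count.
#'
#' @param variants Tibble with `chrom` and `pos`.
#' @param window_bp Window width in bp (positions `p` with
#'   `start <= p < start + window_bp` fall in a window).
#' @param min_count Minimum variants per window.
#' @return Tibble `chrom`, `start`, `end` (1-based positions of the first
#'   and last variant in the merged region), `count` (max single-window
#'   count).
#' @export
find_clusters <- function(variants, window_bp = 1000, min_count = 5) {
  df <- as_tibble(variants) |> arrange(.data$chrom, .data$pos)
  out <- df |>
    group_by(.data$chrom) |>
    dplyr::group_modify(function(d, key) {
      pos <- sort(d$pos)
      n <- length(pos)
      hits <- list()
      for (i in seq_len(n)) {
        in_win <- which(pos >= pos[i] & pos < pos[i] + window_bp)
        if (length(in_win) >= min_count) {
          hits[[length(hits) + 1]] <- tibble(
            start = pos[i], end = pos[max(in_win)], count = length(in_win))
        }
      }
      if (length(hits) == 0) {
        return(tibble(start = integer(0), end = integer(0), count = integer(0)))
      }
      merge_windows(bind_rows(hits))
    }) |>
    ungroup()
  out
}

# Merge overlapping [start, end] hit windows; keep the max count per region.
merge_windows <- function(hits) {
  hits <- hits[order(hits$start), ]
  regions <- list()
  cur <- hits[1, ]
  for (i in seq_len(nrow(hits))[-1]) {
    h <- hits[i, ]
    if (h$start <= cur$end) {
      cur$end <- max(cur$end, h$end)
      cur$count <- max(cur$count, h$count)
    } else {
      regions[[length(regions) + 1]] <- cur
      cur <- h
    }
  }
  regions[[length(regions) + 1]] <- cur
  bind_rows(regions)
}

#' Export a density track as bedGraph
#'
#' @param track A `density_track` from [bin_density()].
#' @param path Output path.
#' @param column Which column to export (`"count"` or `"smoothed"`).
#' @return The path, invisibly.
#' @export
write_bedgraph <- function(track, path, column = "count") {
  gr <- GenomicRanges::GRanges(
    seqnames = track$chrom,
    ranges = IRanges::IRanges(start = track$start + 1L, end = track$end),
    score = as.numeric(track[[column]])
  )
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Export cluster regions as BED
#'
#' Internal 1-based inclusive regions are converted to BED's 0-based
#' half-open convention.
#'
#' @param clusters Output of [find_clusters()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_bed <- function(clusters, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = clusters$chrom,
    ranges = IRanges::IRanges(start = clusters$start, end = clusters$end),
    score = as.numeric(clusters$count)
  )
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Density-track panel plot
#'
#' @param object A `density_track`.
#' @param ... Unused.
#' @return A ggplot of binned counts per chromosome.
#' @method autoplot density_track
#' @export
autoplot.density_track <- function(object, ...) {
  y <- if ("smoothed" %in% names(object)) "smoothed" else "count"
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$start / 1e6, y = .data[[y]])) +
    ggplot2::geom_step(colour = "firebrick") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = paste0("variants per bin (", y, ")"),
                  title = "Variant density") +
    ggplot2::theme_minimal()
}
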