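# Reference-sequence access and homopolymer context.
#
# References are held in memory as a Biostrings::DNAStringSet keyed by
# (chr-prefix-stripped) chromosome name; at the scale this package targets
# (synthetic or per-region sequence) an indexed on-disk FASTA is not needed.

#' Load a reference FASTA
#'
#' @param path Path to a FASTA file.
#' @return A `DNAStringSet` with normalized (no `chr` prefix) names.
#' @export
read_reference <- function(path) {
  ref <- Biostrings::readDNAStringSet(path)
  # FASTA headers may carry descriptions after the first whitespace
  names(ref) <- normalize_chrom(sub("\\s.*$", "", names(ref)))
  ref
}

ref_sequence <- function(ref, chrom) {
  chrom <- normalize_chrom(chrom)
  if (!chrom %in% names(ref)) {
    abort(paste0("chromosome not in reference: ", chrom))
  }
  ref[[chrom]]
}

#' Is a deletion embedded in a homopolymer run?
#'
#' Tests whether every deleted base of a VCF-style deletion (ALT is a
#' prefix of REF, position anchored one base before the deleted interval)
#' lies inside a run of at least `min_run` identical reference bases. The
#' run is evaluated on the reference sequence spanning the deleted interval
#' plus one flanking base on each side, so a deleted base counts as
#' homopolymeric when it matches either neighbour within that window.
#'
#' @param ref A `DNAStringSet` reference (see [read_reference()]).
#' @param chrom Chromosome name.
#' @param pos 1-based position of the record (the anchor base).
#' @param ref_allele,alt_allele REF and ALT strings; must describe a
#'   deletion (`nchar(ref_allele) > nchar(alt_allele)`).
#' @param min_run Minimum run length that counts as homopolymeric.
#' @return `TRUE` if the whole deleted interval is homopolymeric.
#' @examples
#' ref <- Biostrings::DNAStringSet(c(`1` = "AATTTGC"))
#' homopolymer_context(ref, "1", 2, "AT", "A")  # deletes one T of TTT
#' @export
homopolymer_context <- function(ref, chrom, pos, ref_allele, alt_allele,
                                min_run = 2) {
  if (nchar(ref_allele) <= nchar(alt_allele)) {
    abort("homopolymer_context expects a deletion (REF longer than ALT)")
  }
  if (substr(ref_allele, 1, nchar(alt_allele)) != alt_allele) {
    abort("ALT must be a prefix of REF for a VCF-style deletion")
  }
  seq <- ref_sequence(ref, chrom)
  del_start <- pos + nchar(alt_allele)
  del_end <- pos + nchar(ref_allele) - 1L
  if (pos < 1 || del_end > length(seq)) {
    abort(paste0("deletion outside reference bounds: ", chrom, ":", pos))
  }
  win_start <- max(1L, del_start - 1L)
  win_end <- min(length(seq), del_end + 1L)
  window <- strsplit(as.character(Biostrings::subseq(seq, win_start, win_end)), "")[[1]]
  runs <- rle(window)
  run_len_at <- rep(runs$lengths, runs$lengths)
  del_idx <- (del_start:del_end) - win_start + 1L
  all(run_len_at[del_idx] >= min_run)
}

#' Maximal homopolymer runs of a reference
#'
#' @param ref A `DNAStringSet`.
#' @param min_run Minimum run length to report.
#' @return A tibble with columns `chrom`, `start`, `end`, `length`, `base`
#'   (1-based inclusive coordinates).
#' @export
homopolymer_runs <- function(ref, min_run = 2) {
  out <- imap(as.list(ref), function(seq, chrom) {
    chars <- strsplit(as.character(seq), "")[[1]]
    runs <- rle(chars)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    keep <- runs$lengths >= min_run
    tibble(chrom = chrom, start = starts[keep], end = ends[keep],
           length = runs$lengths[keep], base = runs$values[keep])
  })
  bind_rows(out)
}
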