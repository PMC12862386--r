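#' Read / write crosslink tracks and peaks as BED6
#'
#' Crosslink sites are single-nucleotide BED6 records (`name = "site"`,
#' score = cDNA count); peaks are interval records with the summed count as
#' score. BED is 0-based half-open, matching the package's internal
#' convention, so coordinates pass through unchanged.
#'
#' @param track Crosslink tibble (`chrom`, `pos`, `strand`, `count`).
#' @param peaks Peak tibble (`chrom`, `start`, `end`, `strand`, `score`,
#'   `fdr`, `gene_id`).
#' @param path File path.
#' @return Readers return tibbles; writers return `path` invisibly.
#' @export
write_track_bed <- function(track, path) {
  validate_track(track)
  readr::write_tsv(
    tibble(chrom = track$chrom, start = track$pos, end = track$pos + 1L,
           name = "site", score = track$count, strand = track$strand),
    path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_track_bed
#' @export
read_track_bed <- function(path) {
  df <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "name",
                                            "score", "strand"),
                        col_types = "ciicic", progress = FALSE)
  check_strand(df$strand)
  tibble(chrom = df$chrom, pos = df$start, strand = df$strand,
         count = as.integer(df$score))
}

#' @rdname write_track_bed
#' @export
write_peaks_bed <- function(peaks, path) {
  readr::write_tsv(
    tibble(chrom = peaks$chrom, start = peaks$start, end = peaks$end,
           name = if ("gene_id" %in% names(peaks)) peaks$gene_id else "peak",
           score = peaks$score, strand = peaks$strand),
    path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_track_bed
#' @export
read_peaks_bed <- function(path) {
  df <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "name",
                                            "score", "strand"),
                        col_types = "ciicdc", progress = FALSE)
  check_strand(df$strand)
  tibble(chrom = df$chrom, start = df$start, end = df$end,
         strand = df$strand, score = df$score, fdr = NA_real_,
         gene_id = df$name)
}
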