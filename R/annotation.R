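#' Genome annotation container
#'
#' A lightweight container for a synthetic or imported gene annotation.
#' All coordinates are 0-based half-open, one convention throughout the
#' package; GTF files are converted on ingest/egress.
#'
#' @param genes Tibble with columns `gene_id`, `chrom`, `strand`,
#'   `gene_biotype` (one of `"protein_coding"`, `"lncRNA"`).
#' @param transcripts Tibble with columns `tx_id`, `gene_id`.
#' @param exons Tibble with columns `tx_id`, `gene_id`, `chrom`, `strand`,
#'   `exon_rank` (transcriptional order, 1 = 5'-most exon), `start`, `end`.
#' @param cds Tibble with columns `tx_id`, `gene_id`, `chrom`, `strand`,
#'   `start`, `end` giving the genomic span of the coding region (absent
#'   rows for non-coding transcripts).
#'
#' @return An object of class `genome_annotation`.
#' @export
genome_annotation <- function(genes, transcripts, exons, cds = NULL) {
  genes <- as_tibble(genes)
  transcripts <- as_tibble(transcripts)
  exons <- as_tibble(exons)
  if (is.null(cds)) {
    cds <- tibble(tx_id = character(), gene_id = character(),
                  chrom = character(), strand = character(),
                  start = integer(), end = integer())
  }
  cds <- as_tibble(cds)
  check_strand(genes$strand)
  if (any(exons$end <= exons$start)) abort("Exons must have end > start.")
  # exons within a transcript must be non-overlapping and ordered
  bad <- exons |>
    arrange(.data$tx_id, .data$start) |>
    group_by(.data$tx_id) |>
    summarise(ok = all(.data$start[-1] >= .data$end[-n()]) || n() == 1L,
              .groups = "drop") |>
    filter(!.data$ok)
  if (nrow(bad)) {
    abort(sprintf("Overlapping exons in transcript(s): %s.",
                  paste(utils::head(bad$tx_id, 3), collapse = ", ")))
  }
  structure(list(genes = genes, transcripts = transcripts,
                 exons = exons, cds = cds),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("<genome_annotation>\n")
  cat("  genes:      ", nrow(x$genes), "\n")
  cat("  transcripts:", nrow(x$transcripts), "\n")
  cat("  exons:      ", nrow(x$exons), "\n")
  cat("  CDS spans:  ", nrow(x$cds), "\n")
  invisible(x)
}

#' Per-gene genic region table
#'
#' Decomposes every gene into non-overlapping region pieces used both by the
#' crosslink simulator and by peak biotype annotation: `CDS`, `UTR5`, `UTR3`
#' and `intron` for protein-coding genes, `noncoding` (exonic) and `intron`
#' for lncRNAs.
#'
#' @param annotation A [genome_annotation()].
#' @return Tibble with columns `gene_id`, `gene_biotype`, `chrom`, `strand`,
#'   `start`, `end`, `region`.
#' @export
gene_regions <- function(annotation) {
  stopifnot(inherits(annotation, "genome_annotation"))
  ex <- annotation$exons |>
    left_join(annotation$genes |> select("gene_id", "gene_biotype"),
              by = "gene_id")
  cds <- annotation$cds

  exonic <- ex |>
    left_join(cds |> select("tx_id", cds_start = "start", cds_end = "end"),
              by = "tx_id")

  pieces <- exonic |>
    group_by(.data$tx_id) |>
    group_split_regions()

  introns <- extract_introns(annotation) |>
    left_join(annotation$genes |> select("gene_id", "gene_biotype"),
              by = "gene_id") |>
    mutate(region = "intron") |>
    select("gene_id", "gene_biotype", "chrom", "strand", "start", "end",
           "region")

  bind_rows(pieces, introns) |>
    arrange(.data$chrom, .data$start)
}

# Split each exon of a transcript into CDS/UTR pieces (coding) or label it
# noncoding; vectorised over the grouped exon table.
group_split_regions <- function(grouped) {
  purrr::map_dfr(dplyr::group_rows(grouped), function(idx) {
    d <- dplyr::ungroup(grouped)[idx, ]
    if (is.na(d$cds_start[1])) {
      return(d |> mutate(region = "noncoding") |>
               select("gene_id", "gene_biotype", "chrom", "strand",
                      "start", "end", "region"))
    }
    cs <- d$cds_start[1]; ce <- d$cds_end[1]
    strand <- d$strand[1]
    out <- purrr::map_dfr(seq_len(nrow(d)), function(i) {
      s <- d$start[i]; e <- d$end[i]
      segs <- list()
      if (s < cs) segs <- c(segs, list(c(s, min(e, cs), 1L)))   # genomic-left UTR
      if (max(s, cs) < min(e, ce)) {
        segs <- c(segs, list(c(max(s, cs), min(e, ce), 0L)))    # CDS
      }
      if (e > ce) segs <- c(segs, list(c(max(s, ce), e, 2L)))   # genomic-right UTR
      purrr::map_dfr(segs, \(x) tibble(start = x[1], end = x[2], side = x[3]))
    })
    out$region <- dplyr::case_when(
      out$side == 0L ~ "CDS",
      (out$side == 1L) == (strand == "+") ~ "UTR5",
      TRUE ~ "UTR3"
    )
    out |>
      mutate(gene_id = d$gene_id[1], gene_biotype = d$gene_biotype[1],
             chrom = d$chrom[1], strand = strand) |>
      select("gene_id", "gene_biotype", "chrom", "strand", "start", "end",
             "region")
  })
}

#' Extract unique introns from an annotation
#'
#' Introns are the gaps between consecutive exons of each transcript,
#' deduplicated over (chrom, start, end, strand).
#'
#' @param annotation A [genome_annotation()].
#' @return Tibble with columns `chrom`, `start`, `end`, `strand`, `gene_id`,
#'   `length`.
#' @export
extract_introns <- function(annotation) {
  stopifnot(inherits(annotation, "genome_annotation"))
  ex <- annotation$exons |> arrange(.data$tx_id, .data$start)
  bad <- ex |>
    group_by(.data$tx_id) |>
    summarise(ok = n() == 1L || all(.data$start[-1] >= .data$end[-n()]),
              .groups = "drop") |>
    filter(!.data$ok)
  if (nrow(bad)) {
    abort(sprintf("Malformed transcript(s) with overlapping exons: %s.",
                  paste(utils::head(bad$tx_id, 3), collapse = ", ")))
  }
  ints <- ex |>
    group_by(.data$tx_id) |>
    summarise(
      chrom = .data$chrom[1], strand = .data$strand[1],
      gene_id = .data$gene_id[1],
      intron_start = if (n() > 1L) list(.data$end[-n()]) else list(integer()),
      intron_end = if (n() > 1L) list(.data$start[-1]) else list(integer()),
      .groups = "drop"
    ) |>
    tidyr::unnest(c("intron_start", "intron_end")) |>
    rename(start = "intron_start", end = "intron_end")
  ints |>
    distinct(.data$chrom, .data$start, .data$end, .data$strand,
             .keep_all = TRUE) |>
    mutate(length = .data$end - .data$start) |>
    select("chrom", "start", "end", "strand", "gene_id", "length") |>
    arrange(.data$chrom, .data$start)
}

#' Write / read an annotation as GTF
#'
#' `write_annotation_gtf()` serialises gene/transcript/exon/CDS features;
#' `read_annotation_gtf()` rebuilds the [genome_annotation()] (coordinates
#' converted between GTF 1-based closed and the internal 0-based half-open
#' convention by rtracklayer).
#'
#' @param annotation A [genome_annotation()].
#' @param path File path.
#' @return `write_annotation_gtf()` returns `path` invisibly;
#'   `read_annotation_gtf()` returns a [genome_annotation()].
#' @export
write_annotation_gtf <- function(annotation, path) {
  rows <- list()
  g <- annotation$genes
  tx <- annotation$transcripts |>
    left_join(g, by = "gene_id")
  tx_span <- annotation$exons |>
    group_by(.data$tx_id) |>
    summarise(start = min(.data$start), end = max(.data$end),
              .groups = "drop")
  tx <- tx |> left_join(tx_span, by = "tx_id")
  gene_span <- tx |>
    group_by(.data$gene_id) |>
    summarise(start = min(.data$start), end = max(.data$end),
              .groups = "drop")
  g2 <- g |> left_join(gene_span, by = "gene_id")

  feat <- function(df, type, tx_id = NA_character_) {
    GenomicRanges::GRanges(
      seqnames = df$chrom,
      ranges = IRanges::IRanges(df$start + 1L, df$end),
      strand = df$strand,
      type = type,
      gene_id = df$gene_id,
      transcript_id = if ("tx_id" %in% names(df)) df$tx_id else NA_character_,
      gene_biotype = if ("gene_biotype" %in% names(df)) df$gene_biotype
                     else NA_character_
    )
  }
  gr <- c(
    feat(g2, "gene"),
    feat(tx, "transcript"),
    feat(annotation$exons |>
           left_join(g |> select("gene_id", "gene_biotype"), by = "gene_id"),
         "exon"),
    if (nrow(annotation$cds))
      feat(annotation$cds |>
             left_join(g |> select("gene_id", "gene_biotype"), by = "gene_id"),
           "CDS")
  )
  # CDS phase is irrelevant downstream; silence the exporter's reminder
  suppressWarnings(rtracklayer::export(gr, path, format = "gtf"))
  invisible(path)
}

#' @rdname write_annotation_gtf
#' @export
read_annotation_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as_tibble(as.data.frame(gr)) |>
    mutate(chrom = as.character(.data$seqnames),
           strand = as.character(.data$strand),
           start = .data$start - 1L)   # back to 0-based half-open
  genes <- df |> filter(.data$type == "gene") |>
    select("gene_id", "chrom", "strand", "gene_biotype") |>
    distinct()
  transcripts <- df |> filter(.data$type == "transcript") |>
    select(tx_id = "transcript_id", "gene_id") |>
    distinct()
  exons <- df |> filter(.data$type == "exon") |>
    select(tx_id = "transcript_id", "gene_id", "chrom", "strand",
           "start", "end") |>
    group_by(.data$tx_id) |>
    arrange(.data$start, .by_group = TRUE) |>
    mutate(exon_rank = if (.data$strand[1] == "+") row_number()
                       else rev(row_number())) |>
    ungroup() |>
    mutate(start = as.integer(.data$start), end = as.integer(.data$end))
  cds <- df |> filter(.data$type == "CDS") |>
    group_by(tx_id = .data$transcript_id) |>
    summarise(gene_id = .data$gene_id[1], chrom = .data$chrom[1],
              strand = .data$strand[1],
              start = as.integer(min(.data$start)),
              end = as.integer(max(.data$end)), .groups = "drop")
  genome_annotation(genes, transcripts, exons, cds)
}
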