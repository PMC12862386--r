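#' Subtract isotype-control crosslink sites
#'
#' Removes from a protein track every site whose (chrom, pos, strand) key is
#' present in the control replicates; surviving counts are unchanged. The
#' default removes sites present in *any* control replicate (the union of
#' IgG positions); `mode = "all"` removes only sites present in every
#' control replicate.
#'
#' @param protein_track Crosslink tibble (`chrom`, `pos`, `strand`, `count`).
#' @param control_tracks A single control tibble or a list of them.
#' @param mode `"union"` (default) or `"all"`.
#' @return Filtered crosslink tibble.
#' @export
subtract_control <- function(protein_track, control_tracks,
                             mode = c("union", "all")) {
  mode <- match.arg(mode)
  validate_track(protein_track)
  if (is.data.frame(control_tracks)) control_tracks <- list(control_tracks)
  if (!length(control_tracks)) return(protein_track)
  purrr::walk(control_tracks, validate_track)
  keys <- purrr::map(control_tracks, \(t) t |> select("chrom", "pos", "strand"))
  drop <- if (mode == "union") {
    bind_rows(keys) |> distinct()
  } else {
    Reduce(\(a, b) inner_join(a, b, by = c("chrom", "pos", "strand")),
           purrr::map(keys, distinct))
  }
  anti_join(protein_track, drop, by = c("chrom", "pos", "strand"))
}

#' Merge replicate crosslink tracks
#'
#' Collapses a list of per-replicate tracks into a single track with one
#' record per (chrom, pos, strand) and the count summed across replicates.
#'
#' @param tracks Non-empty list of crosslink tibbles (a single tibble is
#'   accepted).
#' @return Merged crosslink tibble.
#' @export
merge_replicates <- function(tracks) {
  if (is.data.frame(tracks)) tracks <- list(tracks)
  if (!length(tracks)) abort("`tracks` must contain at least one track.")
  purrr::walk(tracks, validate_track)
  bind_rows(tracks) |>
    group_by(.data$chrom, .data$pos, .data$strand) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    arrange(.data$chrom, .data$pos) |>
    mutate(count = as.integer(.data$count))
}

#' Permutation peak scorer
#'
#' Assigns crosslink sites to genes, scores each site by the summed counts
#' in a +/- `half_window` neighbourhood on the same gene and strand, and
#' estimates a per-site FDR by randomly re-placing the gene's site counts
#' across all of the gene's positions `n_perm` times: for an observed score
#' `s`, `FDR(s)` is the permutation-expected number of sites scoring at
#' least `s` divided by the observed number, capped at 1 and made monotone
#' non-increasing in `s`. Adjacent FDR-passing sites within `half_window`
#' of each other are merged into peaks spanning them; a peak's score is the
#' summed count of all sites in the span and its FDR the minimum site FDR.
#'
#' Sites outside every annotated gene are dropped (their number is
#' reported with a message). Sites overlapping several same-strand genes go
#' to the gene with the longest genomic transcript span, ties broken
#' lexicographically by `gene_id`.
#'
#' @param track Crosslink tibble.
#' @param annotation A [genome_annotation()].
#' @param half_window Neighbourhood half-width in nt (default 3).
#' @param n_perm Number of permutations (>= 100).
#' @param fdr_cutoff Site FDR threshold used for peak merging.
#' @param seed Optional seed.
#'
#' @return Peak tibble: `chrom`, `start`, `end`, `strand`, `score`, `fdr`,
#'   `gene_id`.
#' @export
score_peaks <- function(track, annotation, half_window = 3L, n_perm = 1000L,
                        fdr_cutoff = 0.05, seed = NULL) {
  stopifnot(inherits(annotation, "genome_annotation"))
  validate_track(track)
  if (n_perm < 100) abort("`n_perm` must be >= 100.")
  if (!nrow(track)) return(empty_peaks())

  assigned <- assign_sites_to_genes(track, annotation)
  n_dropped <- nrow(track) - nrow(assigned)
  if (n_dropped > 0) {
    rlang::inform(sprintf("%d site(s) outside all genes dropped.", n_dropped))
  }
  if (!nrow(assigned)) return(empty_peaks())

  with_seed_if(seed, {
    assigned |>
      group_by(.data$gene_id) |>
      dplyr::group_map(\(d, key) score_gene_sites(d, key$gene_id, half_window,
                                                  n_perm, fdr_cutoff)) |>
      bind_rows() |>
      arrange(.data$chrom, .data$start)
  })
}

assign_sites_to_genes <- function(track, annotation) {
  spans <- annotation$exons |>
    group_by(.data$gene_id) |>
    summarise(chrom = .data$chrom[1], strand = .data$strand[1],
              start = min(.data$start), end = max(.data$end),
              .groups = "drop") |>
    mutate(span_len = .data$end - .data$start)
  gr_genes <- intervals_to_granges(spans)
  gr_sites <- sites_to_granges(track)
  hits <- GenomicRanges::findOverlaps(gr_sites, gr_genes, ignore.strand = FALSE)
  if (!length(hits)) return(track[0, ] |> mutate(gene_id = character(),
                                                 gene_start = integer(),
                                                 gene_end = integer()))
  h <- tibble(site = S4Vectors::queryHits(hits),
              gene = S4Vectors::subjectHits(hits)) |>
    mutate(gene_id = spans$gene_id[.data$gene],
           span_len = spans$span_len[.data$gene],
           gene_start = spans$start[.data$gene],
           gene_end = spans$end[.data$gene]) |>
    arrange(.data$site, dplyr::desc(.data$span_len), .data$gene_id) |>
    distinct(.data$site, .keep_all = TRUE)
  track[h$site, ] |>
    mutate(gene_id = h$gene_id, gene_start = h$gene_start,
           gene_end = h$gene_end)
}

# Neighbourhood sums for sorted positions via cumulative counts.
window_scores <- function(pos, counts, w) {
  o <- order(pos)
  p <- pos[o]; cnt <- counts[o]
  cs <- c(0, cumsum(cnt))
  lo <- findInterval(p - w - 0.5, p)
  hi <- findInterval(p + w + 0.5, p)
  s <- (cs[hi + 1L] - cs[lo + 1L])[order(o)]
  s
}

score_gene_sites <- function(d, gene_id, w, n_perm, fdr_cutoff) {
  k <- nrow(d)
  L <- max(d$gene_end[1] - d$gene_start[1], k)
  obs <- window_scores(d$pos, d$count, w)
  counts <- d$count
  perm_scores <- unlist(lapply(seq_len(n_perm), function(i) {
    pp <- sample.int(L, k, replace = FALSE)
    window_scores(pp, counts, w)
  }), use.names = FALSE)

  sorted_perm <- sort(perm_scores)
  sorted_obs <- sort(obs)
  uniq <- sort(unique(obs))
  exp_ge <- (length(sorted_perm) -
               findInterval(uniq - 0.5, sorted_perm)) / n_perm
  obs_ge <- length(sorted_obs) - findInterval(uniq - 0.5, sorted_obs)
  fdr_u <- pmin(1, exp_ge / obs_ge)
  # monotone non-increasing in score: take the running min from high scores
  fdr_u <- rev(cummin(rev(fdr_u)))
  fdr <- fdr_u[match(obs, uniq)]

  sig <- fdr < fdr_cutoff
  if (!any(sig)) return(empty_peaks())
  dd <- d |> mutate(fdr = fdr) |> arrange(.data$pos)
  sig_idx <- which(dd$fdr < fdr_cutoff)
  sp <- dd$pos[sig_idx]
  grp <- cumsum(c(1L, diff(sp) > w))
  purrr::map_dfr(split(sig_idx, grp), function(idx) {
    s0 <- min(dd$pos[idx]); e0 <- max(dd$pos[idx]) + 1L
    span_sites <- dd$pos >= s0 & dd$pos < e0
    tibble(chrom = dd$chrom[1], start = s0, end = e0,
           strand = dd$strand[1],
           score = sum(dd$count[span_sites]),
           fdr = min(dd$fdr[idx]), gene_id = gene_id)
  })
}

#' Filter peaks on score and FDR
#'
#' Retains peaks with `score > min_score` (strict) and `fdr < max_fdr`
#' (strict), the thresholds used to define highly significant peaks.
#'
#' @param peaks Peak tibble.
#' @param min_score Exclusive score threshold (default 5).
#' @param max_fdr Exclusive FDR threshold (default 0.05).
#' @return Filtered peak tibble.
#' @export
filter_peaks <- function(peaks, min_score = 5, max_fdr = 0.05) {
  peaks |> filter(.data$score > min_score, .data$fdr < max_fdr)
}

#' Annotate peaks with RNA biotypes
#'
#' Assigns each peak one region class by fixed precedence
#' CDS > 3'UTR > 5'UTR > intron > noncoding > intergenic (same-strand
#' overlap of at least one nucleotide), and reports class proportions over
#' all peaks plus, for intronic peaks, the host-gene biotype split
#' (pre-mRNA vs lncRNA).
#'
#' @param peaks Peak tibble.
#' @param annotation A [genome_annotation()].
#' @return Object of class `biotype_assignment`: list with `assignments`
#'   (per-peak tibble), `proportions` and `intronic_host` tibbles.
#' @export
annotate_biotypes <- function(peaks, annotation) {
  stopifnot(inherits(annotation, "genome_annotation"))
  display <- c(CDS = "CDS", UTR3 = "3'UTR", UTR5 = "5'UTR",
               intron = "intron", noncoding = "noncoding")
  precedence <- c("CDS", "UTR3", "UTR5", "intron", "noncoding")
  if (!nrow(peaks)) {
    out <- list(assignments = peaks |> mutate(biotype = character()),
                proportions = tibble(biotype = character(), n = integer(),
                                     proportion = numeric()),
                intronic_host = tibble(host_biotype = character(),
                                       n = integer(), proportion = numeric()))
    return(structure(out, class = "biotype_assignment"))
  }
  regions <- gene_regions(annotation)
  gr_reg <- intervals_to_granges(regions)
  gr_pk <- intervals_to_granges(peaks)
  hits <- GenomicRanges::findOverlaps(gr_pk, gr_reg, ignore.strand = FALSE)
  h <- tibble(pk = S4Vectors::queryHits(hits),
              reg = S4Vectors::subjectHits(hits)) |>
    mutate(region = regions$region[.data$reg],
           gene_id = regions$gene_id[.data$reg],
           gene_biotype = regions$gene_biotype[.data$reg],
           prio = match(.data$region, precedence)) |>
    arrange(.data$pk, .data$prio) |>
    distinct(.data$pk, .keep_all = TRUE)

  assignments <- peaks |>
    mutate(.row = row_number()) |>
    left_join(h |> select(".row" = "pk", "region", host_gene = "gene_id",
                          host_biotype = "gene_biotype"),
              by = ".row") |>
    mutate(biotype = dplyr::coalesce(unname(display[.data$region]),
                                     "intergenic")) |>
    select(-".row", -"region")

  proportions <- assignments |>
    dplyr::count(.data$biotype, name = "n") |>
    mutate(proportion = .data$n / sum(.data$n)) |>
    arrange(dplyr::desc(.data$n))

  intronic_host <- assignments |>
    filter(.data$biotype == "intron") |>
    mutate(host = if_else(.data$host_biotype == "protein_coding",
                          "pre-mRNA", "lncRNA")) |>
    dplyr::count(host_biotype = .data$host, name = "n") |>
    mutate(proportion = .data$n / sum(.data$n))

  structure(list(assignments = assignments, proportions = proportions,
                 intronic_host = intronic_host),
            class = "biotype_assignment")
}

#' @export
print.biotype_assignment <- function(x, ...) {
  cat("<biotype_assignment> ", nrow(x$assignments), "peaks\n")
  print(x$proportions)
  invisible(x)
}

#' Splice-junction metaprofiles of crosslink density
#'
#' Accumulates crosslink counts at strand-aware offsets around every
#' annotated intron-exon (3'SS) and exon-intron (5'SS) junction and
#' normalises each profile to counts per million (CPM). Offset 0 is the
#' first exonic nucleotide at the 3'SS and the first intronic nucleotide at
#' the 5'SS; negative offsets are transcriptionally upstream.
#'
#' @param track Crosslink tibble.
#' @param annotation A [genome_annotation()].
#' @param flank Window half-width in nt (> 0).
#' @return Tibble of class `junction_profile` with columns `junction`
#'   (`"intron-exon"` / `"exon-intron"`), `offset`, `count`, `cpm`.
#' @export
junction_metaprofile <- function(track, annotation, flank = 100L) {
  stopifnot(inherits(annotation, "genome_annotation"))
  if (flank <= 0) abort("`flank` must be > 0.")
  validate_track(track)
  introns <- extract_introns(annotation)
  plus <- introns$strand == "+"
  j3 <- tibble(chrom = introns$chrom, strand = introns$strand,
               pos = if_else(plus, introns$end, introns$start - 1L),
               junction = "intron-exon")
  j5 <- tibble(chrom = introns$chrom, strand = introns$strand,
               pos = if_else(plus, introns$start, introns$end - 1L),
               junction = "exon-intron")
  juncs <- bind_rows(j3, j5)

  grid <- tidyr::expand_grid(junction = c("intron-exon", "exon-intron"),
                             offset = seq(-flank, flank))
  if (!nrow(track) || !nrow(juncs)) {
    out <- grid |> mutate(count = 0L, cpm = 0)
    return(structure(out, class = c("junction_profile", class(out)),
                     flank = flank))
  }

  gr_j <- GenomicRanges::GRanges(juncs$chrom,
                                 IRanges::IRanges(juncs$pos + 1L - flank,
                                                  juncs$pos + 1L + flank),
                                 strand = juncs$strand)
  gr_s <- sites_to_granges(track)
  hits <- GenomicRanges::findOverlaps(gr_s, gr_j, ignore.strand = FALSE)
  acc <- tibble(site = S4Vectors::queryHits(hits),
                j = S4Vectors::subjectHits(hits)) |>
    mutate(junction = juncs$junction[.data$j],
           offset = if_else(juncs$strand[.data$j] == "+",
                            track$pos[.data$site] - juncs$pos[.data$j],
                            juncs$pos[.data$j] - track$pos[.data$site]),
           count = track$count[.data$site]) |>
    group_by(.data$junction, .data$offset) |>
    summarise(count = sum(.data$count), .groups = "drop")

  out <- grid |>
    left_join(acc, by = c("junction", "offset")) |>
    mutate(count = dplyr::coalesce(.data$count, 0L)) |>
    group_by(.data$junction) |>
    mutate(cpm = if (sum(.data$count) > 0)
                   .data$count / sum(.data$count) * 1e6 else 0) |>
    ungroup()
  structure(out, class = c("junction_profile", class(out)), flank = flank)
}
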