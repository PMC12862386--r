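#' Simulate skipped-exon events with planted binding association
#'
#' Draws cassette-exon (SE) trios from the annotation, assigns each event a
#' P-value and inclusion-level difference (hence a splicing-change metric
#' `|dPSI| * -log10(P)`), and generates a nearby-binding indicator from a
#' logistic model with a planted slope on that metric. Bound events receive
#' a peak inside the event window (3' end of the upstream exon to 5' end of
#' the downstream exon); unbound events receive none.
#'
#' @param annotation A [genome_annotation()]; only transcripts with >= 3
#'   exons contribute trios.
#' @param n_events Number of events (<= available exon trios).
#' @param frac_bound_nearby Target fraction of events with a nearby peak
#'   (the logistic intercept is solved to hit it on average).
#' @param slope Planted log-odds slope of binding on the splicing metric.
#' @param n_reps Replicates per condition for the junction-count columns.
#' @param seed Optional seed.
#'
#' @return List with `events` (rMATS SE junction-count layout), `peaks`
#'   (BED6-style peak tibble) and `truth` (per-event metric and bound flag).
#' @export
sim_splice_events <- function(annotation, n_events = 200L,
                              frac_bound_nearby = 0.3, slope = 0,
                              n_reps = 3L, seed = NULL) {
  stopifnot(inherits(annotation, "genome_annotation"))
  trios <- exon_trios(annotation)
  if (n_events > nrow(trios)) {
    abort(sprintf("`n_events` (%d) exceeds available exon trios (%d).",
                  n_events, nrow(trios)))
  }
  with_seed_if(seed, {
    ev <- trios[sample.int(nrow(trios), n_events), ]
    dpsi <- runif(n_events, -0.6, 0.6)
    p <- runif(n_events)^3
    metric <- abs(dpsi) * (-log10(pmax(p, 1e-300)))

    bound <- if (frac_bound_nearby >= 1) {
      rep(TRUE, n_events)
    } else if (frac_bound_nearby <= 0) {
      rep(FALSE, n_events)
    } else {
      b0 <- solve_intercept(metric, slope, frac_bound_nearby)
      runif(n_events) < stats::plogis(b0 + slope * metric)
    }

    # junction counts consistent with psi in the two conditions
    psi1 <- pmin(1, pmax(0, 0.5 + dpsi / 2))
    psi2 <- pmin(1, pmax(0, 0.5 - dpsi / 2))
    cnt <- function(psi) {
      vapply(psi, function(pp) {
        tot <- stats::rpois(n_reps, 30) + 2L
        inc <- rbinom(n_reps, tot, pp)
        paste(inc, collapse = ",")
      }, character(1))
    }
    cnt_s <- function(psi) {
      vapply(psi, function(pp) {
        tot <- stats::rpois(n_reps, 30) + 2L
        paste(tot - rbinom(n_reps, tot, pp), collapse = ",")
      }, character(1))
    }

    events <- tibble(
      ID = seq_len(n_events),
      GeneID = ev$gene_id, geneSymbol = ev$gene_id,
      chr = ev$chrom, strand = ev$strand,
      exonStart_0base = ev$ex_start, exonEnd = ev$ex_end,
      upstreamES = ev$up_start, upstreamEE = ev$up_end,
      downstreamES = ev$down_start, downstreamEE = ev$down_end,
      IJC_SAMPLE_1 = cnt(psi1), SJC_SAMPLE_1 = cnt_s(psi1),
      IJC_SAMPLE_2 = cnt(psi2), SJC_SAMPLE_2 = cnt_s(psi2),
      IncFormLen = 100L, SkipFormLen = 50L,
      PValue = p, FDR = p.adjust(p, "BH"),
      IncLevel1 = vapply(psi1, \(x) paste(rep(round(x, 3), n_reps),
                                          collapse = ","), character(1)),
      IncLevel2 = vapply(psi2, \(x) paste(rep(round(x, 3), n_reps),
                                          collapse = ","), character(1)),
      IncLevelDifference = round(psi1 - psi2, 3)
    )

    # peaks land inside the cassette exon, hence inside the event window
    bi <- which(bound)
    peaks <- if (length(bi)) {
      right <- if_else(ev$up_start[bi] < ev$down_start[bi],
                       ev$down_start[bi], ev$up_start[bi])
      room <- pmax(1L, ev$ex_end[bi] - ev$ex_start[bi] - 5L)
      s <- ev$ex_start[bi] +
        as.integer(floor(runif(length(bi)) * room))
      tibble(chrom = ev$chrom[bi], start = s,
             end = pmin(s + 8L, right),
             strand = ev$strand[bi], score = 10, fdr = 0.01,
             gene_id = ev$gene_id[bi])
    } else {
      empty_peaks()
    }

    list(events = events, peaks = peaks,
         truth = tibble(ID = seq_len(n_events), metric = metric,
                        bound = bound))
  })
}

# All genomically-consecutive exon triples, with up/downstream resolved by
# strand (upstream = transcriptionally preceding exon).
exon_trios <- function(annotation) {
  annotation$exons |>
    group_by(.data$tx_id) |>
    arrange(.data$start, .by_group = TRUE) |>
    filter(n() >= 3L) |>
    summarise(
      gene_id = .data$gene_id[1], chrom = .data$chrom[1],
      strand = .data$strand[1],
      idx = list(seq_len(n() - 2L)),
      s = list(.data$start), e = list(.data$end),
      .groups = "drop"
    ) |>
    tidyr::unnest("idx") |>
    mutate(
      l_start = purrr::map2_int(.data$s, .data$idx, \(x, i) x[[i]]),
      l_end = purrr::map2_int(.data$e, .data$idx, \(x, i) x[[i]]),
      ex_start = purrr::map2_int(.data$s, .data$idx, \(x, i) x[[i + 1L]]),
      ex_end = purrr::map2_int(.data$e, .data$idx, \(x, i) x[[i + 1L]]),
      r_start = purrr::map2_int(.data$s, .data$idx, \(x, i) x[[i + 2L]]),
      r_end = purrr::map2_int(.data$e, .data$idx, \(x, i) x[[i + 2L]])
    ) |>
    mutate(
      up_start = if_else(.data$strand == "+", .data$l_start, .data$r_start),
      up_end = if_else(.data$strand == "+", .data$l_end, .data$r_end),
      down_start = if_else(.data$strand == "+", .data$r_start, .data$l_start),
      down_end = if_else(.data$strand == "+", .data$r_end, .data$l_end)
    ) |>
    select("gene_id", "chrom", "strand", "ex_start", "ex_end",
           "up_start", "up_end", "down_start", "down_end")
}

# Solve the logistic intercept so the mean bound probability hits `target`.
solve_intercept <- function(metric, slope, target) {
  f <- function(b0) mean(stats::plogis(b0 + slope * metric)) - target
  stats::uniroot(f, lower = -50, upper = 50)$root
}

#' Write an rMATS-style SE junction-count table
#'
#' @param events Event tibble as produced by [sim_splice_events()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_rmats_se <- function(events, path) {
  readr::write_tsv(events, path)
  invisible(path)
}
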