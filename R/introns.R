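#' Bound introns and summed peak scores
#'
#' An intron is bound when at least one peak overlaps it by >= 1 nt on the
#' same strand; its `summed_score` is the sum of the scores of all
#' overlapping peaks (a peak overlapping two introns contributes to both).
#'
#' @param peaks Peak tibble.
#' @param introns Intron tibble from [extract_introns()].
#' @return The bound subset of `introns` with a `summed_score` column.
#' @export
bound_introns <- function(peaks, introns) {
  if (!nrow(peaks) || !nrow(introns)) {
    return(introns[0, ] |> mutate(summed_score = numeric()))
  }
  gr_p <- intervals_to_granges(peaks)
  gr_i <- intervals_to_granges(introns)
  hits <- GenomicRanges::findOverlaps(gr_p, gr_i, ignore.strand = FALSE)
  if (!length(hits)) {
    return(introns[0, ] |> mutate(summed_score = numeric()))
  }
  sums <- tibble(intron = S4Vectors::subjectHits(hits),
                 score = peaks$score[S4Vectors::queryHits(hits)]) |>
    group_by(.data$intron) |>
    summarise(summed_score = sum(.data$score), .groups = "drop")
  introns[sums$intron, ] |>
    mutate(summed_score = sums$summed_score) |>
    arrange(.data$chrom, .data$start)
}

#' Length-weighted random control introns
#'
#' Samples `n` introns without replacement with per-draw selection
#' probability proportional to the remaining introns' lengths, the control
#' that accounts for longer introns being more likely to harbour peaks by
#' chance. `replace = TRUE` switches to with-replacement sampling.
#'
#' @param introns Intron tibble with a `length` column.
#' @param n Number of introns to draw (>= 1; <= nrow for
#'   without-replacement).
#' @param replace Sample with replacement.
#' @param seed Optional seed.
#' @return Tibble of sampled introns.
#' @export
sample_control_introns <- function(introns, n, replace = FALSE, seed = NULL) {
  if (!nrow(introns)) abort("`introns` must be nonempty.")
  if (n < 1) abort("`n` must be >= 1.")
  if (!replace && n > nrow(introns)) {
    abort("`n` exceeds the number of available introns.")
  }
  with_seed_if(seed, {
    idx <- sample.int(nrow(introns), n, replace = replace,
                      prob = introns$length)
    introns[idx, ]
  })
}

#' One-way ANOVA on log intron lengths
#'
#' Compares intron lengths across named groups (e.g. protein-bound,
#' IgG-bound, length-weighted random control) with a fixed-effects one-way
#' ANOVA on log10 length, the scale on which intron lengths are reported.
#'
#' @param groups Named list of intron tibbles (each with a `length`
#'   column) or of numeric length vectors; >= 2 groups, each n >= 2.
#' @param log_transform Use log10 lengths (default); `FALSE` tests raw
#'   lengths.
#' @return Object of class `intron_anova`: list with `statistic` (F),
#'   `df_between`, `df_within`, `p.value`, `group_means` tibble and the
#'   underlying per-intron data.
#' @export
compare_intron_lengths <- function(groups, log_transform = TRUE) {
  if (length(groups) < 2) abort("Need at least 2 groups.")
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  vals <- purrr::imap_dfr(groups, function(g, nm) {
    x <- if (is.data.frame(g)) g$length else g
    tibble(group = nm, length = as.numeric(x))
  })
  sizes <- table(vals$group)
  if (any(sizes < 2)) abort("Every group needs at least 2 members.")
  vals$y <- if (log_transform) log10(vals$length) else vals$length
  fit <- stats::aov(y ~ group, data = vals)
  an <- stats::anova(fit)
  res <- structure(list(
    statistic = an[["F value"]][1],
    df_between = an[["Df"]][1],
    df_within = an[["Df"]][2],
    p.value = an[["Pr(>F)"]][1],
    group_means = vals |>
      group_by(.data$group) |>
      summarise(n = n(), mean_log_length = mean(.data$y), .groups = "drop"),
    data = vals,
    log_transform = log_transform
  ), class = "intron_anova")
  res
}

#' @export
print.intron_anova <- function(x, ...) {
  cat(sprintf("<intron_anova> F(%d, %d) = %.4g, P = %.3g\n",
              x$df_between, x$df_within, x$statistic, x$p.value))
  print(x$group_means)
  invisible(x)
}
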