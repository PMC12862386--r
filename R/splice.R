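#' Read an rMATS skipped-exon junction-count table
#'
#' Parses the standard `SE.MATS.JC.txt` column layout (tab-separated,
#' rMATS 4.x headers). Coordinates stay 0-based as emitted by rMATS.
#' Comma-separated per-replicate junction counts are kept as strings; use
#' [total_junction_counts()] for their sum.
#'
#' @param path TSV path.
#' @return Tibble of events.
#' @export
read_rmats_se <- function(path) {
  df <- readr::read_tsv(
    path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      IJC_SAMPLE_1 = "c", SJC_SAMPLE_1 = "c",
      IJC_SAMPLE_2 = "c", SJC_SAMPLE_2 = "c",
      IncLevel1 = "c", IncLevel2 = "c", chr = "c", strand = "c"))
  required <- c("GeneID", "chr", "strand", "exonStart_0base", "exonEnd",
                "upstreamES", "upstreamEE", "downstreamES", "downstreamEE",
                "IJC_SAMPLE_1", "SJC_SAMPLE_1", "IJC_SAMPLE_2",
                "SJC_SAMPLE_2", "PValue", "FDR", "IncLevelDifference")
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    abort(sprintf("rMATS SE table is missing mandatory column(s): %s.",
                  paste(miss, collapse = ", ")))
  }
  bad <- which(!df$strand %in% c("+", "-"))
  if (length(bad)) {
    abort(sprintf("Malformed strand value in row(s): %s.",
                  paste(utils::head(bad, 5), collapse = ", ")))
  }
  df
}

#' Total inclusion + skipping junction counts per event
#'
#' Sums the comma-separated IJC and SJC replicate counts across all samples
#' of both conditions (per-condition totals available via `per_condition`).
#'
#' @param events rMATS SE tibble.
#' @param per_condition Return a two-column tibble of per-condition totals
#'   instead of one grand total.
#' @return Integer vector (or tibble).
#' @export
total_junction_counts <- function(events, per_condition = FALSE) {
  sum_csv <- function(x) vapply(strsplit(as.character(x), ","),
                                \(v) sum(as.numeric(v)), numeric(1))
  t1 <- sum_csv(events$IJC_SAMPLE_1) + sum_csv(events$SJC_SAMPLE_1)
  t2 <- sum_csv(events$IJC_SAMPLE_2) + sum_csv(events$SJC_SAMPLE_2)
  if (per_condition) tibble(condition1 = t1, condition2 = t2) else t1 + t2
}

#' Filter skipped-exon events on significance
#'
#' Keeps events with `FDR <= max_fdr` (inclusive), `|IncLevelDifference| >
#' min_dpsi` (strict) and total inclusion + skipping junction counts summed
#' over all samples `>= min_counts`. `per_sample = TRUE` instead requires
#' the count threshold in every sample-condition total.
#'
#' @param events rMATS SE tibble.
#' @param max_fdr FDR threshold (default 0.05, inclusive).
#' @param min_dpsi Absolute inclusion-difference threshold (default 0.1,
#'   exclusive).
#' @param min_counts Count threshold (default 10, inclusive).
#' @param per_sample Apply `min_counts` per condition rather than in total.
#' @return Filtered tibble.
#' @export
filter_splice_events <- function(events, max_fdr = 0.05, min_dpsi = 0.1,
                                 min_counts = 10, per_sample = FALSE) {
  if (!nrow(events)) return(events)
  if (per_sample) {
    tc <- total_junction_counts(events, per_condition = TRUE)
    ok_counts <- tc$condition1 >= min_counts & tc$condition2 >= min_counts
  } else {
    ok_counts <- total_junction_counts(events) >= min_counts
  }
  events |>
    filter(.data$FDR <= max_fdr,
           abs(.data$IncLevelDifference) > min_dpsi,
           ok_counts)
}

#' Event windows spanning the flanking exon boundaries
#'
#' For each event builds the stranded genomic interval from the 3' end of
#' the upstream exon to the 5' end of the downstream exon — genomically,
#' from the end of the left flanking exon to the start of the right
#' flanking exon — so the window always covers both flanking introns and
#' the cassette exon. Degenerate windows (start >= end) are flagged and
#' excluded.
#'
#' @param events rMATS SE tibble.
#' @return Tibble `chrom`, `start`, `end`, `strand` plus the event columns;
#'   excluded degenerate rows are dropped with a warning.
#' @export
event_window <- function(events) {
  if (!nrow(events)) {
    return(events |> mutate(start = integer(), end = integer(),
                            chrom = character()))
  }
  up_left <- events$upstreamES < events$downstreamES
  win_start <- if_else(up_left, events$upstreamEE, events$downstreamEE)
  win_end <- if_else(up_left, events$downstreamES, events$upstreamES)
  out <- events |>
    mutate(chrom = .data$chr, start = win_start, end = win_end)
  bad <- out$start >= out$end
  if (any(bad)) {
    warn(sprintf("%d degenerate event window(s) excluded.", sum(bad)))
    out <- out[!bad, ]
  }
  out
}

#' Splicing-change metric
#'
#' The product of absolute effect size and statistical significance,
#' `|IncLevelDifference| * -log10(P)`, with P floored at `p_floor` so that
#' zero P-values do not produce infinities.
#'
#' @param events rMATS SE tibble (or anything with `IncLevelDifference`
#'   and `PValue` columns).
#' @param p_floor Lower bound applied to P (default 1e-300).
#' @return Numeric vector of metric values.
#' @export
splice_metric <- function(events, p_floor = 1e-300) {
  if (p_floor <= 0) abort("`p_floor` must be > 0.")
  p <- events$PValue
  if (any(p < 0, na.rm = TRUE)) abort("P-values must be >= 0.")
  abs(events$IncLevelDifference) * (-log10(pmax(p, p_floor)))
}

#' Logistic association between splicing change and nearby binding
#'
#' Marks each event as bound when >= 1 peak overlaps its window on the same
#' strand, and fits `bound ~ splice_metric` by logistic regression
#' (iteratively reweighted least squares). Perfect separation — all events
#' bound, none bound, or a glm separation warning — yields a flagged result
#' with the Wald P omitted rather than an error.
#'
#' @param events rMATS SE tibble (>= 10 events).
#' @param peaks Peak tibble.
#' @param p_floor P floor passed to [splice_metric()].
#' @return Object of class `binding_assoc`: list with `slope`, `intercept`,
#'   their standard errors, `z`, `p.value`, `n`, `n_bound`, `separation`
#'   flag, and the per-event `data` tibble.
#' @export
fit_binding_association <- function(events, peaks, p_floor = 1e-300) {
  if (nrow(events) < 10) abort("Need at least 10 events.")
  win <- event_window(events)
  metric <- splice_metric(win, p_floor)
  bound <- rep(FALSE, nrow(win))
  if (nrow(peaks)) {
    gr_w <- intervals_to_granges(win)
    gr_p <- intervals_to_granges(peaks)
    hits <- GenomicRanges::findOverlaps(gr_w, gr_p, ignore.strand = FALSE)
    bound[unique(S4Vectors::queryHits(hits))] <- TRUE
  }
  dat <- tibble(metric = metric, bound = bound)
  if (all(bound) || !any(bound)) {
    return(structure(list(slope = NA_real_, intercept = NA_real_,
                          slope_se = NA_real_, intercept_se = NA_real_,
                          z = NA_real_, p.value = NA_real_,
                          n = nrow(dat), n_bound = sum(bound),
                          separation = TRUE, data = dat),
                     class = "binding_assoc"))
  }
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(bound ~ metric, family = stats::binomial(), data = dat,
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  cf <- summary(fit)$coefficients
  structure(list(slope = cf["metric", "Estimate"],
                 intercept = cf["(Intercept)", "Estimate"],
                 slope_se = cf["metric", "Std. Error"],
                 intercept_se = cf["(Intercept)", "Std. Error"],
                 z = cf["metric", "z value"],
                 p.value = if (sep) NA_real_ else cf["metric", "Pr(>|z|)"],
                 n = nrow(dat), n_bound = sum(bound),
                 separation = sep, data = dat),
            class = "binding_assoc")
}

#' @export
print.binding_assoc <- function(x, ...) {
  if (x$separation) {
    cat("<binding_assoc> perfect separation flagged;",
        sprintf("n = %d, bound = %d\n", x$n, x$n_bound))
  } else {
    cat(sprintf(
      "<binding_assoc> slope = %.4g (SE %.3g), Wald P = %.3g, n = %d (%d bound)\n",
      x$slope, x$slope_se, x$p.value, x$n, x$n_bound))
  }
  invisible(x)
}
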