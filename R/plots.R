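#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_col geom_histogram
#'   geom_vline geom_violin geom_point labs facet_wrap theme_minimal
#' @export
ggplot2::autoplot

#' Plot a junction metaprofile
#'
#' CPM crosslink density around intron-exon (3'SS) and exon-intron (5'SS)
#' junctions.
#'
#' @param object A `junction_profile` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.junction_profile <- function(object, ...) {
  ggplot(object, aes(x = .data$offset, y = .data$cpm)) +
    geom_line() +
    facet_wrap(~junction) +
    geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    labs(x = "offset from junction (nt)", y = "crosslink density (CPM)") +
    theme_minimal()
}

#' Plot a resampling null distribution
#'
#' Histogram of null overlaps with the observed overlap marked.
#'
#' @param object A `resampling_null`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.resampling_null <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$null_overlap)) +
    geom_histogram(binwidth = 1, fill = "grey70", colour = "white") +
    geom_vline(xintercept = object$observed_overlap, colour = "firebrick") +
    labs(x = "null overlap", y = "iterations",
         subtitle = sprintf("observed = %d, empirical P = %.3g",
                            object$observed_overlap, object$empirical_p)) +
    theme_minimal()
}

#' Plot biotype proportions
#'
#' Stacked-bar style summary of peak region classes.
#'
#' @param object A `biotype_assignment`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.biotype_assignment <- function(object, ...) {
  ggplot(object$proportions,
         aes(x = stats::reorder(.data$biotype, -.data$proportion),
             y = .data$proportion)) +
    geom_col(fill = "steelblue") +
    labs(x = NULL, y = "proportion of peaks") +
    theme_minimal()
}

#' Violin plot of intron log-lengths per group
#'
#' @param object An `intron_anova`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.intron_anova <- function(object, ...) {
  ggplot(object$data, aes(x = .data$group, y = .data$y)) +
    geom_violin(fill = "grey85") +
    labs(x = NULL,
         y = if (object$log_transform) "log10 intron length" else
           "intron length",
         subtitle = sprintf("ANOVA F = %.3g, P = %.3g",
                            object$statistic, object$p.value)) +
    theme_minimal()
}

#' Volcano plot of co-IP moderated tests
#'
#' @param object A `coip_classification`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.coip_classification <- function(object, ...) {
  if (is.null(object$tests) || !nrow(object$tests)) {
    abort("No tested proteins to plot.")
  }
  ggplot(object$tests,
         aes(x = .data$log2fc, y = -log10(.data$p.value),
             colour = .data$class3)) +
    geom_point(alpha = 0.7) +
    labs(x = "log2 fold-change (bait - control)", y = "-log10 P",
         colour = "class III") +
    theme_minimal()
}
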