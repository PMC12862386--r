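#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy and glance methods
#'
#' broom-style accessors for the package's fitted objects: per-component
#' tibbles via `tidy()`, one-row model summaries via `glance()`.
#'
#' @param x A fitted object (`resampling_null`, `binding_assoc`,
#'   `intron_anova`, `coip_classification`).
#' @param ... Unused.
#' @name rbpsuite-tidiers
NULL

#' @rdname rbpsuite-tidiers
#' @export
tidy.resampling_null <- function(x, ...) {
  tibble(iteration = seq_along(x$null_overlaps),
         null_overlap = x$null_overlaps)
}

#' @rdname rbpsuite-tidiers
#' @export
glance.resampling_null <- function(x, ...) {
  association_report(x)
}

#' @rdname rbpsuite-tidiers
#' @export
tidy.binding_assoc <- function(x, ...) {
  tibble(term = c("(Intercept)", "metric"),
         estimate = c(x$intercept, x$slope),
         std.error = c(x$intercept_se, x$slope_se),
         statistic = c(NA_real_, x$z),
         p.value = c(NA_real_, x$p.value))
}

#' @rdname rbpsuite-tidiers
#' @export
glance.binding_assoc <- function(x, ...) {
  tibble(slope = x$slope, slope_se = x$slope_se, p.value = x$p.value,
         n = x$n, n_bound = x$n_bound, separation = x$separation)
}

#' @rdname rbpsuite-tidiers
#' @export
tidy.intron_anova <- function(x, ...) {
  x$group_means
}

#' @rdname rbpsuite-tidiers
#' @export
glance.intron_anova <- function(x, ...) {
  tibble(statistic = x$statistic, df_between = x$df_between,
         df_within = x$df_within, p.value = x$p.value)
}

#' @rdname rbpsuite-tidiers
#' @export
tidy.coip_classification <- function(x, ...) {
  out <- x$classes
  if (!is.null(x$tests) && nrow(x$tests)) {
    out <- out |> left_join(x$tests, by = "protein")
  }
  out
}

#' @rdname rbpsuite-tidiers
#' @export
glance.coip_classification <- function(x, ...) {
  cls <- x$classes$class
  tibble(n_class_I = sum(cls == "I"), n_class_II = sum(cls == "II"),
         n_tested = sum(cls == "tested"),
         n_excluded = sum(cls == "excluded"),
         n_contaminant = sum(cls == "contaminant"),
         n_class_III = if (is.null(x$tests)) 0L else sum(x$tests$class3))
}
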