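#' Quantile abundance bins
#'
#' Partitions genes into `n_bins` near-equal abundance bins by sorting on
#' `mean_count`; when the bin sizes do not divide evenly the remainders go
#' to the lower-abundance bins. Bin 1 holds the lowest counts.
#'
#' @param results Tibble with columns `gene_id` and `mean_count`.
#' @param n_bins Number of bins (1 <= n_bins <= number of genes).
#' @return `results` with an integer `bin` column.
#' @export
bin_genes <- function(results, n_bins) {
  n <- nrow(results)
  if (n_bins < 1) abort("`n_bins` must be >= 1.")
  if (n_bins > n) abort("`n_bins` exceeds the number of genes.")
  sizes <- rep(n %/% n_bins, n_bins)
  rem <- n %% n_bins
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  ord <- order(results$mean_count)
  bin <- integer(n)
  bin[ord] <- rep(seq_len(n_bins), times = sizes)
  results |> mutate(bin = bin)
}

#' Abundance-binned resampling null for gene-set overlap
#'
#' Tests whether the overlap between differentially bound (iCLIP) and
#' differentially abundant (RNA-seq) genes exceeds chance, while respecting
#' the detection-power bias of abundance: genes are binned on their mean
#' counts separately per dataset; in each iteration, each dataset draws at
#' random (without replacement, within each of its own bins) as many genes
#' as it has significant genes in that bin, and the null overlap is the
#' intersection of the two draws. The empirical P-value uses the add-one
#' convention `(1 + #\{null >= observed\}) / (1 + n_iter)`, so it is never 0.
#'
#' @param binding,expression Tibbles with columns `gene_id`, `mean_count`
#'   and `significant` (logical), one row per gene; the two tables must
#'   cover the same genes.
#' @param n_bins Number of abundance bins (default 5).
#' @param n_iter Number of resampling iterations (>= 100; default 1000).
#' @param joint_bins Bin on the *binding* dataset's counts for both
#'   datasets instead of separately.
#' @param seed Optional seed.
#'
#' @return Object of class `resampling_null`: list with `observed_overlap`,
#'   `null_overlaps` (integer vector), `empirical_p`, `empirical_p_lesser`,
#'   `n_iter`, `n_bins`, `n_sig_binding`, `n_sig_expression`, `seed`.
#' @export
resample_overlap_null <- function(binding, expression, n_bins = 5L,
                                  n_iter = 1000L, joint_bins = FALSE,
                                  seed = NULL) {
  if (n_iter < 100) abort("`n_iter` must be >= 100.")
  if (!setequal(binding$gene_id, expression$gene_id)) {
    abort("`binding` and `expression` must cover the same genes.")
  }
  expression <- expression[match(binding$gene_id, expression$gene_id), ]
  n <- nrow(binding)
  b_binned <- bin_genes(binding, n_bins)
  e_binned <- if (joint_bins) expression |> mutate(bin = b_binned$bin)
              else bin_genes(expression, n_bins)

  sig_b <- binding$significant
  sig_e <- expression$significant
  observed <- sum(sig_b & sig_e)

  # per-bin member indices and significant counts, per dataset
  bins_b <- split(seq_len(n), b_binned$bin)
  bins_e <- split(seq_len(n), e_binned$bin)
  k_b <- vapply(bins_b, \(ix) sum(sig_b[ix]), integer(1))
  k_e <- vapply(bins_e, \(ix) sum(sig_e[ix]), integer(1))
  if (any(k_b > lengths(bins_b)) || any(k_e > lengths(bins_e))) {
    abort("Internal inconsistency: a bin's significant count exceeds its size.")
  }

  null_overlaps <- with_seed_if(seed, {
    vapply(seq_len(n_iter), function(i) {
      v1 <- logical(n); v2 <- logical(n)
      for (b in seq_along(bins_b)) {
        if (k_b[b] > 0) {
          v1[bins_b[[b]][sample.int(length(bins_b[[b]]), k_b[b])]] <- TRUE
        }
      }
      for (b in seq_along(bins_e)) {
        if (k_e[b] > 0) {
          v2[bins_e[[b]][sample.int(length(bins_e[[b]]), k_e[b])]] <- TRUE
        }
      }
      sum(v1 & v2)
    }, integer(1))
  })

  structure(list(
    observed_overlap = observed,
    null_overlaps = null_overlaps,
    empirical_p = (1 + sum(null_overlaps >= observed)) / (1 + n_iter),
    empirical_p_lesser = (1 + sum(null_overlaps <= observed)) / (1 + n_iter),
    n_iter = as.integer(n_iter), n_bins = as.integer(n_bins),
    n_sig_binding = sum(sig_b), n_sig_expression = sum(sig_e),
    seed = seed
  ), class = "resampling_null")
}

#' @export
print.resampling_null <- function(x, ...) {
  cat(sprintf(
    "<resampling_null> observed = %d, null mean = %.2f (sd %.2f), empirical P = %.4g\n",
    x$observed_overlap, mean(x$null_overlaps), sd(x$null_overlaps),
    x$empirical_p))
  invisible(x)
}

#' Summarise a resampling null
#'
#' Reports the observed overlap, the null mean and SD, the fold enrichment
#' `observed / max(null mean, eps)` and the empirical P-value. A degenerate
#' all-zero null is flagged.
#'
#' @param null A `resampling_null` object.
#' @param eps Guard for the fold denominator.
#' @return One-row tibble.
#' @export
association_report <- function(null, eps = 1e-9) {
  stopifnot(inherits(null, "resampling_null"))
  mu <- mean(null$null_overlaps)
  degenerate <- mu == 0
  if (degenerate && null$observed_overlap > 0) {
    warn("Null distribution is all zeros; fold enrichment uses the eps guard.")
  }
  tibble(observed = null$observed_overlap,
         null_mean = mu, null_sd = sd(null$null_overlaps),
         fold_enrichment = null$observed_overlap / max(mu, eps),
         empirical_p = null$empirical_p,
         degenerate_null = degenerate,
         n_iter = null$n_iter, n_bins = null$n_bins)
}
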