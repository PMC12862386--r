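test_that("bin_genes builds near-equal bins ordered by abundance", {
  res <- tibble::tibble(gene_id = paste0("g", 1:13),
                        mean_count = c(5, 1, 9, 3, 7, 2, 8, 4, 6, 10,
                                       11, 0.5, 12))
  b <- bin_genes(res, 5)
  expect_equal(sort(as.integer(table(b$bin)), decreasing = TRUE),
               c(3, 3, 3, 2, 2))
  # remainders go to the lower-abundance bins
  expect_equal(as.integer(table(b$bin)[c("1", "2", "3", "4", "5")]),
               c(3, 3, 3, 2, 2))
  # bins are monotone in abundance
  agg <- tapply(b$mean_count, b$bin, max)
  expect_true(all(diff(agg) > 0))
  expect_true(all(tapply(b$mean_count, b$bin, min)[-1] >
                    head(agg, -1)))
  expect_error(bin_genes(res, 14), "exceeds")
  expect_error(bin_genes(res, 0), ">= 1")
})

test_that("resampling null preserves per-bin significant counts", {
  ann <- flat_annotation(200)
  sim <- sim_de_tables(ann, frac_sig = 0.2, seed = 71)
  null <- resample_overlap_null(sim$binding, sim$expression, n_bins = 4,
                                n_iter = 100, seed = 72)
  expect_s3_class(null, "resampling_null")
  expect_length(null$null_overlaps, 100)
  expect_equal(null$n_sig_binding, sum(sim$binding$significant))
  expect_equal(null$observed_overlap,
               sum(sim$binding$significant & sim$expression$significant))
  # hand-check one iteration's mechanics: expected null mean under
  # within-bin uniformity equals sum_b k_b * k'_b' weighted overlap; just
  # verify the null stays within the attainable range
  expect_true(all(null$null_overlaps >= 0))
  expect_true(all(null$null_overlaps <= min(null$n_sig_binding,
                                            null$n_sig_expression)))
})

test_that("the empirical P uses the add-one convention and is never 0", {
  ann <- flat_annotation(150)
  sim <- sim_de_tables(ann, frac_sig = 0.3, joint_frac = 0.3, seed = 73)
  # joint_frac == frac_sig: every significant gene overlaps -> extreme obs
  null <- resample_overlap_null(sim$binding, sim$expression,
                                n_iter = 199, seed = 74)
  expect_gte(null$empirical_p, 1 / 200)
  expect_equal(null$empirical_p,
               (1 + sum(null$null_overlaps >= null$observed_overlap)) / 200)
})

test_that("binned null is calibrated under confounded independence", {
  # abundance-confounded but independent datasets: the naive hypergeometric
  # test is anti-conservative, the binned empirical P should be ~ uniform
  ann <- flat_annotation(600)
  pvals <- purrr::map_dbl(1:120, function(i) {
    sim <- sim_de_tables(ann, frac_sig = 0.15, seed = 7000 + i)
    null <- resample_overlap_null(sim$binding, sim$expression, n_bins = 5,
                                  n_iter = 199, seed = 8000 + i)
    null$empirical_p
  })
  expect_lt(mean(pvals < 0.05), 0.11)
  expect_gt(mean(pvals < 0.5), 0.3)
  expect_gt(mean(pvals), 0.4)
})

test_that("a planted joint fraction is detected", {
  ann <- flat_annotation(600)
  sim <- sim_de_tables(ann, frac_sig = 0.15, joint_frac = 0.08, seed = 75)
  null <- resample_overlap_null(sim$binding, sim$expression,
                                n_iter = 999, seed = 76)
  expect_lt(null$empirical_p, 0.01)
  rep <- association_report(null)
  expect_gt(rep$fold_enrichment, 1.5)
  expect_false(rep$degenerate_null)
})

test_that("joint_bins and gene-set mismatches are handled", {
  ann <- flat_annotation(100)
  sim <- sim_de_tables(ann, frac_sig = 0.2, seed = 77)
  null <- resample_overlap_null(sim$binding, sim$expression,
                                joint_bins = TRUE, n_iter = 100, seed = 78)
  expect_s3_class(null, "resampling_null")
  expect_error(
    resample_overlap_null(sim$binding[-1, ], sim$expression, n_iter = 100),
    "same genes")
  expect_error(
    resample_overlap_null(sim$binding, sim$expression, n_iter = 50),
    ">= 100")
})

test_that("degenerate all-zero nulls are flagged in the report", {
  binding <- tibble::tibble(gene_id = paste0("g", 1:100),
                            mean_count = 1:100,
                            significant = c(TRUE, rep(FALSE, 99)))
  expression <- tibble::tibble(gene_id = paste0("g", 1:100),
                               mean_count = 1:100,
                               significant = c(TRUE, rep(FALSE, 99)))
  null <- resample_overlap_null(binding, expression, n_bins = 100,
                                n_iter = 100, seed = 79)
  # one significant gene per dataset pinned to its own singleton bin:
  # every draw picks it, so the null is all ones, not degenerate
  expect_equal(unique(null$null_overlaps), 1L)
  # with coarse bins the same gene is rarely co-drawn; force degeneracy
  null2 <- resample_overlap_null(
    dplyr::mutate(binding, significant = FALSE), expression,
    n_iter = 100, seed = 80)
  expect_equal(unique(null2$null_overlaps), 0L)
  rep2 <- association_report(null2)
  expect_true(rep2$degenerate_null)
})

test_that("tidy/glance on resampling_null", {
  ann <- flat_annotation(80)
  sim <- sim_de_tables(ann, frac_sig = 0.2, seed = 81)
  null <- resample_overlap_null(sim$binding, sim$expression, n_iter = 100,
                                seed = 82)
  td <- generics::tidy(null)
  expect_equal(nrow(td), 100)
  gl <- generics::glance(null)
  expect_equal(gl$observed, null$observed_overlap)
  expect_equal(gl$empirical_p, null$empirical_p)
})

test_that("sim_de_tables plants confounding and joint structure as declared", {
  ann <- flat_annotation(3000)
  # confounding on: significant genes are abundance-shifted upward
  sim <- sim_de_tables(ann, frac_sig = 0.1, seed = 83)
  w <- stats::wilcox.test(sim$binding$mean_count[sim$binding$significant],
                          sim$binding$mean_count[!sim$binding$significant],
                          alternative = "greater")
  expect_lt(w$p.value, 1e-6)
  # confounding off, no joint fraction: overlap close to independence
  sim2 <- sim_de_tables(ann, frac_sig = 0.2, abundance_confounding = FALSE,
                        seed = 84)
  obs <- sum(sim2$binding$significant & sim2$expression$significant)
  expected <- 3000 * 0.2 * 0.2
  expect_lt(abs(obs - expected), 4 * sqrt(expected))
  # fractions are exact
  expect_equal(sum(sim2$binding$significant), 600)
  expect_error(sim_de_tables(ann, frac_sig = 0.1, joint_frac = 0.2),
               "cannot exceed")
  # planted joint genes are significant in both tables
  sim3 <- sim_de_tables(ann, frac_sig = 0.1, joint_frac = 0.05, seed = 85)
  joint <- sim3$truth$joint_genes
  expect_length(joint, 150)
  expect_true(all(sim3$binding$significant[match(joint,
                                                 sim3$binding$gene_id)]))
  expect_true(all(sim3$expression$significant[match(joint,
                                                    sim3$expression$gene_id)]))
})
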