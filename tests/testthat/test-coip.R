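pep_fixture <- function() {
  # 3 proteins x known peptides, plus a contaminant and a shared peptide
  tibble::tibble(
    peptide = c("a1", "a2", "b1", "b2", "c1", "k1", "s1"),
    protein = c("A", "A", "B", "B", "C", "KER", "A;B"),
    contaminant = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
    b1 = c(1000, 2000, 500, NA, 800, 100, 50),
    b2 = c(1100, 1900, 450, 600, NA, 100, 50),
    b3 = c(900, 2100, NA, 640, 820, 100, 50),
    c1 = c(NA, NA, 480, 610, 790, 100, 50),
    c2 = c(NA, NA, 470, NA, 805, 100, 50),
    c3 = c(NA, NA, 500, 630, 815, 100, 50))
}

test_that("aggregate_peptides filters, normalises and aggregates", {
  pm <- aggregate_peptides(pep_fixture())
  expect_s3_class(pm, "protein_matrix")
  # contaminant and multi-group peptides removed
  expect_setequal(pm$abundance$protein, c("A", "B", "C"))
  expect_equal(pm$contaminant_proteins, "KER")
  # diff.median: every sample's peptide-level median is the grand median
  usable <- pep_fixture() |>
    dplyr::filter(!contaminant, !grepl(";", protein))
  samples <- c("b1", "b2", "b3", "c1", "c2", "c3")
  logm <- log2(as.matrix(usable[samples]))
  med <- apply(logm, 2, median, na.rm = TRUE)
  target <- median(med)
  shifted <- sweep(logm, 2, med) + target
  # protein A in sample b1: median of its two shifted peptides
  want_A_b1 <- median(shifted[usable$protein == "A", "b1"], na.rm = TRUE)
  expect_equal(pm$abundance$b1[pm$abundance$protein == "A"], want_A_b1)
  # presence = any peptide observed
  expect_true(pm$presence$b2[pm$presence$protein == "B"])
  expect_false(pm$presence$c1[pm$presence$protein == "A"])
  expect_error(aggregate_peptides(dplyr::select(pep_fixture(), -b2)), "b2")
})

test_that("presence classes follow the I/II scheme", {
  pm <- aggregate_peptides(pep_fixture())
  cls <- classify_presence(pm)
  expect_equal(cls$class[cls$protein == "A"], "I")     # 3 bait, 0 control
  expect_equal(cls$class[cls$protein == "B"], "tested")
  expect_equal(cls$class[cls$protein == "C"], "tested")

  # class II: exactly 2 bait, 0 control
  pep <- pep_fixture() |>
    dplyr::mutate(b3 = dplyr::if_else(protein == "A", NA_real_, b3))
  cls2 <- classify_presence(aggregate_peptides(pep))
  expect_equal(cls2$class[cls2$protein == "A"], "II")
})

test_that("asymmetric eligibility excludes over-missing proteins", {
  pep <- pep_fixture() |>
    dplyr::mutate(b2 = dplyr::if_else(protein == "B", NA_real_, b2),
                  b3 = dplyr::if_else(protein == "B", NA_real_, b3))
  pm <- aggregate_peptides(pep)
  # B now misses 2 of 3 bait values -> excluded under bait_max_missing = 1
  imp <- impute_missing(pm, "minprob", proteins = c("B", "C"), seed = 1)
  expect_true("B" %in% imp$excluded)
  expect_false("C" %in% imp$excluded)
  # relaxing the bait limit readmits it
  imp2 <- impute_missing(pm, "minprob", proteins = c("B", "C"),
                         bait_max_missing = 2, seed = 1)
  expect_length(imp2$excluded, 0)
})

test_that("minprob draws from the low tail; knn averages neighbours", {
  sim <- sim_peptides(design = c(enriched = 10, null = 90), lfc = 2,
                      missing_rate = 0.35, seed = 101)
  pm <- aggregate_peptides(sim$peptides)
  imp <- impute_missing(pm, "minprob", seed = 102)
  m0 <- as.matrix(pm$abundance[c("b1", "b2", "b3", "c1", "c2", "c3")])
  m1 <- as.matrix(imp$abundance[c("b1", "b2", "b3", "c1", "c2", "c3")])
  expect_false(any(is.na(m1)))
  m0a <- m0[match(imp$abundance$protein, pm$abundance$protein), ,
            drop = FALSE]
  filled <- m1[is.na(m0a)]
  # imputed values sit in the low tail of the observed abundances
  expect_gt(length(filled), 10)
  expect_lt(mean(filled), quantile(m0, 0.25, na.rm = TRUE))

  imp_knn <- impute_missing(pm, "knn", seed = 103)
  mk <- as.matrix(imp_knn$abundance[c("b1", "b2", "b3", "c1", "c2", "c3")])
  expect_false(any(is.na(mk)))
  # knn fills stay within the observed range (means of observed values)
  expect_gte(min(mk), min(m0, na.rm = TRUE) - 1e-9)
  expect_lte(max(mk), max(m0, na.rm = TRUE) + 1e-9)
})

test_that("moderated test with d0 = 0 reproduces the ordinary pooled t", {
  withr::with_seed(111, {
    ab <- tibble::tibble(
      protein = paste0("P", 1:40),
      b1 = rnorm(40, 25), b2 = rnorm(40, 25), b3 = rnorm(40, 25),
      c1 = rnorm(40, 24.5), c2 = rnorm(40, 24.5), c3 = rnorm(40, 24.5))
  })
  groups <- setNames(rep(c("bait", "control"), each = 3),
                     c("b1", "b2", "b3", "c1", "c2", "c3"))
  res <- moderated_test(ab, groups, d0 = 0)
  i <- 7
  tt <- stats::t.test(as.numeric(ab[i, c("b1", "b2", "b3")]),
                      as.numeric(ab[i, c("c1", "c2", "c3")]),
                      var.equal = TRUE)
  expect_equal(res$t[i], unname(tt$statistic), tolerance = 1e-10)
  expect_equal(res$p.value[i], tt$p.value, tolerance = 1e-10)
  expect_equal(res$df[i], 4)
  expect_equal(res$adj.p.value, p.adjust(res$p.value, "BH"))
})

test_that("estimated shrinkage matches limma's empirical-Bayes moderation", {
  skip_if_not_installed("limma")
  sim <- sim_peptides(design = c(enriched = 15, null = 185), lfc = 1.5,
                      seed = 112)
  pm <- aggregate_peptides(sim$peptides)
  groups <- pm$groups
  ab <- pm$abundance
  res <- moderated_test(ab, groups)
  m <- as.matrix(ab[names(groups)])
  rownames(m) <- ab$protein
  design <- cbind(1, as.numeric(groups == "bait"))
  fit <- limma::eBayes(limma::lmFit(m, design))
  # hyperparameters agree up to estimator differences (both moment-match
  # the log sample variances; at d = 4 and n = 200 the prior df estimate
  # is noisy, so compare shrunk statistics rather than d0 itself)
  d0 <- attr(res, "d0")
  expect_true(d0 > 0)
  if (is.finite(d0) && is.finite(fit$df.prior)) {
    expect_lt(abs(log(d0) - log(fit$df.prior)), log(2))
  }
  expect_equal(attr(res, "s0_sq"), fit$s2.prior, tolerance = 0.25)
  expect_gt(cor(res$t, fit$t[res$protein, 2]), 0.99)
  # moderated P-values rank the enriched proteins the same way
  expect_gt(cor(rank(res$p.value), rank(fit$p.value[res$protein, 2])), 0.98)
})

test_that("classify_coip recovers a planted design end to end", {
  sim <- sim_peptides(design = c(I = 5, II = 3, enriched = 6, null = 86,
                                 contaminant = 2),
                      lfc = 2, seed = 113)
  cc <- classify_coip(sim$peptides, seed = 114)
  expect_s3_class(cc, "coip_classification")
  truth <- sim$truth
  got <- cc$classes
  expect_setequal(got$protein[got$class == "I"],
                  truth$protein[truth$class == "I"])
  expect_setequal(got$protein[got$class == "II"],
                  truth$protein[truth$class == "II"])
  expect_setequal(got$protein[got$class == "contaminant"],
                  truth$protein[truth$class == "contaminant"])
  # class III: the enriched set, at FDR control
  hits <- cc$tests$protein[cc$tests$class3]
  enriched <- truth$protein[truth$class == "enriched"]
  expect_gte(length(intersect(hits, enriched)), 5)
  expect_lte(length(setdiff(hits, enriched)), 1)
  # classes partition all proteins
  expect_equal(sort(got$protein), sort(truth$protein))
  expect_equal(anyDuplicated(got$protein), 0L)
  gl <- generics::glance(cc)
  expect_equal(gl$n_class_I, 5L)
  expect_equal(gl$n_class_II, 3L)
  expect_equal(gl$n_class_III, sum(cc$tests$class3))
})

test_that("negative enrichment is never class III", {
  sim <- sim_peptides(design = c(enriched = 8, null = 92), lfc = -2,
                      seed = 115)
  cc <- classify_coip(sim$peptides, seed = 116)
  expect_equal(sum(cc$tests$class3), 0L)
})

test_that("trigamma_inverse inverts trigamma", {
  for (y in c(0.05, 0.5, 2, 9, 40)) {
    x <- trigamma(y)
    expect_equal(rbpsuite:::trigamma_inverse(x), y, tolerance = 1e-6)
  }
})
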