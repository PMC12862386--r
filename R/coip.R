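#' Filter, normalise and aggregate peptide abundances
#'
#' Drops contaminant-flagged peptides and peptides mapping to more than one
#' protein group (semicolon-separated accessions), log2-transforms, applies
#' diff.median normalisation (each sample's log2 values shifted so its
#' median equals the grand median of sample medians) and aggregates to
#' protein level by the median of a protein's peptide values per sample.
#' A protein counts as "identified" in a sample when at least one of its
#' peptides is observed there.
#'
#' @param peptides Tibble with columns `peptide`, `protein`, `contaminant`
#'   and raw-scale sample columns (`NA`/blank = missing).
#' @param bait_cols,control_cols Sample column names.
#' @return Object of class `protein_matrix`: list with `abundance` (tibble,
#'   protein x sample log2 values), `presence` (logical tibble), `groups`
#'   (named vector), `contaminant_proteins` (accessions observed only with
#'   the contaminant flag).
#' @export
aggregate_peptides <- function(peptides,
                               bait_cols = c("b1", "b2", "b3"),
                               control_cols = c("c1", "c2", "c3")) {
  samples <- c(bait_cols, control_cols)
  miss <- setdiff(c("peptide", "protein", "contaminant", samples),
                  names(peptides))
  if (length(miss)) {
    abort(sprintf("Peptide table missing column(s): %s.",
                  paste(miss, collapse = ", ")))
  }
  contam <- setdiff(unique(peptides$protein[peptides$contaminant]),
                    unique(peptides$protein[!peptides$contaminant]))
  usable <- peptides |>
    filter(!.data$contaminant, !grepl(";", .data$protein))
  groups <- setNames(rep(c("bait", "control"),
                         c(length(bait_cols), length(control_cols))), samples)
  if (!nrow(usable)) {
    warn("No usable peptides after filtering.")
    ab <- tibble(protein = character())
    for (s in samples) ab[[s]] <- numeric()
    return(structure(list(abundance = ab, presence = ab, groups = groups,
                          contaminant_proteins = contam),
                     class = "protein_matrix"))
  }
  logm <- usable |>
    mutate(across(dplyr::all_of(samples), \(x) log2(as.numeric(x))))
  med <- vapply(samples, \(s) median(logm[[s]], na.rm = TRUE), numeric(1))
  target <- median(med)
  for (s in samples) logm[[s]] <- logm[[s]] - med[[s]] + target

  ab <- logm |>
    group_by(.data$protein) |>
    summarise(across(dplyr::all_of(samples),
                     \(x) if (all(is.na(x))) NA_real_
                          else median(x, na.rm = TRUE)),
              .groups = "drop")
  pres <- ab |>
    mutate(across(dplyr::all_of(samples), \(x) !is.na(x)))
  structure(list(abundance = ab, presence = pres, groups = groups,
                 contaminant_proteins = contam),
            class = "protein_matrix")
}

#' @export
print.protein_matrix <- function(x, ...) {
  cat("<protein_matrix>", nrow(x$abundance), "proteins x",
      length(x$groups), "samples\n")
  invisible(x)
}

#' Presence-based interactor classes
#'
#' Class I proteins are identified in all bait samples and no control
#' sample; class II in exactly `n_bait - 1` bait samples (two of three in
#' the standard design) and no control; everything else is a candidate for
#' statistical testing.
#'
#' @param pm A `protein_matrix`.
#' @return Tibble `protein`, `n_bait_detected`, `n_control_detected`,
#'   `class` (`"I"`, `"II"` or `"tested"`).
#' @export
classify_presence <- function(pm) {
  stopifnot(inherits(pm, "protein_matrix"))
  bait <- names(pm$groups)[pm$groups == "bait"]
  ctrl <- names(pm$groups)[pm$groups == "control"]
  pres <- pm$presence
  nb <- rowSums(as.matrix(pres[bait]))
  nc <- rowSums(as.matrix(pres[ctrl]))
  tibble(protein = pres$protein,
         n_bait_detected = nb, n_control_detected = nc,
         class = dplyr::case_when(
           nb == length(bait) & nc == 0 ~ "I",
           nb == length(bait) - 1L & nc == 0 ~ "II",
           TRUE ~ "tested"))
}

#' Asymmetric missing-value imputation
#'
#' Imputes missing abundances for tested proteins under the asymmetric
#' eligibility rule: at most `bait_max_missing` (default 1) missing bait
#' values and at most `control_max_missing` (default 2) missing control
#' values; proteins beyond these limits are excluded. The asymmetry is
#' deliberately stricter on the bait side, accepting fewer would-be
#' interactors while letting more potential contaminants into the control.
#' `minprob` draws each missing value from a normal centred at the sample's
#' `q` abundance quantile with sd `sd_scale` times the median per-protein
#' sd; `knn` fills from the `k` nearest proteins (Euclidean distance over
#' shared observed samples) that are observed in the target sample.
#'
#' @param pm A `protein_matrix`.
#' @param method `"minprob"` or `"knn"`.
#' @param proteins Proteins to impute (default: all rows of `pm`).
#' @param bait_max_missing,control_max_missing Eligibility limits.
#' @param q MinProb quantile (default 0.01).
#' @param sd_scale MinProb sd down-scaling (default 0.5).
#' @param k kNN neighbour count (default 10; reduced with a warning when
#'   fewer usable neighbours exist).
#' @param seed Optional seed.
#' @return List with `abundance` (imputed tibble, eligible proteins only)
#'   and `excluded` (character vector of ineligible proteins).
#' @export
impute_missing <- function(pm, method = c("minprob", "knn"), proteins = NULL,
                           bait_max_missing = 1L, control_max_missing = 2L,
                           q = 0.01, sd_scale = 0.5, k = 10L, seed = NULL) {
  stopifnot(inherits(pm, "protein_matrix"))
  method <- match.arg(method)
  ab <- pm$abundance
  if (!is.null(proteins)) ab <- ab |> filter(.data$protein %in% proteins)
  if (!nrow(ab)) return(list(abundance = ab, excluded = character()))
  bait <- names(pm$groups)[pm$groups == "bait"]
  ctrl <- names(pm$groups)[pm$groups == "control"]
  m <- as.matrix(ab[c(bait, ctrl)])
  rownames(m) <- ab$protein
  miss_b <- rowSums(is.na(m[, bait, drop = FALSE]))
  miss_c <- rowSums(is.na(m[, ctrl, drop = FALSE]))
  eligible <- miss_b <= bait_max_missing & miss_c <= control_max_missing
  excluded <- rownames(m)[!eligible]
  m <- m[eligible, , drop = FALSE]
  if (any(is.na(m))) {
    m <- with_seed_if(seed, {
      if (method == "minprob") impute_minprob(m, q, sd_scale)
      else impute_knn(m, k)
    })
  }
  out <- as_tibble(m) |> mutate(protein = rownames(m), .before = 1)
  list(abundance = out, excluded = excluded)
}

impute_minprob <- function(m, q, sd_scale) {
  prot_sd <- apply(m, 1, \(x) if (sum(!is.na(x)) >= 2) sd(x, na.rm = TRUE)
                              else NA_real_)
  sd_imp <- sd_scale * median(prot_sd, na.rm = TRUE)
  if (!is.finite(sd_imp)) sd_imp <- 0.3
  if (all(is.na(m))) abort("Cannot impute: no observed values at all.")
  global_centre <- quantile(m, probs = q, na.rm = TRUE, names = FALSE)
  for (j in seq_len(ncol(m))) {
    nas <- is.na(m[, j])
    if (!any(nas)) next
    centre <- quantile(m[, j], probs = q, na.rm = TRUE, names = FALSE)
    # a sample with no observed values falls back to the matrix-wide tail
    if (!is.finite(centre)) centre <- global_centre
    m[nas, j] <- rnorm(sum(nas), centre, sd_imp)
  }
  m
}

impute_knn <- function(m, k) {
  for (i in seq_len(nrow(m))) {
    nas <- which(is.na(m[i, ]))
    if (!length(nas)) next
    obs_i <- !is.na(m[i, ])
    for (j in nas) {
      cand <- which(!is.na(m[, j]) & seq_len(nrow(m)) != i)
      if (!length(cand)) next
      d <- vapply(cand, function(r) {
        shared <- obs_i & !is.na(m[r, ])
        if (!any(shared)) return(Inf)
        sqrt(mean((m[i, shared] - m[r, shared])^2))
      }, numeric(1))
      cand <- cand[is.finite(d)]
      d <- d[is.finite(d)]
      if (!length(cand)) next
      kk <- min(k, length(cand))
      if (kk < k) warn(sprintf("kNN: only %d usable neighbours; k reduced.", kk))
      nb <- cand[order(d)[seq_len(kk)]]
      m[i, j] <- mean(m[nb, j])
    }
  }
  m
}

#' Moderated two-sample test with empirical-Bayes variance shrinkage
#'
#' Per protein: the bait-minus-control mean log2 difference, a pooled
#' sample variance shrunk towards a prior `s0^2` with prior degrees of
#' freedom `d0` estimated from the marginal distribution of log sample
#' variances (moment matching on the scaled-F model), the moderated t on
#' `d0 + d` degrees of freedom, a two-sided P and Benjamini-Hochberg
#' adjustment. `d0 = 0` reproduces the ordinary pooled t exactly.
#'
#' @param abundance Tibble with `protein` and sample columns (complete
#'   after imputation; proteins with < 2 values in a group are excluded).
#' @param groups Named vector mapping sample columns to `"bait"` /
#'   `"control"`.
#' @param d0 Optional fixed prior degrees of freedom (`NULL` = estimate).
#' @param fdr Class-III adjusted-P threshold (default 0.05).
#' @return Tibble `protein`, `log2fc`, `t`, `df`, `p.value`, `adj.p.value`,
#'   `class3`, plus attributes `d0` and `s0_sq`.
#' @export
moderated_test <- function(abundance, groups, d0 = NULL, fdr = 0.05) {
  bait <- names(groups)[groups == "bait"]
  ctrl <- names(groups)[groups == "control"]
  m <- as.matrix(abundance[c(bait, ctrl)])
  rownames(m) <- abundance$protein
  nb_obs <- rowSums(!is.na(m[, bait, drop = FALSE]))
  nc_obs <- rowSums(!is.na(m[, ctrl, drop = FALSE]))
  ok <- nb_obs >= 2 & nc_obs >= 2
  m <- m[ok, , drop = FALSE]
  if (!nrow(m)) {
    out <- tibble(protein = character(), log2fc = numeric(), t = numeric(),
                  df = numeric(), p.value = numeric(),
                  adj.p.value = numeric(), class3 = logical())
    attr(out, "d0") <- NA_real_
    return(out)
  }
  mb <- rowMeans(m[, bait, drop = FALSE], na.rm = TRUE)
  mc <- rowMeans(m[, ctrl, drop = FALSE], na.rm = TRUE)
  vb <- apply(m[, bait, drop = FALSE], 1, var, na.rm = TRUE)
  vc <- apply(m[, ctrl, drop = FALSE], 1, var, na.rm = TRUE)
  nb <- rowSums(!is.na(m[, bait, drop = FALSE]))
  nc <- rowSums(!is.na(m[, ctrl, drop = FALSE]))
  d <- nb + nc - 2
  s2 <- pmax(((nb - 1) * vb + (nc - 1) * vc) / d, 1e-12)

  if (is.null(d0)) {
    hp <- fit_f_hyperparameters(s2, d)
    d0 <- hp$d0; s0_sq <- hp$s0_sq
  } else if (d0 == 0) {
    s0_sq <- 0
  } else {
    # with fixed d0, match the prior scale to the mean log variance
    s0_sq <- fit_f_hyperparameters(s2, d, fixed_d0 = d0)$s0_sq
  }

  s2_post <- if (is.infinite(d0)) rep(s0_sq, length(s2))
             else (d0 * s0_sq + d * s2) / (d0 + d)
  se <- sqrt(s2_post * (1 / nb + 1 / nc))
  tt <- (mb - mc) / se
  df_tot <- d0 + d
  p <- 2 * pt(-abs(tt), df = df_tot)
  adj <- p.adjust(p, "BH")
  out <- tibble(protein = rownames(m), log2fc = unname(mb - mc),
                t = unname(tt), df = unname(df_tot), p.value = unname(p),
                adj.p.value = unname(adj),
                class3 = unname(adj < fdr & (mb - mc) > 0))
  attr(out, "d0") <- d0
  attr(out, "s0_sq") <- s0_sq
  out
}

# Moment-match (d0, s0^2) of the scaled-F variance model on log sample
# variances: var(log s2) = trigamma(d/2) + trigamma(d0/2).
fit_f_hyperparameters <- function(s2, d, fixed_d0 = NULL) {
  z <- log(s2)
  d_half <- d / 2
  if (is.null(fixed_d0)) {
    evar <- var(z) - mean(trigamma(d_half))
    if (!is.finite(evar) || evar <= 0) {
      d0 <- Inf
    } else {
      d0 <- 2 * trigamma_inverse(evar)
    }
  } else {
    d0 <- fixed_d0
  }
  emean <- mean(z) - mean(digamma(d_half) - log(d_half))
  if (is.infinite(d0)) {
    s0_sq <- exp(emean)
  } else {
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s0_sq = s0_sq)
}

# Newton inversion of the trigamma function (decreasing, positive).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-8) break
  }
  y
}

#' End-to-end co-IP interactor classification
#'
#' Composes [aggregate_peptides()], [classify_presence()],
#' [impute_missing()] and [moderated_test()] into the class I / II / III
#' scheme: presence-only classes bypass imputation and testing; remaining
#' proteins are imputed under the asymmetric rule (or excluded) and tested
#' with the moderated t; class III = adjusted P below the FDR threshold
#' with positive bait enrichment.
#'
#' @inheritParams aggregate_peptides
#' @inheritParams impute_missing
#' @param fdr Class-III FDR threshold.
#' @return Object of class `coip_classification`: list with `classes`
#'   (tibble `protein`, `class` over
#'   I/II/tested/excluded/contaminant), `tests` (moderated-test tibble),
#'   `matrix` (the `protein_matrix`) and `counts`.
#' @export
classify_coip <- function(peptides, method = c("minprob", "knn"),
                          bait_cols = c("b1", "b2", "b3"),
                          control_cols = c("c1", "c2", "c3"),
                          bait_max_missing = 1L, control_max_missing = 2L,
                          fdr = 0.05, seed = NULL, ...) {
  method <- match.arg(method)
  pm <- aggregate_peptides(peptides, bait_cols, control_cols)
  if (!nrow(pm$abundance)) {
    warn("No proteins to classify.")
    cls <- tibble(protein = pm$contaminant_proteins,
                  class = rep("contaminant", length(pm$contaminant_proteins)))
    return(structure(list(classes = cls, tests = NULL, matrix = pm,
                          counts = table(cls$class)),
                     class = "coip_classification"))
  }
  pres <- classify_presence(pm)
  tested_ids <- pres$protein[pres$class == "tested"]
  imp <- impute_missing(pm, method, proteins = tested_ids,
                        bait_max_missing = bait_max_missing,
                        control_max_missing = control_max_missing,
                        seed = seed, ...)
  tests <- moderated_test(imp$abundance, pm$groups, fdr = fdr)
  few <- setdiff(imp$abundance$protein, tests$protein)

  classes <- bind_rows(
    pres |> filter(.data$class != "tested") |> select("protein", "class"),
    tibble(protein = tests$protein, class = "tested"),
    tibble(protein = c(imp$excluded, few),
           class = rep("excluded", length(imp$excluded) + length(few))),
    tibble(protein = pm$contaminant_proteins,
           class = rep("contaminant", length(pm$contaminant_proteins)))
  )
  structure(list(classes = classes, tests = tests, matrix = pm,
                 counts = c(table(classes$class),
                            III = sum(tests$class3))),
            class = "coip_classification")
}

#' @export
print.coip_classification <- function(x, ...) {
  cat("<coip_classification>\n")
  print(x$counts)
  invisible(x)
}
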