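#' Simulate paired differential-binding / differential-expression tables
#'
#' Emulates the two result tables the abundance-binned overlap null consumes:
#' one per gene for differential binding (iCLIP) and one for differential
#' abundance (RNA-seq). Both mean counts derive from a shared lognormal gene
#' abundance (plus dataset noise), so abundance is a common confounder. With
#' `abundance_confounding = TRUE`, significant genes are selected with
#' probability proportional to their within-dataset abundance rank — the
#' detection-power bias the binned resampling null is designed to absorb —
#' while remaining independent between datasets unless `joint_frac` plants a
#' true association.
#'
#' @param annotation A [genome_annotation()] supplying gene ids.
#' @param frac_sig Fraction of genes significant in each dataset (length 1
#'   or 2: binding, expression).
#' @param joint_frac `NULL` for no planted association (overlap arises only
#'   from confounding, if on); otherwise the fraction of all genes forced to
#'   be significant in both datasets. Must not exceed either marginal.
#' @param abundance_confounding Logical; rank-weighted significance
#'   selection.
#' @param abundance_meanlog,abundance_sdlog Lognormal parameters of the
#'   shared gene abundance.
#' @param noise_sdlog Dataset-specific lognormal noise on mean counts.
#' @param seed Optional seed.
#'
#' @return List with tibbles `binding` and `expression` (columns `gene_id`,
#'   `mean_count`, `log2fc`, `pvalue`, `padj`, `significant`) and `truth`
#'   (planted joint gene set and parameters).
#' @export
sim_de_tables <- function(annotation, frac_sig = 0.1, joint_frac = NULL,
                          abundance_confounding = TRUE,
                          abundance_meanlog = log(100), abundance_sdlog = 1.2,
                          noise_sdlog = 0.4, seed = NULL) {
  stopifnot(inherits(annotation, "genome_annotation"))
  frac_sig <- rep_len(frac_sig, 2L)
  if (any(frac_sig < 0 | frac_sig > 1)) abort("`frac_sig` must be in [0, 1].")
  if (!is.null(joint_frac)) {
    if (joint_frac < 0 || joint_frac > 1) abort("`joint_frac` must be in [0, 1].")
    if (joint_frac > min(frac_sig)) {
      abort("`joint_frac` cannot exceed either marginal significant fraction.")
    }
  }
  with_seed_if(seed, {
    genes <- annotation$genes$gene_id
    n <- length(genes)
    base <- rlnorm(n, abundance_meanlog, abundance_sdlog)
    count_b <- base * rlnorm(n, 0, noise_sdlog)
    count_e <- base * rlnorm(n, 0, noise_sdlog)
    n_sig <- round(frac_sig * n)

    sel_weight <- function(counts) {
      if (abundance_confounding) rank(counts, ties.method = "first") / n
      else rep(1, n)
    }
    w_b <- sel_weight(count_b)
    w_e <- sel_weight(count_e)

    if (is.null(joint_frac)) {
      sig_b <- safe_weighted_pick(n, n_sig[1], w_b)
      sig_e <- safe_weighted_pick(n, n_sig[2], w_e)
      joint_planted <- character()
    } else {
      n_joint <- round(joint_frac * n)
      joint <- safe_weighted_pick(n, n_joint, w_b * w_e)
      rest <- setdiff(seq_len(n), joint)
      sig_b <- c(joint, rest[safe_weighted_pick(length(rest),
                                                n_sig[1] - n_joint,
                                                w_b[rest])])
      sig_e <- c(joint, rest[safe_weighted_pick(length(rest),
                                                n_sig[2] - n_joint,
                                                w_e[rest])])
      joint_planted <- genes[joint]
    }

    mk_table <- function(counts, sig_idx) {
      sig <- seq_len(n) %in% sig_idx
      p <- ifelse(sig, runif(n, 0, 0.01), runif(n, 0.05, 1))
      tibble(gene_id = genes, mean_count = counts,
             log2fc = ifelse(sig, rnorm(n, 0, 2), rnorm(n, 0, 0.2)),
             pvalue = p, padj = pmin(1, p * 2),
             significant = sig)
    }
    list(binding = mk_table(count_b, sig_b),
         expression = mk_table(count_e, sig_e),
         truth = list(joint_genes = joint_planted,
                      frac_sig = frac_sig, joint_frac = joint_frac,
                      abundance_confounding = abundance_confounding))
  })
}

safe_weighted_pick <- function(n, k, w) {
  k <- max(0L, min(n, as.integer(k)))
  if (k == 0L) return(integer())
  sample.int(n, k, replace = FALSE, prob = w)
}

#' Simulate a peptide-level co-IP abundance table
#'
#' Builds a label-free co-IP quantification table (3 bait + 3 control
#' samples) with proteins planted into designed classes: `I` (present in all
#' bait, absent in all control), `II` (exactly 2 bait, no control),
#' `enriched` (present everywhere with a planted log2 fold-change), `null`
#' (present everywhere, no enrichment) and `contaminant` (flagged).
#'
#' @param design Named counts per class, e.g.
#'   `c(I = 5, II = 3, enriched = 4, null = 88, contaminant = 2)`.
#' @param lfc Planted log2 fold-change (bait minus control) of `enriched`
#'   proteins.
#' @param peptides_per_protein Integer range of peptides per protein.
#' @param base_mean,base_sd Normal parameters of the per-protein base log2
#'   abundance.
#' @param sample_sd Within-protein, between-sample log2 standard deviation.
#' @param missing_rate Extra missing-completely-at-random rate applied to
#'   `enriched` and `null` peptide observations.
#' @param seed Optional seed.
#'
#' @return List with `peptides` (tibble: `peptide`, `protein`, `contaminant`,
#'   sample columns `b1..b3`, `c1..c3` on the raw scale, `NA` = missing) and
#'   `truth` (tibble `protein`, `class`, `lfc`).
#' @export
sim_peptides <- function(design = c(I = 5, II = 3, enriched = 4, null = 88,
                                    contaminant = 0),
                         lfc = 2, peptides_per_protein = c(2L, 4L),
                         base_mean = 25, base_sd = 2, sample_sd = 0.3,
                         missing_rate = 0, seed = NULL) {
  if (any(design < 0)) abort("Design counts must be >= 0.")
  classes <- rep(names(design), design)
  with_seed_if(seed, {
    n <- length(classes)
    samples <- c(paste0("b", 1:3), paste0("c", 1:3))
    rows <- purrr::map(seq_len(n), function(i) {
      cl <- classes[i]
      prot <- sprintf("P%04d", i)
      n_pep <- sample(seq(peptides_per_protein[1], peptides_per_protein[2]), 1L)
      base <- rnorm(1, base_mean, base_sd)
      pep_off <- rnorm(n_pep, 0, 0.5)
      vals <- matrix(rnorm(n_pep * 6L, 0, sample_sd), n_pep, 6L,
                     dimnames = list(NULL, samples))
      vals <- vals + base + pep_off
      if (cl %in% c("enriched")) vals[, 1:3] <- vals[, 1:3] + lfc
      present <- switch(cl,
        I = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
        II = c(sample(c(TRUE, TRUE, FALSE)), FALSE, FALSE, FALSE),
        rep(TRUE, 6L))
      vals[, !present] <- NA_real_
      if (cl %in% c("enriched", "null") && missing_rate > 0) {
        drop <- matrix(runif(n_pep * 6L) < missing_rate, n_pep, 6L)
        vals[drop] <- NA_real_
      }
      out <- as_tibble(2^vals)
      out$peptide <- sprintf("%s_pep%02d", prot, seq_len(n_pep))
      out$protein <- prot
      out$contaminant <- cl == "contaminant"
      out
    })
    peptides <- bind_rows(rows) |>
      select("peptide", "protein", "contaminant", dplyr::all_of(samples))
    truth <- tibble(protein = sprintf("P%04d", seq_len(n)), class = classes,
                    lfc = ifelse(classes == "enriched", lfc, 0))
    list(peptides = peptides, truth = truth)
  })
}
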