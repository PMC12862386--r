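---
title: "rbpsuite: statistical methods and simulation models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{rbpsuite: statistical methods and simulation models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
library(rbpsuite)
```

This vignette documents the statistical procedures implemented in rbpsuite
and the generative models used to validate them. Throughout, genomic
coordinates are 0-based half-open internally; interchange with
GenomicRanges converts on entry (`start + 1`) and exit. All stochastic
functions take an explicit `seed`; `NULL` leaves the RNG state untouched.

## 1. Crosslink tracks and peak calling

A crosslink track is a tibble with one row per
(chrom, pos, strand) site and a cDNA `count`. Positions must be whole
numbers; duplicate sites within a track are invalid.

**Control subtraction.** `subtract_control(track, control_tracks, mode)`
removes protein-track sites that also appear in the isotype-control
tracks. `mode = "union"` (default) drops a site present in *any* control
replicate — the conservative choice when controls are shallow, since any
control evidence marks a position as sticky. `mode = "all"` requires
presence in every control.

**Replicate merging.** `merge_replicates(tracks)` sums counts over
identical (chrom, pos, strand) keys across replicates, so downstream
scoring sees pooled cDNA depth.

**Permutation peak scorer.** `score_peaks(track, annotation, half_window,
n_perm, seed)` works gene by gene:

1. Each site's score $s_i$ is the summed count in the window
   $[p_i - w, p_i + w]$ on the same strand, $w$ = `half_window` (default
   3, matching the footprint of UV crosslink clusters).
2. For each of `n_perm` permutations (default 100), the gene's observed
   counts are shuffled across its occupied positions and scores are
   recomputed, giving a null score distribution that preserves the
   gene's count spectrum and site density.
3. The per-site FDR at score $s$ is
   $\widehat{\mathrm{FDR}}(s) =
   \mathbb{E}_{\text{perm}}[\#\{\text{sites} \ge s\}] / \#\{\text{obs}
   \ge s\}$, capped at 1 and made monotone non-increasing in $s$ by a
   reverse cumulative minimum. Monotonisation is what makes the estimate
   a proper step function of the score: a larger score can never carry a
   larger FDR.
4. FDR-passing sites (site FDR < 0.05) within $w$ of each other are
   merged into peaks. A peak's span runs from the first to one past the
   last passing site, its `score` is the summed raw counts in the span,
   and its `fdr` is the minimum site FDR.

`filter_peaks(peaks, min_score = 5, max_fdr = 0.05)` applies strict
`score > min_score` and `fdr < max_fdr`. The score floor removes
one-to-two-read fragments that pass the FDR test in shallow genes but
carry no usable signal.

Because the permutation is within-gene, highly expressed genes do not
inflate peak calls in lowly expressed ones; on enrichment-free tracks the
fraction of sites falling inside reported peaks stays at or below the
nominal 5%.

**Biotype annotation.** `gene_regions(annotation)` decomposes each gene
into disjoint segments and `annotate_biotypes(peaks, annotation)` assigns
each peak the class of its midpoint with precedence
CDS > 3′UTR > 5′UTR > intron > noncoding > intergenic, splitting intronic
hits by host biotype (pre-mRNA vs lncRNA). Precedence resolves isoform
ambiguity deterministically in favour of the most information-rich class.

**Junction metaprofiles.** `junction_metaprofile(track, annotation,
flank)` accumulates strand-aware crosslink density around exon–intron and
intron–exon junctions. Offset 0 is the first exonic nucleotide at the
3′SS and the first intronic nucleotide at the 5′SS; each profile is
normalised to counts-per-million within the profile so junction classes
are comparable across sequencing depths.

## 2. Intron binding

`bound_introns(peaks, introns)` marks an intron bound when a same-strand
peak overlaps it by at least 1 nt (half-open interval logic; abutting
features do not overlap). `sample_control_introns(introns, n, seed)`
draws controls with probability proportional to intron length — the
correct null when asking whether *bound* introns are short, because
longer introns accumulate peaks by chance alone.
`compare_intron_lengths()` runs a one-way ANOVA on $\log_{10}$ length via
`stats::aov` and returns an `intron_anova` object with `tidy()`,
`glance()` and `autoplot()` methods.

## 3. Abundance-binned overlap null

Naive overlap tests between "differentially bound" and "differentially
expressed" gene sets are anti-conservative because both detections are
powered by abundance. `resample_overlap_null(binding, expression,
n_bins = 5, n_iter = 999, seed)`:

1. `bin_genes()` splits genes into `n_bins` near-equal quantile bins on
   each table's `mean_count` (remainder genes go to the lower bins, so
   bin sizes differ by at most 1).
2. Each iteration redraws, without replacement and uniformly within each
   bin, the same number of "significant" genes per bin as observed in
   that table, independently for the two tables, and records the overlap.
3. The empirical P is $(1 + \#\{\text{null} \ge \text{obs}\}) /
   (1 + n_{\text{iter}})$ — the add-one form that can never report
   exactly zero.

The object reports `fold_enrichment` (observed / null mean) and flags a
`degenerate_null` when the null distribution is constant (e.g. every bin
saturated), in which case the P value is uninformative by construction.
With 999 iterations the P-value resolution is 0.001, sufficient for the
single-test setting this is used in. Under abundance confounding alone
(significance probability increasing in abundance rank in *both* tables,
but independently), the empirical P is uniform; a genuinely shared gene
set drives it down.

## 4. Splicing association

`read_rmats_se()` reads rMATS skipped-exon (SE) junction-count output,
keeping junction-count strings as character columns ("12,15,9") and
validating the column set and strands.
`filter_splice_events(events, max_fdr = 0.05, min_abs_dpsi = 0.1,
min_total_count = 10, per_sample = FALSE)` applies FDR ≤ 0.05
(inclusive, matching rMATS reporting), |ΔPSI| > 0.1 (strict) and a floor
on summed inclusion+skipping junction counts — underpowered events add
noise to the downstream regression.

`event_window()` spans from the upstream flanking exon's end to the
downstream flanking exon's start (strand-aware), i.e. the whole
alternative region a regulator could act on; degenerate windows are
warned about and dropped. An event is *bound* when a same-strand peak
overlaps its window.

`splice_metric(events)` computes
$m = |\Delta\mathrm{PSI}| \cdot (-\log_{10} \max(P, 10^{-300}))$,
combining effect size and confidence on one axis; the floor avoids
infinities from underflowed P values. `fit_binding_association()` fits
$\Pr(\text{bound}) = \mathrm{logit}^{-1}(\beta_0 + \beta_1 m)$ with
`stats::glm(family = binomial())`, refuses fewer than 10 events, and
flags perfect separation (fitted probabilities all ~0/1) instead of
reporting meaningless Wald statistics.

## 5. Co-IP interactor classification

`classify_coip(peptides, ...)` implements a presence/enrichment scheme
for label-free co-IP MS with 3 bait and 3 control runs:

* **Filtering.** Contaminant-flagged proteins and peptides shared
  between protein groups are removed; intensities are $\log_2$
  transformed.
* **Normalisation and aggregation.** Columns are diff.median normalised
  (each sample's median shifted to the grand median — robust to a few
  strong interactors) and peptides are aggregated to protein medians.
* **Presence classes.** Class I: quantified in all 3 bait and 0 control
  runs. Class II: exactly 2 bait, 0 control. These patterns are stronger
  evidence than any test on imputed values, so they are called before
  imputation.
* **Eligibility.** Remaining proteins enter the test only with ≤ 1
  missing bait and ≤ 2 missing control values. The asymmetry is
  deliberate: a missing control value is expected for a true interactor
  (abundance below detection), while a missing bait value undermines the
  enrichment estimate itself.
* **Imputation.** `impute_missing(method = "minprob")` draws from a
  normal centred at the sample column's 1% intensity quantile with sd =
  0.5 × the median protein sd — a left-censoring model for
  below-detection values. If a column has no observed values among the
  eligible proteins, the global 1% quantile is used as its centre.
  `method = "knn"` (k = 10, Euclidean over observed entries) is the
  alternative when missingness is not believed to be censoring.
* **Moderated test.** Per-protein variances are shrunk toward a prior:
  $(d_0, s_0^2)$ are estimated by moment matching on
  $\log s_g^2$ using digamma/trigamma identities, with
  $\mathrm{trigamma}^{-1}$ computed by Newton iteration. The moderated
  statistic uses $\tilde{s}_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$
  with $d_0 + d_g$ degrees of freedom. When the moment estimate gives
  $d_0 = 0$ (no evidence of variance pooling), the test falls back to
  the ordinary pooled t. Class III = Benjamini–Hochberg adjusted
  P < 0.05 *and* positive bait log2 fold change; depletion is never an
  interaction call.

## 6. Membrane localisation

`measure_membrane(mask, intensity, thickness = 5, include_halo = FALSE)`
quantifies membrane enrichment from a labelled cell mask and an intensity
image:

1. `find_boundaries_thick()` marks every pixel with at least one
   differing 8-neighbour (image borders are not treated as boundaries),
   yielding a 2-pixel-thick boundary as in scikit-image's thick mode.
2. `thicken_boundary()` applies iterated 3×3 dilation until the band is
   `thickness` pixels wide.
3. The membrane zone of a cell is the thickened boundary intersected
   with *that cell's own pixels* (`include_halo = FALSE`). Restricting
   to own pixels keeps the measured ratio independent of background and
   neighbouring-cell intensity; setting `include_halo = TRUE` reproduces
   the variant that also counts the exterior halo.
4. The per-cell statistic is mean membrane intensity / mean whole-cell
   intensity; `per = "image"` aggregates to image means first when cells
   within an image are not independent.

`welch_t(x, y)` is Welch's unequal-variance t-test with explicit
conventions for degenerate inputs (zero variance in both groups with
equal means → t = 0, P = 1).

## 7. Generative models

The simulators are the package's ground-truth instruments; their defaults
are fixed study conditions, not fitting knobs.

* **`sim_annotation(n_genes, seed)`** draws gene structures (multi-exon
  coding genes with CDS strictly inside the transcript, single-exon
  genes, noncoding genes) on two chromosomes with non-overlapping loci.
* **`binding_model()`** sets region-class weights (CDS 0.42, intron
  0.236, 3′UTR 0.214, noncoding 0.107, 5′UTR 0.023), an optional
  `ss3_bias` multiplier on density in the last 50 intronic nt before the
  3′SS, and `short_intron_alpha`: intron selection probability
  $\propto L^{1-\alpha}$, so $\alpha = 1$ is length-proportional
  (uniform per-nucleotide) and $\alpha > 1$ concentrates binding in
  short introns. **`sim_crosslinks()`** places unique sites under the
  model with counts $1 + \mathrm{Geom}(0.7)$, plus uniform control
  tracks.
* **`sim_de_tables(annotation, frac_sig, joint_frac, seed)`** gives both
  tables a shared log-normal abundance and makes significance
  probability increase linearly in abundance *rank* in each table
  independently — the realistic confounding the binned null must absorb.
  Rank-linear (rather than abundance-linear) weighting keeps the
  confounding strength invariant to the abundance scale.
  `joint_frac` additionally plants a shared significant gene set.
* **`sim_splice_events(annotation, n_events, slope, seed)`** draws
  ΔPSI ~ U(−0.6, 0.6) and three independent uniform P replicates,
  computes the metric, sets the logistic intercept by `uniroot` so the
  marginal bound fraction hits its target, and places peaks inside the
  cassette exon of bound events.
* **`sim_peptides(design, lfc, seed)`** plants the full class design
  (I / II / enriched / null / contaminant) at protein level with MCAR
  missingness applied only to tested proteins, so presence classes stay
  exact.
* **`sim_cell_image(n_cells, membrane_ratio, noise_sd, seed)`** places
  non-touching circular cells and solves the ring intensity so that the
  *realised* membrane:cell ratio — as measured by `measure_membrane`
  with matching thickness on the noise-free image — equals the planted
  ratio exactly. Planting the realised ratio (rather than a ring/interior
  intensity ratio) makes recovery exact by construction at zero noise,
  which is the property the estimator is validated against. Cell
  placement enforces a separation of at least the two radii plus
  $2 \times$ boundary width plus 2 pixels, so one cell's thickened
  boundary can never intrude into another cell's membrane zone.

## 8. Pipeline

`sim_study(dir, seed, ...)` writes a complete study to disk — GTF
annotation, BED crosslink tracks (protein and control replicates), DE
tables, an rMATS-format SE table, a peptide CSV, TIFF mask/intensity
image pairs for two conditions, a `truth.json` of planted parameters and
a `config.yaml`. `run_study(config, out_dir)` executes all seven analysis
stages from the config, isolates failures per stage (a corrupt input
fails its stage and its dependents, not the rest), and writes per-stage
outputs plus a JSON manifest. Per-stage seeds are derived from the study
seed and the stage label, so stages are reproducible independently.

## 9. Numerical conventions

* Empirical P values always use the add-one form.
* The permutation-FDR curve is monotonised before thresholding.
* `splice_metric` floors P at $10^{-300}$ before the log.
* `trigamma_inverse` runs Newton on $y = \psi'(x)$ from the
  large-$x$ start $x_0 = 0.5 + 1/y$; the moderated test degrades
  gracefully to the pooled t when the prior df estimate is 0, and to a
  point-mass prior when it is infinite.
* Window scoring uses $L = \max(\text{span}, k)$ guards so short genes
  never index out of range.

```{r example}
# end-to-end miniature study
dir <- tempfile("study")
paths <- sim_study(dir, seed = 5, n_genes = 60,
                   total_sites_per_rep = 6000, n_events = 60)
res <- run_study(paths$config, file.path(dir, "results"))
res$stages
```
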