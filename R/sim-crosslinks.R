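#' Crosslink binding model
#'
#' Describes how a simulated RBP distributes crosslink sites across genic
#' region classes, mirroring the binding signatures a CLIP experiment
#' reports: a per-class propensity, an enrichment factor in a window
#' upstream of 3' splice sites, and a short-intron preference.
#'
#' @param biotype_weights Named non-negative weights over region classes
#'   `CDS`, `UTR5`, `UTR3`, `intron`, `noncoding`. Class frequencies among
#'   simulated sites converge to these weights (normalised).
#' @param ss3_bias Density multiplier inside the `ss3_window` nucleotides at
#'   the 3' end of each intron (immediately upstream of the intron-exon
#'   junction). 1 = no bias.
#' @param ss3_window Window width in nt.
#' @param short_intron_alpha Exponent `a` of the per-nucleotide intron weight
#'   `length^(-a)`; `a > 1` concentrates intronic sites in short introns,
#'   0 = proportional-to-length (no bias).
#' @param background_rate Relative per-nucleotide rate used for isotype
#'   control (IgG) replicates; controls are uniform over genic nucleotides.
#' @param count_geom_p Geometric parameter for per-site cDNA counts
#'   (`count = 1 + rgeom(p)`); most sites carry count 1.
#'
#' @return An object of class `binding_model`.
#' @export
binding_model <- function(biotype_weights = c(CDS = 0.42, intron = 0.236,
                                              UTR3 = 0.214, noncoding = 0.107,
                                              UTR5 = 0.023),
                          ss3_bias = 1, ss3_window = 50L,
                          short_intron_alpha = 0,
                          background_rate = 1,
                          count_geom_p = 0.7) {
  classes <- c("CDS", "UTR5", "UTR3", "intron", "noncoding")
  w <- biotype_weights[classes]
  names(w) <- classes
  w[is.na(w)] <- 0
  if (any(w < 0)) abort("Biotype weights must be >= 0.")
  if (all(w == 0)) abort("At least one biotype weight must be > 0.")
  if (ss3_bias < 0 || ss3_window < 1) abort("Invalid 3'SS bias parameters.")
  structure(list(biotype_weights = w, ss3_bias = ss3_bias,
                 ss3_window = as.integer(ss3_window),
                 short_intron_alpha = short_intron_alpha,
                 background_rate = background_rate,
                 count_geom_p = count_geom_p),
            class = "binding_model")
}

#' Simulate crosslink-site tracks
#'
#' Draws per-replicate crosslink tracks for a protein (from the
#' [binding_model()] weights) and for isotype controls (uniform over genic
#' nucleotides), with geometric cDNA counts per site. Sites falling on the
#' same (chrom, pos, strand) are aggregated by summing counts, so each track
#' satisfies the uniqueness invariant.
#'
#' @param annotation A [genome_annotation()].
#' @param model A [binding_model()].
#' @param n_protein_reps,n_control_reps Replicate counts (>= 1).
#' @param total_sites_per_rep Number of site draws per replicate.
#' @param seed Optional seed.
#'
#' @return List with elements `protein` and `control` (lists of crosslink
#'   tibbles `chrom`, `pos`, `strand`, `count`) and `truth` (normalised
#'   class probabilities and model parameters).
#' @export
sim_crosslinks <- function(annotation, model,
                           n_protein_reps = 3L, n_control_reps = 3L,
                           total_sites_per_rep = 20000L, seed = NULL) {
  stopifnot(inherits(annotation, "genome_annotation"),
            inherits(model, "binding_model"))
  if (n_protein_reps < 1 || n_control_reps < 1) {
    abort("Replicate counts must be >= 1.")
  }
  regions <- gene_regions(annotation) |>
    mutate(len = .data$end - .data$start)
  present <- intersect(names(model$biotype_weights), unique(regions$region))
  w <- model$biotype_weights[present]
  if (all(w == 0)) abort("All biotype weights are zero on the classes present in the annotation.")
  w <- w / sum(w)

  with_seed_if(seed, {
    protein <- purrr::map(seq_len(n_protein_reps), function(r) {
      draw_model_sites(regions, model, w, total_sites_per_rep)
    })
    control <- purrr::map(seq_len(n_control_reps), function(r) {
      draw_uniform_sites(regions, model, total_sites_per_rep)
    })
    list(protein = protein, control = control,
         truth = list(class_probs = w,
                      ss3_bias = model$ss3_bias,
                      ss3_window = model$ss3_window,
                      short_intron_alpha = model$short_intron_alpha))
  })
}

draw_model_sites <- function(regions, model, w, n) {
  cls <- sample(names(w), n, replace = TRUE, prob = w)
  out <- purrr::map_dfr(names(w), function(cl) {
    k <- sum(cls == cl)
    if (k == 0L) return(empty_track())
    seg <- regions |> filter(.data$region == cl)
    if (!nrow(seg)) return(empty_track())
    seg_w <- if (cl == "intron" && model$short_intron_alpha != 0) {
      seg$len^(1 - model$short_intron_alpha)
    } else {
      as.numeric(seg$len)
    }
    idx <- sample.int(nrow(seg), k, replace = TRUE, prob = seg_w)
    pos <- positions_within(seg[idx, ],
                            ss3 = (cl == "intron"),
                            bias = model$ss3_bias,
                            win = model$ss3_window)
    tibble(chrom = seg$chrom[idx], pos = pos, strand = seg$strand[idx])
  })
  finalize_track(out, model$count_geom_p)
}

draw_uniform_sites <- function(regions, model, n) {
  idx <- sample.int(nrow(regions), n, replace = TRUE, prob = regions$len)
  pos <- regions$start[idx] +
    as.integer(floor(runif(n) * regions$len[idx]))
  finalize_track(tibble(chrom = regions$chrom[idx], pos = pos,
                        strand = regions$strand[idx]),
                 model$count_geom_p)
}

# Uniform position within each segment, with optional 3'SS-window density
# multiplier for introns. The window sits at the intron's transcriptional
# 3' end: genomic right end on '+', genomic left end on '-'.
positions_within <- function(seg, ss3, bias, win) {
  n <- nrow(seg)
  if (!ss3 || bias == 1) {
    return(seg$start + as.integer(floor(runif(n) * seg$len)))
  }
  wlen <- pmin(win, seg$len)
  blen <- seg$len - wlen
  p_win <- (bias * wlen) / (bias * wlen + blen)
  in_win <- runif(n) < p_win
  off_win <- as.integer(floor(runif(n) * wlen))
  off_body <- as.integer(floor(runif(n) * pmax(blen, 1L)))
  pos <- integer(n)
  plus <- seg$strand == "+"
  # window: last `wlen` nt before the 3'SS
  pos[in_win & plus] <- seg$end[in_win & plus] - 1L - off_win[in_win & plus]
  pos[in_win & !plus] <- seg$start[in_win & !plus] + off_win[in_win & !plus]
  pos[!in_win & plus] <- seg$start[!in_win & plus] + off_body[!in_win & plus]
  pos[!in_win & !plus] <- seg$end[!in_win & !plus] - 1L -
    off_body[!in_win & !plus]
  pos
}

finalize_track <- function(df, geom_p) {
  if (!nrow(df)) return(empty_track())
  df |>
    mutate(count = 1L + rgeom(n(), prob = geom_p)) |>
    group_by(.data$chrom, .data$pos, .data$strand) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    arrange(.data$chrom, .data$pos) |>
    mutate(pos = as.integer(.data$pos), count = as.integer(.data$count))
}
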