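#' Binary morphology on label / logical matrices
#'
#' Minimal shift-based morphology used for membrane-mask construction:
#' `find_boundaries_thick()` marks every pixel having a neighbour with a
#' different label ("thick" semantics: both sides of every edge, including
#' label/background edges); `dilate_binary()` / `erode_binary()` iterate a
#' 3x3 (8-connected) or cross (4-connected) structuring element;
#' `thicken_boundary()` is iterated dilation of a boundary image. Image
#' borders are treated as outside-of-image: out-of-image neighbours are
#' ignored by the boundary scan and count as background for erosion.
#'
#' @param mask Integer label matrix (0 = background).
#' @param x Logical matrix.
#' @param iters,thickness Number of dilation/erosion iterations (>= 1).
#' @param connectivity 8 (default) or 4.
#' @return A logical matrix.
#' @export
find_boundaries_thick <- function(mask, connectivity = 8) {
  if (!is.matrix(mask) || !(is.numeric(mask) || is.integer(mask))) {
    abort("`mask` must be a numeric/integer matrix.")
  }
  if (any(mask != round(mask))) abort("`mask` must contain integer labels.")
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (off in neighbor_offsets(connectivity)) {
    sh <- shift_matrix(mask, off[1], off[2], fill = NA)
    d <- !is.na(sh) & sh != mask
    out <- out | d
  }
  out
}

#' @rdname find_boundaries_thick
#' @export
dilate_binary <- function(x, iters = 1, connectivity = 8) {
  if (iters < 1) abort("`iters` must be >= 1.")
  for (i in seq_len(iters)) {
    acc <- x
    for (off in neighbor_offsets(connectivity)) {
      acc <- acc | shift_matrix(x, off[1], off[2], fill = FALSE)
    }
    x <- acc
  }
  x
}

#' @rdname find_boundaries_thick
#' @export
erode_binary <- function(x, iters = 1, connectivity = 8) {
  if (iters < 1) abort("`iters` must be >= 1.")
  for (i in seq_len(iters)) {
    acc <- x
    for (off in neighbor_offsets(connectivity)) {
      acc <- acc & shift_matrix(x, off[1], off[2], fill = FALSE)
    }
    x <- acc
  }
  x
}

#' @rdname find_boundaries_thick
#' @export
thicken_boundary <- function(x, thickness = 5, connectivity = 8) {
  if (thickness < 1) abort("`thickness` must be >= 1.")
  dilate_binary(x, iters = thickness, connectivity = connectivity)
}

neighbor_offsets <- function(connectivity) {
  if (connectivity == 4) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else if (connectivity == 8) {
    list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
         c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  } else {
    abort("`connectivity` must be 4 or 8.")
  }
}

# Shift a matrix by (dr, dc), filling exposed cells with `fill`.
shift_matrix <- function(m, dr, dc, fill = NA) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- seq_len(nr); cs <- seq_len(nc)
  r_src <- rs - dr; c_src <- cs - dc
  rv <- r_src >= 1 & r_src <= nr
  cv <- c_src >= 1 & c_src <= nc
  out[rs[rv], cs[cv]] <- m[r_src[rv], c_src[cv]]
  out
}

#' Membrane-to-whole-cell intensity measurement
#'
#' Builds a membrane mask from a cell label mask (boundary detection plus
#' iterated binary dilation of fixed `thickness`) and measures, per cell,
#' the mean intensity over the membrane zone and over the whole cell, and
#' their ratio. By default membrane pixels are restricted to the cell's own
#' pixels; `include_halo = TRUE` additionally attributes dilated membrane
#' pixels lying outside any label to their nearest (originating) label.
#'
#' @param mask Integer label matrix, 0 = background.
#' @param intensity Numeric intensity matrix of the same shape.
#' @param membrane_mask Optional precomputed logical membrane mask; computed
#'   from `mask` when `NULL`.
#' @param thickness Dilation thickness (default 5).
#' @param connectivity 8 (default) or 4.
#' @param per `"cell"` (one row per cell) or `"image"` (one aggregate row,
#'   the mean over per-cell ratios).
#' @param include_halo Attribute out-of-cell membrane pixels to the nearest
#'   label (see Details).
#' @param image_id Optional label carried into the output.
#'
#' @return Tibble with columns `cell_id`, `n_cell_px`, `mean_cell`,
#'   `n_membrane_px`, `mean_membrane`, `ratio` (and `image_id`); in
#'   `"image"` mode a single row with `n_cells` and the mean ratio.
#' @export
measure_membrane <- function(mask, intensity, membrane_mask = NULL,
                             thickness = 5, connectivity = 8,
                             per = c("cell", "image"),
                             include_halo = FALSE, image_id = NA_character_) {
  per <- match.arg(per)
  if (!all(dim(mask) == dim(intensity))) {
    abort("`mask` and `intensity` must have the same shape.")
  }
  if (is.null(membrane_mask)) {
    membrane_mask <- thicken_boundary(find_boundaries_thick(mask, connectivity),
                                      thickness, connectivity)
  }
  owner <- mask
  if (include_halo) {
    # propagate labels outward so halo pixels get their originating label
    for (i in seq_len(thickness)) {
      grow <- matrix(0, nrow(owner), ncol(owner))
      for (off in neighbor_offsets(connectivity)) {
        sh <- shift_matrix(owner, off[1], off[2], fill = 0)
        grow <- pmax(grow, sh)
      }
      owner <- ifelse(owner == 0, grow, owner)
    }
  }
  labels <- sort(setdiff(unique(as.vector(mask)), 0))
  rows <- purrr::map_dfr(labels, function(lab) {
    cell_px <- mask == lab
    mem_px <- membrane_mask & (if (include_halo) owner == lab else cell_px)
    if (!any(mem_px)) {
      warn(sprintf("Cell %s has no membrane pixels; dropped.", lab))
      return(tibble())
    }
    tibble(cell_id = lab,
           n_cell_px = sum(cell_px),
           mean_cell = mean(intensity[cell_px]),
           n_membrane_px = sum(mem_px),
           mean_membrane = mean(intensity[mem_px]),
           ratio = mean(intensity[mem_px]) / mean(intensity[cell_px]),
           image_id = image_id)
  })
  if (per == "image") {
    rows <- rows |>
      summarise(image_id = .env$image_id, n_cells = n(),
                ratio = mean(.data$ratio))
  }
  rows
}

#' Welch's two-sample t-test on ratio vectors
#'
#' Thin tidy wrapper around [stats::t.test()] with unequal variances and
#' Welch-Satterthwaite degrees of freedom. When both groups have zero
#' variance and equal means the test is degenerate and `P = 1` by
#' convention.
#'
#' @param group_a,group_b Numeric vectors (each n >= 2).
#' @return One-row tibble: `estimate` (mean A - mean B), `statistic`,
#'   `parameter` (df), `p.value`.
#' @export
welch_t <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort("Each group needs n >= 2.")
  }
  if (sd(group_a) == 0 && sd(group_b) == 0) {
    same <- isTRUE(all.equal(mean(group_a), mean(group_b)))
    return(tibble(estimate = mean(group_a) - mean(group_b),
                  statistic = if (same) 0 else Inf,
                  parameter = length(group_a) + length(group_b) - 2,
                  p.value = if (same) 1 else 0))
  }
  tt <- stats::t.test(group_a, group_b, var.equal = FALSE)
  tibble(estimate = unname(tt$estimate[1] - tt$estimate[2]),
         statistic = unname(tt$statistic),
         parameter = unname(tt$parameter),
         p.value = tt$p.value)
}
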