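#' Simulate a labelled cell image with a planted membrane ratio
#'
#' Places non-overlapping disc-shaped cells in an image, builds the label
#' mask, and paints an intensity image in which each cell has a membrane
#' ring whose brightness is solved so that the realised membrane-to-whole-
#' cell mean-intensity ratio equals the planted `membrane_ratio` exactly at
#' zero noise. The ring is defined morphologically (the `boundary_width`
#' outermost pixel layers of the cell, 8-connected), which is exactly the
#' in-cell zone a boundary-detection + dilation analysis of matched
#' thickness measures.
#'
#' @param n_cells Number of cells.
#' @param membrane_ratio Planted membrane:whole-cell ratio (scalar or one
#'   value per cell). Must satisfy `r * ring_area < cell_area`.
#' @param boundary_width Ring width in pixel layers; with analysis
#'   `thickness = t` the matched width is `t + 1`.
#' @param noise_sd Gaussian noise standard deviation (intensity units).
#' @param image_size `c(height, width)`.
#' @param base_intensity Interior intensity level.
#' @param radius_range Cell radius range (pixels).
#' @param max_tries Placement retries per cell before giving up.
#' @param seed Optional seed.
#'
#' @return List with `mask` (integer label matrix), `intensity` (numeric
#'   matrix, clamped to the 16-bit range) and `truth` (tibble `cell_id`,
#'   `ratio`, `cell_area`, `ring_area`).
#' @export
sim_cell_image <- function(n_cells = 6L, membrane_ratio = 2,
                           boundary_width = 6L, noise_sd = 0,
                           image_size = c(360L, 360L),
                           base_intensity = 1000,
                           radius_range = c(32, 42),
                           max_tries = 500L, seed = NULL) {
  ratios <- rep_len(membrane_ratio, n_cells)
  with_seed_if(seed, {
    H <- image_size[1]; W <- image_size[2]
    mask <- matrix(0L, H, W)
    centers <- matrix(NA_real_, n_cells, 3)  # row, col, radius
    for (i in seq_len(n_cells)) {
      placed <- FALSE
      for (t in seq_len(max_tries)) {
        r <- runif(1, radius_range[1], radius_range[2])
        cy <- runif(1, r + 2, H - r - 2)
        cx <- runif(1, r + 2, W - r - 2)
        ok <- TRUE
        if (i > 1L) {
          prev <- centers[seq_len(i - 1L), , drop = FALSE]
          dd <- sqrt((prev[, 1] - cy)^2 + (prev[, 2] - cx)^2)
          # keep cells far enough apart that a matched-thickness dilation of
          # one cell's boundary can never reach into a neighbouring cell
          ok <- all(dd > prev[, 3] + r + 2 * boundary_width + 2)
        }
        if (ok) { centers[i, ] <- c(cy, cx, r); placed <- TRUE; break }
      }
      if (!placed) {
        abort(sprintf("Could not place cell %d without overlap after %d tries.",
                      i, max_tries))
      }
    }
    rowm <- matrix(seq_len(H), H, W)
    colm <- matrix(seq_len(W), H, W, byrow = TRUE)
    for (i in seq_len(n_cells)) {
      inside <- (rowm - centers[i, 1])^2 + (colm - centers[i, 2])^2 <=
        centers[i, 3]^2
      mask[inside] <- i
    }

    intensity <- matrix(0, H, W)
    truth <- purrr::map_dfr(seq_len(n_cells), function(i) {
      cell <- mask == i
      core <- erode_binary(cell, iters = boundary_width)
      ring <- cell & !core
      a <- sum(cell); a_ring <- sum(ring); a_in <- a - a_ring
      r <- ratios[i]
      if (r * a_ring >= a) {
        abort(sprintf(
          "Cell %d: planted ratio %.2f unattainable (ring is %.0f%% of the cell).",
          i, r, 100 * a_ring / a))
      }
      m <- r * base_intensity * a_in / (a - r * a_ring)
      intensity[core] <<- base_intensity
      intensity[ring] <<- m
      tibble(cell_id = i, ratio = r, cell_area = a, ring_area = a_ring)
    })
    if (noise_sd > 0) {
      intensity <- intensity + rnorm(H * W, 0, noise_sd)
    }
    intensity <- pmin(pmax(intensity, 0), 65535)
    list(mask = mask, intensity = intensity, truth = truth)
  })
}

#' Read / write 16-bit grayscale TIFF images
#'
#' Values are stored as 16-bit unsigned integers; `read_image_tiff()`
#' returns the matrix rescaled back to the 0..65535 range, and label masks
#' round-trip exactly.
#'
#' @param img Numeric or integer matrix with values in 0..65535.
#' @param path File path.
#' @return `write_image_tiff()` returns `path` invisibly;
#'   `read_image_tiff()` returns a numeric matrix.
#' @export
write_image_tiff <- function(img, path) {
  tiff::writeTIFF(round(img) / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path) {
  round(tiff::readTIFF(path) * 65535)
}
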