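#' Per-cell pixel-intensity skewness
#'
#' The punctum statistic: the third standardized moment of the pixel
#' fluorescence-intensity distribution over the masked (in-cell) pixels,
#' using population central moments,
#' `mu3_tilde = m3 / m2^(3/2)`. A spatially homogeneous protein
#' distribution gives a roughly symmetric intensity histogram
#' (skewness near 0); a punctum adds a prolonged high-intensity tail
#' (skewness > 0). The statistic is invariant under affine intensity
#' rescaling `I -> alpha I + beta` (alpha > 0).
#'
#' @param image Numeric matrix (or a `cell_image` from
#'   [simulate_cell_image()], in which case its mask is used).
#' @param mask Logical matrix of the same shape; at least 3 pixels.
#' @return The skewness (dimensionless).
#' @examples
#' cell_skewness(matrix(c(1, 1, 1, 9), 2), matrix(TRUE, 2, 2))  # 2/sqrt(3)
#' @export
cell_skewness <- function(image, mask = NULL) {
  if (inherits(image, "cell_image")) {
    if (is.null(mask)) mask <- image$mask
    image <- image$image
  }
  stopifnot(is.matrix(image), is.logical(mask),
            all(dim(image) == dim(mask)))
  v <- image[mask]
  if (length(v) < 3) stop("mask must contain at least 3 pixels")
  m <- mean(v)
  m2 <- mean((v - m)^2)
  if (m2 <= 0) stop("zero pixel variance: skewness undefined")
  mean((v - m)^3) / m2^1.5
}

#' Classify a cell as punctate by skewness thresholding
#'
#' A cell is called punctate when its pixel-intensity skewness strictly
#' exceeds `threshold` (a value exactly at the threshold is not punctate).
#' The default threshold should be calibrated on a punctum-free null,
#' e.g. with [skewness_threshold()].
#'
#' @inheritParams cell_skewness
#' @param threshold Skewness decision threshold.
#' @param cell_id Optional identifier carried into the output.
#' @return A one-row tibble: `cell_id`, `skewness`, `threshold`,
#'   `is_punctate`.
#' @export
classify_punctum <- function(image, mask = NULL, threshold, cell_id = NA) {
  sk <- cell_skewness(image, mask)
  tibble::tibble(cell_id = cell_id, skewness = sk, threshold = threshold,
                 is_punctate = sk > threshold)
}

#' Calibrate the punctum-call threshold on a synthetic null
#'
#' Renders `n_cells` punctum-free cells with the supplied geometry/optics
#' and returns an upper quantile (default the 99th percentile) of their
#' skewness values. Cells without condensates have near-symmetric
#' intensity histograms, so this bounds the false-positive rate by
#' construction.
#'
#' @param geometry,optics Passed to the renderer.
#' @param n_emitters Emitters per null cell.
#' @param n_cells Number of null cells.
#' @param prob Quantile level.
#' @param seed Optional integer seed.
#' @return The threshold (a number).
#' @export
skewness_threshold <- function(geometry = cell_geometry(),
                               optics = optics_camera(),
                               n_emitters = 400, n_cells = 100,
                               prob = 0.99, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sk <- purrr::map_dbl(seq_len(n_cells), function(i) {
    em <- sample_emitters(geometry, n_emitters)
    cell_skewness(simulate_cell_image(geometry, em, optics))
  })
  as.numeric(stats::quantile(sk, prob))
}

#' Fraction of cells with puncta, weighted by cell counts
#'
#' Pools punctum calls across images: the point estimate is the total
#' number of punctate cells divided by the total number of cells (i.e.
#' per-image fractions weighted by cell counts). Dispersion across images
#' is the cell-count-weighted s.d. of per-image fractions, with the
#' corresponding weighted s.e.m.
#'
#' @param calls A data frame with one row per cell, containing
#'   `is_punctate` (logical) and an image identifier column.
#' @param image_col Name of the image identifier column.
#' @return A one-row tibble: `fraction`, `sd`, `sem`, `n_cells`,
#'   `n_images`.
#' @examples
#' calls <- tibble::tibble(
#'   image = rep(c("a", "b"), c(10, 30)),
#'   is_punctate = rep(c(TRUE, FALSE, TRUE, FALSE), c(5, 5, 3, 27)))
#' fraction_with_puncta(calls)  # 8/40 = 0.2
#' @export
fraction_with_puncta <- function(calls, image_col = "image") {
  stopifnot(is.data.frame(calls), nrow(calls) > 0,
            image_col %in% names(calls), "is_punctate" %in% names(calls))
  per_img <- calls |>
    dplyr::group_by(.data[[image_col]]) |>
    dplyr::summarise(n = dplyr::n(), k = sum(.data$is_punctate),
                     .groups = "drop") |>
    dplyr::mutate(frac = .data$k / .data$n)
  w <- per_img$n / sum(per_img$n)
  p <- sum(per_img$k) / sum(per_img$n)     # equals sum(w * frac)
  vw <- sum(w * (per_img$frac - p)^2)
  tibble::tibble(fraction = p,
                 sd = sqrt(vw),
                 sem = sqrt(vw / nrow(per_img)),
                 n_cells = sum(per_img$n),
                 n_images = nrow(per_img))
}

#' Two-channel pixel colocalization
#'
#' Pearson correlation of two channels over the masked pixels; the
#' standard readout for colocalization of two tagged proteins.
#'
#' @param image_a,image_b Numeric matrices of identical shape.
#' @param mask Logical matrix; at least 3 pixels.
#' @return Pearson correlation in `[-1, 1]`.
#' @export
colocalize_channels <- function(image_a, image_b, mask) {
  stopifnot(all(dim(image_a) == dim(image_b)),
            all(dim(image_a) == dim(mask)))
  a <- image_a[mask]
  b <- image_b[mask]
  if (length(a) < 3) stop("mask must contain at least 3 pixels")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("constant channel: correlation undefined")
  stats::cor(a, b)
}
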