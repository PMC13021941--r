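#' Single-molecule intensity from tracking
#'
#' Robust central estimate (median) of per-localization integrated
#' intensities from single-molecule tracking; the unit intensity used to
#' convert whole-cell fluorescence to copy number.
#'
#' @param tracks Track tibble with an `intensity` column, or a numeric
#'   vector of intensities.
#' @param min_n Minimum number of localizations.
#' @return The single-molecule intensity, counts.
#' @export
single_molecule_intensity <- function(tracks, min_n = 30) {
  v <- if (is.data.frame(tracks)) tracks$intensity else as.numeric(tracks)
  v <- v[is.finite(v)]
  if (length(v) < min_n)
    stop(sprintf("need >= %d localizations, got %d", min_n, length(v)))
  stats::median(v)
}

#' Per-cell copy number and concentration
#'
#' Copy number is the background-subtracted whole-cell fluorescence
#' intensity divided by the single-molecule intensity:
#' `N = (sum(masked pixels) - background_per_px * n_px) / I1`.
#' Concentration follows from the spherocylinder volume of the cell
#' geometry: `C = N / (N_A * V)` (µM with V in µm³).
#'
#' @param image Numeric matrix or a `cell_image` (whose mask and geometry
#'   are used by default).
#' @param mask Logical integration mask. Use a generous mask (or the
#'   whole field for an isolated cell): a tight outline clips PSF tails
#'   of emitters at the cell boundary.
#' @param background Background level per pixel, in image counts (i.e.
#'   photons x gain for rendered images).
#' @param I1 Single-molecule intensity, counts (> 0).
#' @param geometry Optional [cell_geometry()] for the concentration.
#' @param cell_id Identifier carried to the output.
#' @return A one-row tibble: `cell_id`, `integrated_intensity`,
#'   `single_molecule_intensity`, `copy_number`, `volume_um3`,
#'   `concentration_uM`.
#' @export
copy_number <- function(image, mask = NULL, background = 0, I1,
                        geometry = NULL, cell_id = NA) {
  if (inherits(image, "cell_image")) {
    if (is.null(mask)) mask <- image$mask
    if (is.null(geometry)) geometry <- image$geometry
    image <- image$image
  }
  if (is.null(mask)) mask <- matrix(TRUE, nrow(image), ncol(image))
  stopifnot(I1 > 0, all(dim(image) == dim(mask)))
  tot <- sum(image[mask]) - background * sum(mask)
  if (tot < 0) {
    warning("background-subtracted intensity negative; clipped to 0")
    tot <- 0
  }
  N <- tot / I1
  vol <- if (!is.null(geometry)) cell_volume(geometry) else NA_real_
  avogadro <- 6.02214076e23
  # molecules per um^3 -> mol/L: 1 um^3 = 1e-15 L
  conc <- if (is.finite(vol)) N / (avogadro * vol * 1e-15) * 1e6 else NA_real_
  tibble::tibble(cell_id = cell_id,
                 integrated_intensity = sum(image[mask]),
                 single_molecule_intensity = I1,
                 copy_number = N, volume_um3 = vol,
                 concentration_uM = conc)
}

#' Pearson correlation with two-sided t-test
#'
#' Standard per-cell correlation analysis (e.g. copy number vs lag time)
#' returning Pearson's rho and the two-sided t-test p-value.
#'
#' @param data A data frame, or a numeric vector `x`.
#' @param x,y Column names when `data` is a data frame; otherwise `y` is
#'   the second numeric vector.
#' @return A one-row tibble: `rho`, `statistic`, `df`, `p.value`, `n`.
#' @export
correlate <- function(data, x, y) {
  if (is.data.frame(data)) {
    xv <- data[[x]]
    yv <- data[[y]]
  } else {
    xv <- as.numeric(data)
    yv <- as.numeric(x)
  }
  keep <- is.finite(xv) & is.finite(yv)
  xv <- xv[keep]
  yv <- yv[keep]
  if (length(xv) < 3) stop("need at least 3 finite pairs")
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0)
    stop("zero-variance input: correlation undefined")
  ct <- stats::cor.test(xv, yv, method = "pearson")
  tibble::tibble(rho = unname(ct$estimate),
                 statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p.value = ct$p.value,
                 n = length(xv))
}

#' Segment cells from a label image
#'
#' Splits a label image (0 = background, positive integers = cells) into
#' per-cell masks and fits a spherocylinder to each: the principal axis
#' of the pixel coordinates gives the orientation, the extent along it
#' the length, and half the transverse extent the radius.
#'
#' @param labels Integer matrix; pixel `[1, 1]` center at (0, 0) µm.
#' @param pixel_size µm per pixel.
#' @return A list: `masks` (named list of logical matrices) and
#'   `geometries` (tibble with `cell_id`, `length_um`, `radius_um`,
#'   `center_x`, `center_y`, `angle_rad`, plus a list-column `geometry`
#'   of [cell_geometry()] objects).
#' @export
segment_cells <- function(labels, pixel_size = 0.1) {
  ids <- sort(setdiff(unique(as.vector(labels)), 0))
  if (length(ids) == 0)
    return(list(masks = list(),
                geometries = tibble::tibble(cell_id = integer(),
                                            length_um = numeric(),
                                            radius_um = numeric(),
                                            center_x = numeric(),
                                            center_y = numeric(),
                                            angle_rad = numeric(),
                                            geometry = list())))
  masks <- list()
  rows <- purrr::map_dfr(ids, function(id) {
    m <- labels == id
    masks[[as.character(id)]] <<- m
    w <- which(m, arr.ind = TRUE)
    xy <- cbind((w[, "col"] - 1) * pixel_size,
                (w[, "row"] - 1) * pixel_size)
    ctr <- colMeans(xy)
    cv <- stats::cov(xy)
    eg <- eigen(cv, symmetric = TRUE)
    ax <- eg$vectors[, 1]
    ang <- atan2(ax[2], ax[1]) %% pi
    proj_a <- (xy[, 1] - ctr[1]) * ax[1] + (xy[, 2] - ctr[2]) * ax[2]
    proj_b <- -(xy[, 1] - ctr[1]) * ax[2] + (xy[, 2] - ctr[2]) * ax[1]
    len <- diff(range(proj_a)) + pixel_size
    rad <- (diff(range(proj_b)) + pixel_size) / 2
    rad <- min(rad, len / 2)
    tibble::tibble(cell_id = id, length_um = len, radius_um = rad,
                   center_x = ctr[1], center_y = ctr[2], angle_rad = ang,
                   geometry = list(cell_geometry(len, rad, ctr, ang)))
  })
  list(masks = masks, geometries = rows)
}
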