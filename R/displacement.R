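#' Displacement-length distribution from single-molecule tracks
#'
#' Computes the Euclidean image-plane distance between localizations
#' `lag_frames` apart within each track and bins the lengths. Gaps: a
#' displacement is only formed between localizations exactly
#' `lag_frames` apart, so steps across missing frames are excluded.
#' Lengths beyond the last bin edge are accumulated in the last bin, so
#' the total count always equals the number of displacement pairs.
#'
#' @param tracks A tibble with columns `track_id`, `frame`, `x_um`,
#'   `y_um` (as produced by [simulate_membrane_tracks()]).
#' @param lag_frames Frame lag (default 1).
#' @param bins Either a number of uniform bins (edges run from 0 to the
#'   99.5th percentile of the observed lengths) or a numeric vector of
#'   bin edges starting at 0.
#' @param t_tl Frame time-lapse, s (used downstream to convert to D).
#' @param epsilon Localization error, µm (metadata carried to the fit).
#' @return An object of class `displacement_distribution`: `edges`,
#'   `counts`, `t_lag` (= `lag_frames * t_tl`), `epsilon`, `r` (the raw
#'   lengths).
#' @export
displacement_distribution <- function(tracks, lag_frames = 1, bins = 50,
                                      t_tl = 0.06, epsilon = 0) {
  stopifnot(all(c("track_id", "frame", "x_um", "y_um") %in% names(tracks)))
  d <- tracks |>
    dplyr::arrange(.data$track_id, .data$frame) |>
    dplyr::group_by(.data$track_id) |>
    dplyr::mutate(
      dx = dplyr::lead(.data$x_um, lag_frames) - .data$x_um,
      dy = dplyr::lead(.data$y_um, lag_frames) - .data$y_um,
      dframe = dplyr::lead(.data$frame, lag_frames) - .data$frame) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$dframe == lag_frames)
  r <- sqrt(d$dx^2 + d$dy^2)
  if (length(r) == 0) stop("no displacement pairs at this lag")
  if (length(bins) == 1) {
    hi <- as.numeric(stats::quantile(r, 0.995))
    if (hi <= 0) hi <- max(r, 1e-6)
    edges <- seq(0, hi, length.out = bins + 1)
  } else {
    edges <- as.numeric(bins)
    stopifnot(edges[1] == 0, !is.unsorted(edges, strictly = TRUE))
  }
  counts <- bin_clamped(r, edges)
  structure(list(edges = edges, counts = counts,
                 t_lag = lag_frames * t_tl, epsilon = epsilon, r = r,
                 n = length(r)),
            class = "displacement_distribution")
}

# histogram with overflow accumulated into the last bin
#' @noRd
bin_clamped <- function(r, edges) {
  nb <- length(edges) - 1
  idx <- findInterval(r, edges, rightmost.closed = TRUE, left.open = TRUE)
  idx[r <= edges[1]] <- 1L
  idx[idx > nb] <- nb
  idx[idx < 1L] <- 1L
  tabulate(idx, nbins = nb)
}

#' @export
print.displacement_distribution <- function(x, ...) {
  cat(sprintf(
    "<displacement_distribution> %d pairs in %d bins (0-%.3g um), t_lag %g s, epsilon %g um\n",
    x$n, length(x$counts), max(x$edges), x$t_lag, x$epsilon))
  invisible(x)
}

#' @export
as.data.frame.displacement_distribution <- function(x, ...) {
  nb <- length(x$counts)
  data.frame(bin_lo = x$edges[-(nb + 1)], bin_hi = x$edges[-1],
             bin_mid = (x$edges[-1] + x$edges[-(nb + 1)]) / 2,
             count = x$counts)
}

#' Super-resolution rendering of displacement-filtered localizations
#'
#' 2-D histogram image of the localizations whose adjacent displacement
#' (the step to the previous or next frame within the same track) is at
#' most `r_max`, isolating the slow, membrane-bound population. With
#' `r_max = Inf` all localizations are included.
#'
#' @param tracks Track tibble (`track_id`, `frame`, `x_um`, `y_um`).
#' @param r_max Displacement filter, µm.
#' @param pixel_size Rendering pixel size, µm/px.
#' @param blur_sigma Optional Gaussian blur sigma, µm (e.g. the mean
#'   localization precision); `NULL` for a raw histogram.
#' @return A list: `image` (matrix), `n_kept`, `kept` (logical per row of
#'   `tracks`), `origin` (µm coordinate of the center of pixel `[1, 1]`).
#' @export
render_super_resolution <- function(tracks, r_max = Inf, pixel_size = 0.03,
                                    blur_sigma = NULL) {
  tr <- tracks |>
    dplyr::arrange(.data$track_id, .data$frame) |>
    dplyr::group_by(.data$track_id) |>
    dplyr::mutate(
      d_next = sqrt((dplyr::lead(.data$x_um) - .data$x_um)^2 +
                      (dplyr::lead(.data$y_um) - .data$y_um)^2),
      d_prev = sqrt((.data$x_um - dplyr::lag(.data$x_um))^2 +
                      (.data$y_um - dplyr::lag(.data$y_um))^2)) |>
    dplyr::ungroup()
  keep <- if (is.infinite(r_max)) rep(TRUE, nrow(tr)) else
    (!is.na(tr$d_next) & tr$d_next <= r_max) |
    (!is.na(tr$d_prev) & tr$d_prev <= r_max)
  pts <- tr[keep, ]
  if (nrow(pts) == 0) {
    warning("no localizations pass the displacement filter")
    return(list(image = matrix(0, 1, 1), n_kept = 0L, kept = keep,
                origin = c(0, 0)))
  }
  x0 <- floor(min(pts$x_um) / pixel_size) * pixel_size
  y0 <- floor(min(pts$y_um) / pixel_size) * pixel_size
  cx <- pmax(1L, ceiling((pts$x_um - x0) / pixel_size + 1e-9))
  cy <- pmax(1L, ceiling((pts$y_um - y0) / pixel_size + 1e-9))
  nx <- max(cx)
  ny <- max(cy)
  img <- matrix(0, ny, nx)
  for (i in seq_along(cx)) img[cy[i], cx[i]] <- img[cy[i], cx[i]] + 1
  if (!is.null(blur_sigma) && blur_sigma > 0) {
    img <- gaussian_blur(img, blur_sigma / pixel_size)
  }
  list(image = img, n_kept = nrow(pts), kept = keep, origin = c(x0, y0))
}

# separable Gaussian blur, sigma in pixels
#' @noRd
gaussian_blur <- function(img, sigma_px) {
  half <- max(1L, ceiling(3 * sigma_px))
  k <- stats::dnorm(-half:half, sd = sigma_px)
  k <- k / sum(k)
  conv1 <- function(m) {
    out <- matrix(0, nrow(m), ncol(m))
    for (j in seq_along(k)) {
      off <- j - half - 1L
      src <- pmin(pmax(seq_len(nrow(m)) + off, 1L), nrow(m))
      out <- out + k[j] * m[src, , drop = FALSE]
    }
    out
  }
  t(conv1(t(conv1(img))))
}

#' Split localizations and diffusion by punctum membership
#'
#' Labels each localization as inside a punctum (distance to the punctum
#' center at most its radius `R`; the boundary is inclusive) or outside,
#' then builds region-restricted displacement distributions (a
#' displacement belongs to the region of its starting localization) and,
#' optionally, per-region single-state diffusion fits.
#'
#' @param tracks Track tibble.
#' @param punctum A list or one-row data frame with `x_um`, `y_um`,
#'   `r_um` (fitted punctum center and radius).
#' @param t_tl,epsilon Passed to [displacement_distribution()].
#' @param bins Binning for the per-region distributions.
#' @param fit If `TRUE`, fit a single Brownian state per region.
#' @return A list: `labels` (tibble with `inside`), `dist_in`,
#'   `dist_out`, and when `fit = TRUE` also `fit_in`, `fit_out`.
#' @export
segment_by_punctum <- function(tracks, punctum, t_tl = 0.06, epsilon = 0,
                               bins = 50, fit = TRUE) {
  d <- sqrt((tracks$x_um - punctum$x_um)^2 +
              (tracks$y_um - punctum$y_um)^2)
  lab <- dplyr::mutate(tracks, inside = d <= punctum$r_um)
  steps <- lab |>
    dplyr::arrange(.data$track_id, .data$frame) |>
    dplyr::group_by(.data$track_id) |>
    dplyr::mutate(
      r = sqrt((dplyr::lead(.data$x_um) - .data$x_um)^2 +
                 (dplyr::lead(.data$y_um) - .data$y_um)^2),
      dframe = dplyr::lead(.data$frame) - .data$frame) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$dframe == 1)
  region_dist <- function(sel) {
    r <- steps$r[steps$inside == sel]
    if (length(r) == 0) return(NULL)
    hi <- as.numeric(stats::quantile(r, 0.995))
    edges <- if (length(bins) == 1) seq(0, max(hi, 1e-6), length.out = bins + 1)
             else as.numeric(bins)
    structure(list(edges = edges, counts = bin_clamped(r, edges),
                   t_lag = t_tl, epsilon = epsilon, r = r, n = length(r)),
              class = "displacement_distribution")
  }
  din <- region_dist(TRUE)
  dout <- region_dist(FALSE)
  out <- list(labels = lab, dist_in = din, dist_out = dout)
  if (fit) {
    out$fit_in <- if (!is.null(din)) fit_diffusion_states(din, K = 1) else NULL
    out$fit_out <- if (!is.null(dout)) fit_diffusion_states(dout, K = 1) else NULL
  }
  out
}
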