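#' Place fluorescent emitters on the cell membrane
#'
#' Samples `n` emitter positions on the spherocylinder surface. With a
#' punctum, a fraction `phi` of the emitters is placed inside a circular
#' membrane patch of radius `punctum_radius` centered at a membrane point,
#' emulating a protein condensate; the remainder (and all emitters when
#' `phi = 0`) are area-uniform over the envelope.
#'
#' @param geometry A [cell_geometry()].
#' @param n Number of emitters.
#' @param punctum_radius Patch radius, µm, or `NULL` for no punctum.
#'   Typical condensates are ~0.2-0.3 µm in radius (400-600 nm across).
#' @param phi Enrichment fraction in `[0, 1]`: fraction of emitters placed
#'   inside the patch.
#' @param punctum_axial Signed axial position of the punctum center along
#'   the medial axis as a fraction of `length/2` (1 = pole, 0 = midcell).
#'   Condensates sit near the poles, so the default is 0.8.
#' @param seed Optional integer seed.
#' @return An object of class `emitter_field`: local-frame `positions`
#'   (n x 3), logical `in_punctum`, and the punctum description.
#' @export
sample_emitters <- function(geometry, n, punctum_radius = NULL, phi = 0,
                            punctum_axial = 0.8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n >= 0, phi >= 0, phi <= 1)
  if (!is.null(punctum_radius) && punctum_radius > geometry$length)
    stop("punctum radius exceeds cell length")
  punctum <- NULL
  pos <- sample_surface(geometry, n)
  in_p <- rep(FALSE, n)
  if (!is.null(punctum_radius) && phi > 0 && n > 0) {
    ctr <- project_to_surface(
      geometry,
      matrix(c(punctum_axial * geometry$length / 2, 0, geometry$radius), 1))
    n_in <- round(phi * n)
    if (n_in > 0) {
      got <- matrix(0, 0, 3)
      while (nrow(got) < n_in) {  # rejection-sample the membrane patch
        cand <- sample_surface(geometry, max(200, 4 * n_in))
        d <- sqrt(rowSums((cand - matrix(ctr, nrow(cand), 3, byrow = TRUE))^2))
        got <- rbind(got, cand[d <= punctum_radius, , drop = FALSE])
      }
      idx <- seq_len(n_in)
      pos[idx, ] <- got[idx, ]
      in_p[idx] <- TRUE
    }
    punctum <- list(center = as.numeric(ctr), radius = punctum_radius,
                    phi = phi)
  }
  structure(list(positions = pos, in_punctum = in_p, punctum = punctum,
                 geometry = geometry),
            class = "emitter_field")
}

#' Render a wide-field fluorescence image of one cell
#'
#' Renders emitters through an integrated-Gaussian PSF onto a pixel grid
#' and applies an EMCCD noise model: photon shot noise (Poisson), electron
#' multiplication (gamma with scale `em_gain`), and Gaussian read noise.
#' The ground-truth cell mask (pixels whose centers fall inside the
#' projected cell outline) and emitter bookkeeping are returned alongside.
#'
#' Image convention: a numeric matrix; rows index y, columns index x, and
#' the center of pixel `[1, 1]` is at (0, 0) µm.
#'
#' @param geometry A [cell_geometry()].
#' @param emitters An [sample_emitters()] result.
#' @param optics An [optics_camera()].
#' @param brightness Photons emitted per emitter per exposure.
#' @param noise If `FALSE`, returns the noiseless expectation
#'   `(signal + background) * em_gain`.
#' @param pad Margin around the cell outline, µm.
#' @param seed Optional integer seed.
#' @return A list of class `cell_image`: `image`, logical `mask`, `optics`,
#'   `geometry`, and `truth` (emitter count, punctum membership, image-plane
#'   emitter coordinates, brightness).
#' @examples
#' geom <- cell_geometry()
#' em <- sample_emitters(geom, 50, seed = 1)
#' img <- simulate_cell_image(geom, em, optics_camera(), seed = 1)
#' @export
simulate_cell_image <- function(geometry, emitters, optics = optics_camera(),
                                brightness = 100, noise = TRUE, pad = NULL,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  px <- optics$pixel_size
  if (is.null(pad)) pad <- 6 * optics$psf_sigma
  # field of view: bounding box of the projected outline plus pad
  ext <- geometry$length / 2 + pad
  cx <- geometry$center
  nx <- ceiling(2 * ext / px)
  ny <- nx
  x0 <- cx[1] - (nx - 1) / 2 * px   # center of column 1
  y0 <- cx[2] - (ny - 1) / 2 * px
  xc <- x0 + (seq_len(nx) - 1) * px
  yc <- y0 + (seq_len(ny) - 1) * px

  exy <- local_to_image(geometry, emitters$positions)
  sig <- matrix(0, ny, nx)
  s <- optics$psf_sigma
  for (i in seq_len(nrow(exy))) {
    fx <- stats::pnorm(xc + px / 2, exy[i, 1], s) -
      stats::pnorm(xc - px / 2, exy[i, 1], s)
    fy <- stats::pnorm(yc + px / 2, exy[i, 2], s) -
      stats::pnorm(yc - px / 2, exy[i, 2], s)
    sig <- sig + brightness * (fy %o% fx)
  }
  expected <- sig + optics$background
  if (noise) {
    nph <- stats::rpois(length(expected), expected)
    out <- numeric(length(nph))
    pos <- nph > 0
    out[pos] <- stats::rgamma(sum(pos), shape = nph[pos],
                              scale = optics$em_gain)
    out <- out + stats::rnorm(length(out), 0, optics$read_noise)
    img <- matrix(out, ny, nx)
  } else {
    img <- expected * optics$em_gain
  }
  grid <- cbind(rep(xc, each = ny), rep(yc, nx))
  mask <- matrix(in_cell_outline(geometry, grid), ny, nx)
  structure(
    list(image = img, mask = mask, optics = optics, geometry = geometry,
         pixel_origin = c(x0, y0),
         truth = list(n_emitters = nrow(exy),
                      in_punctum = emitters$in_punctum,
                      emitter_xy = exy,
                      punctum = emitters$punctum,
                      brightness = brightness)),
    class = "cell_image")
}
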