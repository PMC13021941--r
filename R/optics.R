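#' Camera and illumination model
#'
#' Parameters of the wide-field / stroboscopic imaging model: a Gaussian
#' point-spread function, a pixelated EMCCD detector with electron
#' multiplication, and the stroboscopic timing (short laser exposure
#' `t_int` within a longer frame time-lapse `t_tl`).
#'
#' @param psf_sigma PSF standard deviation, µm.
#' @param pixel_size Object-space pixel size, µm/px.
#' @param background Background level, photons per pixel per exposure.
#' @param em_gain Electron-multiplication gain (counts per photoelectron).
#' @param read_noise Read noise, counts r.m.s.
#' @param t_int Laser exposure per frame, s.
#' @param t_tl Frame-to-frame time lapse, s. Must satisfy `t_int <= t_tl`.
#' @return An object of class `optics_camera`.
#' @examples
#' optics_camera()  # stroboscopic defaults: 4 ms exposure / 60 ms lapse
#' @export
optics_camera <- function(psf_sigma = 0.13, pixel_size = 0.1, background = 5,
                          em_gain = 250, read_noise = 10,
                          t_int = 0.004, t_tl = 0.06) {
  vals <- c(psf_sigma, pixel_size, background, em_gain, read_noise, t_int, t_tl)
  if (any(!is.finite(vals)) || any(vals[-3] <= 0) || background < 0)
    stop("all optics/camera parameters must be positive (background >= 0)")
  if (t_int > t_tl) stop("t_int must not exceed t_tl")
  structure(list(psf_sigma = psf_sigma, pixel_size = pixel_size,
                 background = background, em_gain = em_gain,
                 read_noise = read_noise, t_int = t_int, t_tl = t_tl),
            class = "optics_camera")
}

#' @export
print.optics_camera <- function(x, ...) {
  cat(sprintf(
    "<optics_camera> PSF sigma %.3f um | %.3f um/px | bg %.1f ph/px | gain %g | read %.1f | t_int %g s / t_tl %g s\n",
    x$psf_sigma, x$pixel_size, x$background, x$em_gain, x$read_noise,
    x$t_int, x$t_tl))
  invisible(x)
}

#' Ground-truth Brownian diffusion-state mixture
#'
#' Specifies K Brownian diffusion states by their diffusion constants and
#' fractional populations; used both to parameterise the track simulator
#' and as the return shape of the mixture fit. States are stored in
#' ascending order of D.
#'
#' @param D Diffusion constants, µm²/s (one per state, >= 0).
#' @param f Fractional populations; must sum to 1.
#' @param epsilon Static localization error, µm (per coordinate, 1 s.d.).
#' @param mode Per-state simulation mode: `"membrane"` (2-D diffusion on
#'   the envelope surface; mobile inner-membrane population) or
#'   `"volume"` (3-D diffusion inside the cell body; the fast periplasmic
#'   population).
#' @return An object of class `diffusion_states`.
#' @examples
#' diffusion_states(D = c(0.15, 6), f = c(0.8, 0.2), epsilon = 0.03,
#'                  mode = c("membrane", "volume"))
#' @export
diffusion_states <- function(D, f = rep(1 / length(D), length(D)),
                             epsilon = 0,
                             mode = rep("membrane", length(D))) {
  stopifnot(length(D) == length(f), all(D >= 0), all(f >= 0), epsilon >= 0,
            length(mode) == length(D), all(mode %in% c("membrane", "volume")))
  if (abs(sum(f) - 1) > 1e-8) stop("state fractions must sum to 1")
  o <- order(D)
  structure(list(D = as.numeric(D[o]), f = as.numeric(f[o]),
                 epsilon = epsilon, K = length(D), mode = mode[o]),
            class = "diffusion_states")
}

#' @export
print.diffusion_states <- function(x, ...) {
  cat(sprintf("<diffusion_states> K = %d, epsilon = %g um\n", x$K, x$epsilon))
  for (k in seq_len(x$K))
    cat(sprintf("  state %d: D = %.4g um^2/s, f = %.3f\n", k, x$D[k], x$f[k]))
  invisible(x)
}
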