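#' Fit punctum geometry (2-D Gaussian)
#'
#' Fits a symmetric 2-D Gaussian (amplitude, center, sigma, offset) to a
#' fluorescence image around an initial center, or to a localization
#' cloud. The condensate radius is reported as `R = r_factor * sigma`
#' (default 2 sigma, roughly the 1/e^2 radius, matching the ~400-600 nm
#' diffraction-limited punctum scale).
#'
#' With two nearby spots, the fit converges to the one nearest the
#' initial center (a property of the local least-squares descent).
#'
#' @param x Either a `cell_image` / numeric matrix, or a localization
#'   tibble with `x_um`, `y_um`.
#' @param init_center Length-2 initial center guess, µm (required for
#'   images; defaults to the localization centroid for clouds).
#' @param pixel_size Pixel size for matrix input, µm (taken from a
#'   `cell_image` automatically).
#' @param r_factor Radius convention, `R = r_factor * sigma`.
#' @param max_resid Rejection threshold: maximal allowed ratio of residual
#'   s.d. to fitted amplitude.
#' @return A one-row tibble of class rows: `x_um`, `y_um`, `r_um`,
#'   `sigma_um`, `amplitude`, `offset`, `resid_ratio`.
#' @export
fit_punctum <- function(x, init_center = NULL, pixel_size = 0.1,
                        r_factor = 2, max_resid = 1.5) {
  if (inherits(x, "cell_image")) {
    pixel_size <- x$optics$pixel_size
    origin <- x$pixel_origin
    img <- x$image
  } else if (is.matrix(x)) {
    origin <- c(0, 0)
    img <- x
  } else {
    stopifnot(all(c("x_um", "y_um") %in% names(x)))
    if (is.null(init_center))
      init_center <- c(stats::median(x$x_um), stats::median(x$y_um))
    # direct moment fit on the cloud
    dx <- x$x_um - init_center[1]
    dy <- x$y_um - init_center[2]
    keep <- sqrt(dx^2 + dy^2) <= 3 * stats::sd(sqrt(dx^2 + dy^2))
    cx <- mean(x$x_um[keep])
    cy <- mean(x$y_um[keep])
    sig <- sqrt((stats::var(x$x_um[keep]) + stats::var(x$y_um[keep])) / 2)
    return(tibble::tibble(x_um = cx, y_um = cy, r_um = r_factor * sig,
                          sigma_um = sig, amplitude = nrow(x),
                          offset = 0, resid_ratio = NA_real_))
  }
  if (is.null(init_center)) stop("init_center required for image input")
  ny <- nrow(img)
  nx <- ncol(img)
  xs <- origin[1] + (seq_len(nx) - 1) * pixel_size
  ys <- origin[2] + (seq_len(ny) - 1) * pixel_size
  df <- data.frame(z = as.vector(img),
                   px = rep(xs, each = ny), py = rep(ys, nx))
  # restrict to a window around the initial guess
  win <- 8 * pixel_size
  df <- df[abs(df$px - init_center[1]) <= win &
             abs(df$py - init_center[2]) <= win, ]
  if (stats::sd(df$z) == 0) stop("flat image: no punctum to fit")
  start <- list(A = max(df$z) - min(df$z), x0 = init_center[1],
                y0 = init_center[2], s = 2 * pixel_size, o = min(df$z))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      z ~ o + A * exp(-((px - x0)^2 + (py - y0)^2) / (2 * s^2)),
      data = df, start = start,
      lower = c(0, -Inf, -Inf, pixel_size / 4, -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("punctum fit did not converge"))
  cf <- stats::coef(fit)
  rr <- stats::sd(stats::resid(fit)) / max(cf["A"], .Machine$double.eps)
  if (!is.finite(rr) || rr > max_resid || cf["A"] <= 0)
    stop("punctum fit rejected: residuals too large relative to amplitude")
  tibble::tibble(x_um = unname(cf["x0"]), y_um = unname(cf["y0"]),
                 r_um = r_factor * unname(cf["s"]),
                 sigma_um = unname(cf["s"]),
                 amplitude = unname(cf["A"]), offset = unname(cf["o"]),
                 resid_ratio = rr)
}

#' Extract in-condensate residence times from a track
#'
#' Thresholds the molecule's distance-to-punctum-center trajectory at the
#' fitted condensate radius `R` (boundary inclusive): maximal runs of
#' consecutive localizations with distance <= R form dwells of duration
#' `run length x t_tl`. Runs separated by at most `gap_tolerance` frames
#' outside (or missing) are merged, absorbing localization noise at the
#' boundary. A dwell still running when the track ends is censored.
#'
#' @param track A single track tibble (`frame`, `x_um`, `y_um`).
#' @param punctum One-row tibble from [fit_punctum()] (`x_um`, `y_um`,
#'   `r_um`).
#' @param t_tl Frame time-lapse, s.
#' @param gap_tolerance Frames allowed outside within one dwell.
#' @return A tibble with `tau_in` (s) and `censored`.
#' @export
residence_times <- function(track, punctum, t_tl = 0.06,
                            gap_tolerance = 1) {
  stopifnot(all(c("frame", "x_um", "y_um") %in% names(track)))
  track <- dplyr::arrange(track, .data$frame)
  d <- sqrt((track$x_um - punctum$x_um)^2 +
              (track$y_um - punctum$y_um)^2)
  inside <- d <= punctum$r_um
  frames <- track$frame
  if (!any(inside)) {
    return(tibble::tibble(tau_in = numeric(), censored = logical()))
  }
  idx <- which(inside)
  runs <- list()
  run_start <- idx[1]
  run_end <- idx[1]
  if (length(idx) > 1) {
    for (i in idx[-1]) {
      # frames outside (or missing) between consecutive inside points
      gap <- frames[i] - frames[run_end] - 1
      if (gap <= gap_tolerance) {
        run_end <- i
      } else {
        runs[[length(runs) + 1]] <- c(run_start, run_end)
        run_start <- i
        run_end <- i
      }
    }
  }
  runs[[length(runs) + 1]] <- c(run_start, run_end)
  tau <- vapply(runs, function(rn)
    (frames[rn[2]] - frames[rn[1]] + 1) * t_tl, numeric(1))
  cens <- vapply(runs, function(rn) rn[2] == length(frames), logical(1))
  tibble::tibble(tau_in = tau, censored = cens)
}

#' Escape-rate estimate with photobleaching correction
#'
#' Fits a single-exponential decay to the observed in-condensate dwell
#' times by maximum likelihood and removes the photobleaching
#' contribution via `k_eff = k_bl * (t_int / t_tl) + k_e`. Because the
#' dwells are recorded as whole frames (multiples of `t_tl`), the
#' exponential likelihood is evaluated at the frame resolution (the dwell
#' frame count is geometric with `p = 1 - exp(-k_eff * t_tl)`); censored
#' dwells contribute survival terms. A naive continuous-exponential MLE
#' on the discretized dwells would be biased upward by
#' ~`k_eff * t_tl / 2`.
#'
#' @param residences A tibble with `tau_in` (s) and optionally
#'   `censored` (dwells ending with the track are right-censored; dwells
#'   ending by photobleaching are events, which is why the bleaching term
#'   is subtracted afterwards).
#' @param k_bl Photobleaching rate constant during exposure, 1/s.
#' @param optics An [optics_camera()] (supplies `t_int`, `t_tl`).
#' @return An object of class `kinetics_result`: `k_eff`, `k_e`, `k_bl`,
#'   `t_int`, `t_tl`, 95% CIs, `n_dwells`, `n_censored`.
#' @export
fit_escape_rate <- function(residences, k_bl = 0, optics = optics_camera()) {
  stopifnot("tau_in" %in% names(residences))
  tau <- residences$tau_in
  cens <- if ("censored" %in% names(residences)) residences$censored
          else rep(FALSE, length(tau))
  if (length(tau) == 0 || all(cens))
    stop("no uncensored dwell times to fit")
  t_tl <- optics$t_tl
  t_int <- optics$t_int
  nfr <- pmax(round(tau / t_tl), 1)
  d <- sum(!cens)
  # geometric MLE with right censoring: p_hat = events / total frames
  # (events each spend N-1 survived frames + 1 event frame; censored
  # dwells contribute N survived frames)
  denom <- sum(nfr[!cens]) + sum(nfr[cens])
  p_hat <- d / denom
  k_eff <- -log(1 - p_hat) / t_tl
  # Wald CI on logit(p), mapped through
  se_logit <- sqrt(1 / (d * (1 - p_hat)))
  z <- stats::qnorm(0.975)
  p_ci <- stats::plogis(stats::qlogis(p_hat) + c(-z, z) * se_logit)
  k_eff_ci <- -log(1 - p_ci) / t_tl
  bleach_term <- k_bl * t_int / t_tl
  k_e <- k_eff - bleach_term
  if (k_e < 0)
    stop(sprintf(
      "invalid correction: k_eff (%.3g) below bleaching term (%.3g)",
      k_eff, bleach_term))
  structure(list(k_eff = k_eff, k_eff_ci = k_eff_ci,
                 k_e = k_e, k_e_ci = k_eff_ci - bleach_term,
                 k_bl = k_bl, t_int = t_int, t_tl = t_tl,
                 n_dwells = length(tau), n_censored = sum(cens)),
            class = "kinetics_result")
}

#' @export
print.kinetics_result <- function(x, ...) {
  cat(sprintf(
    "<kinetics_result> k_eff = %.3g 1/s (95%% CI %.3g-%.3g) from %d dwells (%d censored)\n",
    x$k_eff, x$k_eff_ci[1], x$k_eff_ci[2], x$n_dwells, x$n_censored))
  cat(sprintf("  bleaching term k_bl t_int/t_tl = %.3g 1/s -> k_e = %.3g 1/s\n",
              x$k_bl * x$t_int / x$t_tl, x$k_e))
  if (!is.null(x$k_c)) cat(sprintf("  entry rate k_c = %.3g 1/s\n", x$k_c))
  invisible(x)
}

#' @export
glance.kinetics_result <- function(x, ...) {
  tibble::tibble(k_eff = x$k_eff, k_e = x$k_e,
                 k_e_lo = x$k_e_ci[1], k_e_hi = x$k_e_ci[2],
                 k_bl = x$k_bl, t_int = x$t_int, t_tl = x$t_tl,
                 k_c = x$k_c %||% NA_real_,
                 n_dwells = x$n_dwells, n_censored = x$n_censored)
}

#' Photobleaching rate from track durations
#'
#' With bleaching confined to the laser exposure, the observed track
#' length in frames is geometric with per-frame survival
#' `exp(-k_bl * t_int)`. The geometric MLE on track ON-durations
#' (outside condensates, so escape does not truncate them) therefore
#' gives `k_bl = -log(1 - p_hat) / t_int`.
#'
#' @param tracks Track tibble (`track_id`, `frame`).
#' @param optics An [optics_camera()].
#' @param min_tracks Minimum number of tracks required.
#' @param max_frames Movie length in frames, if known: tracks reaching it
#'   were ended by the movie, not by bleaching, and are treated as
#'   right-censored (with no bleaching at all, every track is censored
#'   and the estimate is 0).
#' @return `k_bl` in 1/s, with the 95% CI as attribute `ci`.
#' @export
estimate_bleach_rate <- function(tracks, optics = optics_camera(),
                                 min_tracks = 100, max_frames = NULL) {
  len <- tracks |>
    dplyr::count(.data$track_id) |>
    dplyr::pull(.data$n)
  if (length(len) < min_tracks)
    stop(sprintf("need >= %d tracks, got %d", min_tracks, length(len)))
  events <- if (is.null(max_frames)) rep(TRUE, length(len))
            else len < max_frames
  d <- sum(events)
  if (d == 0) return(structure(0, ci = c(0, 0)))
  p_hat <- d / sum(len)
  k_bl <- -log(1 - p_hat) / optics$t_int
  se_logit <- sqrt(1 / (d * (1 - p_hat)))
  z <- stats::qnorm(0.975)
  p_ci <- stats::plogis(stats::qlogis(p_hat) + c(-z, z) * se_logit)
  structure(k_bl, ci = -log(1 - p_ci) / optics$t_int)
}

#' Condensate entry rate under quasi-equilibrium
#'
#' Steady-state balance of molecules entering and escaping condensates:
#' `k_c * n_out = k_e * n_in`, so `k_c = k_e * n_in / n_out` where
#' `n_in` / `n_out` are time-averaged localization counts inside/outside
#' the condensates.
#'
#' @param k_e Escape rate constant, 1/s (or a `kinetics_result`).
#' @param n_in,n_out Localization counts inside / outside (`n_out > 0`).
#' @return `k_c` in 1/s; when given a `kinetics_result`, the same object
#'   with `k_c` added.
#' @export
entry_rate <- function(k_e, n_in, n_out) {
  if (n_out <= 0) stop("n_out must be positive")
  if (inherits(k_e, "kinetics_result")) {
    k_e$k_c <- k_e$k_e * n_in / n_out
    return(k_e)
  }
  k_e * n_in / n_out
}
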