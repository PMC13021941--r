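#' Sigmoidal formation curve
#'
#' The four-parameter logistic used throughout the punctum-formation
#' analyses: `f(t) = a + b / (1 + exp(-(t - c) / d))`, with baseline `a`,
#' amplitude `b`, midpoint `c` and exponential time constant `d`. The
#' derived kinetic summaries are `transition_time = 4 d` (straddling the
#' inflection) and `lag_time = c - 2 d` (time from 0 to the start of the
#' transition window).
#'
#' @param t Time(s), h.
#' @param a,b,c,d Sigmoid parameters; `d > 0`.
#' @return `f(t)`.
#' @examples
#' sigmoid_curve(3.4, a = 0, b = 1, c = 3.4, d = 0.35)  # inflection: a + b/2
#' @export
sigmoid_curve <- function(t, a, b, c, d) {
  stopifnot(d > 0)
  a + b / (1 + exp(-(t - c) / d))
}

#' Simulate a noisy punctum-formation time course
#'
#' Samples the sigmoid at `sample_times` and adds i.i.d. Gaussian noise,
#' emulating a per-cell skewness trajectory or a population
#' fraction-with-puncta curve.
#'
#' @param a,b,c,d Sigmoid parameters (see [sigmoid_curve()]).
#' @param sample_times Times, h.
#' @param noise_sd Gaussian noise s.d. (same units as the response).
#' @param seed Optional integer seed.
#' @return A tibble with `t_h`, `value`, and the noiseless `truth`.
#' @export
simulate_formation_timecourse <- function(a, b, c, d, sample_times,
                                          noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mu <- sigmoid_curve(sample_times, a, b, c, d)
  tibble::tibble(t_h = sample_times,
                 value = mu + stats::rnorm(length(mu), 0, noise_sd),
                 truth = mu)
}

#' Simulate observed in-condensate dwell times
#'
#' True dwell times are exponential with the escape rate `k_e`. A molecule
#' is only observable until it photobleaches; with bleaching confined to
#' the laser exposure, the bleaching hazard per unit wall-clock time is
#' `k_bl * t_int / t_tl`. The observed dwell is the minimum of the two
#' competing exponential clocks, discretized upward to multiples of the
#' frame time `t_tl`. Dwells ending by bleaching are still observed
#' *events* for the effective decay rate
#' `k_eff = k_bl * (t_int / t_tl) + k_e`; dwells are marked censored only
#' when the observation window `t_max` ends first.
#'
#' @param k_e Escape rate constant, 1/s.
#' @param k_bl Photobleaching rate constant during exposure, 1/s.
#' @param optics An [optics_camera()] (supplies `t_int`, `t_tl`).
#' @param n_events Number of dwells.
#' @param t_max Observation window, s (`Inf` = unbounded movie).
#' @param seed Optional integer seed.
#' @return A tibble with `tau_in` (s, multiples of `t_tl`), `censored`,
#'   and ground-truth columns `true_dwell` and `bleached`.
#' @examples
#' simulate_punctum_residence(3.1, 15, optics_camera(), n_events = 5, seed = 1)
#' @export
simulate_punctum_residence <- function(k_e, k_bl, optics = optics_camera(),
                                       n_events, t_max = Inf, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(k_e >= 0, k_bl >= 0, n_events >= 0)
  t_tl <- optics$t_tl
  if (n_events == 0) {
    return(tibble::tibble(tau_in = numeric(), censored = logical(),
                          true_dwell = numeric(), bleached = logical()))
  }
  true_dwell <- if (k_e > 0) stats::rexp(n_events, k_e) else rep(Inf, n_events)
  haz_bl <- k_bl * optics$t_int / t_tl
  t_bl <- if (haz_bl > 0) stats::rexp(n_events, haz_bl) else rep(Inf, n_events)
  obs <- pmin(true_dwell, t_bl, t_max)
  if (any(!is.finite(obs)))
    stop("infinite dwell times: set k_e > 0, k_bl > 0 or finite t_max")
  tau <- pmax(ceiling(obs / t_tl), 1) * t_tl
  tibble::tibble(tau_in = tau,
                 censored = t_max <= pmin(true_dwell, t_bl),
                 true_dwell = true_dwell,
                 bleached = t_bl < pmin(true_dwell, t_max))
}

#' Simulate a chopped-light chronoamperometry trace
#'
#' Current = linear baseline drift + `i_photo_step` while the light is on
#' + Gaussian noise. Cathodic currents are negative, so a photocathodic
#' response has `i_photo_step < 0`. The illumination schedule is
#' `on_s` seconds on followed by `off_s` seconds off, repeated `cycles`
#' times, preceded by a dark `lead_s` period so the first on-transition
#' has a full pre-window.
#'
#' @param on_s,off_s On/off durations per cycle, s.
#' @param cycles Number of light cycles.
#' @param i_photo_step Photocurrent step while illuminated, nA.
#' @param drift_slope Baseline drift, nA/s.
#' @param noise_sd Gaussian current noise, nA.
#' @param sample_rate Sampling rate, Hz.
#' @param lead_s Dark lead-in, s.
#' @param seed Optional integer seed.
#' @return A tibble of class `current_trace` with `t_s`, `current_nA`,
#'   `light_on`.
#' @examples
#' simulate_current_trace(cycles = 1, noise_sd = 0, sample_rate = 5)
#' @export
simulate_current_trace <- function(on_s = 15, off_s = 10, cycles = 3,
                                   i_photo_step = -0.4, drift_slope = 0,
                                   noise_sd = 0.05, sample_rate = 10,
                                   lead_s = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  total <- lead_s + cycles * (on_s + off_s)
  if (sample_rate * min(on_s, off_s, lead_s) < 3)
    stop("sample_rate too low: each schedule window needs >= 3 samples")
  t_s <- seq(0, total, by = 1 / sample_rate)
  phase <- (t_s - lead_s) %% (on_s + off_s)
  light_on <- t_s >= lead_s & t_s < lead_s + cycles * (on_s + off_s) &
    phase < on_s
  cur <- drift_slope * t_s + i_photo_step * as.numeric(light_on) +
    stats::rnorm(length(t_s), 0, noise_sd)
  out <- tibble::tibble(t_s = t_s, current_nA = cur, light_on = light_on)
  class(out) <- c("current_trace", class(out))
  attr(out, "sample_rate") <- sample_rate
  out
}
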