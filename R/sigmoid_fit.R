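#' Fit the sigmoidal formation model
#'
#' Least-squares fit of `f(t) = a + b / (1 + exp(-(t - c) / d))` to a
#' formation time course (fraction-with-puncta vs time, normalized
#' skewness vs time, Fe(II) production, menaquinone level, ...). The
#' derived kinetic summaries are `transition_time = 4 d` and
#' `lag_time = c - 2 d`, so that `lag + transition/2 = c` exactly.
#'
#' Initialization: `a = min(y)`, `b = range(y)` (sign from the overall
#' trend), `c` = time of the first half-range crossing, `d` = span / 10,
#' with `d` bounded in (0, span]. A fit whose amplitude is
#' indistinguishable from 0 at the 95% level is flagged
#' `"no_transition"`; a significantly negative amplitude (punctum
#' dissipation) is flagged `"dissipation"`; a midpoint beyond the
#' observed record is flagged `"censored"` (the transition was not
#' captured and the lag estimate is withheld).
#'
#' @param data A data frame with time and value columns, or a numeric
#'   vector of times (then `value` must be the numeric response).
#' @param time,value Column names when `data` is a data frame.
#' @param weights Optional per-point weights (e.g. cell counts).
#' @return An object of class `sigmoid_fit`; see [tidy.sigmoid_fit()] and
#'   [glance.sigmoid_fit()].
#' @examples
#' tc <- simulate_formation_timecourse(0, 1, c = 3.4, d = 0.35,
#'                                     sample_times = seq(0, 10, length.out = 10))
#' fit <- fit_sigmoid(tc)
#' glance(fit)  # lag 2.7 h, transition 1.4 h
#' @export
fit_sigmoid <- function(data, value = NULL, time = "t_h",
                        weights = NULL) {
  if (is.data.frame(data)) {
    vcol <- if (is.null(value)) intersect(c("value", "skewness", "fraction"),
                                          names(data))[1] else value
    if (is.na(vcol) || !vcol %in% names(data))
      stop("could not find a response column; pass `value`")
    t <- data[[time]]
    y <- data[[vcol]]
  } else {
    t <- as.numeric(data)
    y <- as.numeric(value)
  }
  stopifnot(length(t) == length(y), all(is.finite(t)), all(is.finite(y)))
  if (length(t) < 5) stop("need at least 5 points spanning the transition")
  o <- order(t)
  t <- t[o]
  y <- y[o]
  w <- if (is.null(weights)) rep(1, length(t)) else weights[o]

  span <- diff(range(t))
  rng <- diff(range(y))
  increasing <- stats::coef(stats::lm(y ~ t))[2] >= 0
  b0 <- if (increasing) rng else -rng
  a0 <- if (increasing) min(y) else max(y)
  half <- a0 + b0 / 2
  crossed <- if (increasing) y >= half else y <= half
  c0 <- if (any(crossed)) t[which(crossed)[1]] else stats::median(t)
  d0 <- span / 10
  start <- list(a = a0, b = b0, c = c0, d = d0)

  if (rng <= .Machine$double.eps * 10) {
    return(new_sigmoid_fit(NA, 0, NA, NA, rep(NA_real_, 4), t, y,
                           flag = "no_transition"))
  }
  sw <- sqrt(w)
  resid_fn <- function(p)
    sw * (y - (p[1] + p[2] / (1 + exp(-(t - p[3]) / p[4]))))
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(a = a0, b = b0, c = c0, d = d0), fn = resid_fn,
      lower = c(-Inf, -Inf, -Inf, 1e-6),
      upper = c(Inf, Inf, Inf, span),
      control = minpack.lm::nls.lm.control(maxiter = 500, maxfev = 2000)),
    error = function(e) e)
  if (inherits(fit, "error") || !(fit$info %in% 1:4)) {
    msg <- if (inherits(fit, "error")) conditionMessage(fit) else fit$message
    stop(sprintf(
      "sigmoid fit did not converge (%s); initial guesses a=%.3g b=%.3g c=%.3g d=%.3g",
      msg, a0, b0, c0, d0))
  }
  cf <- fit$par
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 4))
  flag <- "ok"
  if (is.finite(se["b"]) && abs(cf["b"]) < stats::qnorm(0.975) * se["b"]) {
    flag <- "no_transition"
  } else if (cf["b"] < 0) {
    flag <- "dissipation"
  } else if (cf["c"] > max(t)) {
    flag <- "censored"
  }
  new_sigmoid_fit(cf["a"], cf["b"], cf["c"], cf["d"], se, t, y, flag = flag)
}

#' @noRd
punctakin_failed_fit <- function(t, y, flag) {
  new_sigmoid_fit(NA_real_, NA_real_, NA_real_, NA_real_,
                  rep(NA_real_, 4), t, y, flag = flag)
}

#' @noRd
new_sigmoid_fit <- function(a, b, c, d, se, t, y, flag = "ok") {
  lag <- if (flag %in% c("ok")) unname(c - 2 * d) else NA_real_
  trans <- if (is.finite(d)) unname(4 * d) else NA_real_
  se <- unname(se)
  structure(
    list(a = unname(a), b = unname(b), c = unname(c), d = unname(d),
         se = stats::setNames(se, c("a", "b", "c", "d")),
         lag_time = lag, transition_time = trans,
         # derived-quantity s.e. by linear propagation (cov term ignored
         # would understate; use full covariance when available)
         flag = flag, t = t, y = y),
    class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat("<sigmoid_fit> f(t) = a + b / (1 + exp(-(t - c)/d))\n")
  cat(sprintf("  a=%.4g b=%.4g c=%.4g d=%.4g  [%s]\n",
              x$a, x$b, x$c, x$d, x$flag))
  if (is.finite(x$lag_time))
    cat(sprintf("  lag = %.4g h, transition = %.4g h\n",
                x$lag_time, x$transition_time))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a sigmoid fit
#'
#' One row per parameter (`a`, `b`, `c`, `d`) with estimates and standard
#' errors.
#'
#' @param x A `sigmoid_fit`.
#' @param ... Unused.
#' @export
tidy.sigmoid_fit <- function(x, ...) {
  tibble::tibble(term = c("a", "b", "c", "d"),
                 estimate = c(x$a, x$b, x$c, x$d),
                 std.error = unname(x$se))
}

#' One-row summary of a sigmoid fit
#'
#' Includes the derived `lag_time` (`c - 2d`) and `transition_time`
#' (`4 d`) and the fit flag.
#'
#' @param x A `sigmoid_fit`.
#' @param ... Unused.
#' @export
glance.sigmoid_fit <- function(x, ...) {
  tibble::tibble(a = x$a, b = x$b, c = x$c, d = x$d,
                 lag_time = x$lag_time,
                 transition_time = x$transition_time,
                 flag = x$flag, n = length(x$t))
}

#' Per-cell punctum-formation kinetics from skewness trajectories
#'
#' For each cell, min-max-normalizes the skewness trajectory (observed
#' minimum to 0, maximum to 1; raw values are retained by the caller) and
#' fits the sigmoid, returning per-cell lag and transition times with
#' standard errors. Dissipating cells (significantly decreasing
#' trajectories) are flagged and not assigned a lag; trajectories whose
#' fitted midpoint falls beyond the record are flagged censored.
#'
#' @param trajectories A data frame with columns `cell_id`, `t_h`,
#'   `skewness`.
#' @param min_span_h Minimum record span required per cell, h.
#' @return A tibble with one row per cell: sigmoid parameters, `lag_time`,
#'   `transition_time`, their standard errors, and `flag`.
#' @export
single_cell_kinetics <- function(trajectories, min_span_h = 2) {
  stopifnot(all(c("cell_id", "t_h", "skewness") %in% names(trajectories)))
  trajectories |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_modify(function(df, key) {
      if (diff(range(df$t_h)) < min_span_h)
        stop(sprintf("cell %s: trajectory spans < %g h", key$cell_id,
                     min_span_h))
      df <- dplyr::arrange(df, .data$t_h)
      rng <- range(df$skewness)
      norm <- if (diff(rng) > 0) (df$skewness - rng[1]) / diff(rng)
              else df$skewness * 0
      fit <- tryCatch(fit_sigmoid(df$t_h, norm), error = function(e) e)
      if (inherits(fit, "error")) {
        # no convergent sigmoid: either the transition never entered the
        # record (signal still rising at the end) or there is none at all
        flag <- if (which.max(norm) > 0.8 * length(norm)) "censored"
                else "no_transition"
        fit <- punctakin_failed_fit(df$t_h, norm, flag)
      }
      g <- glance(fit)
      g$lag_se <- sqrt(fit$se["c"]^2 + 4 * fit$se["d"]^2)
      g$transition_se <- 4 * fit$se["d"]
      g
    }) |>
    dplyr::ungroup()
}
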