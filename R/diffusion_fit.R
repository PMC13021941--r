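#' Fit a Brownian diffusion-state mixture to a displacement distribution
#'
#' Maximum-likelihood fit of a K-component mixture of 2-D Brownian
#' (Rayleigh) step-length distributions,
#' `p(r) = sum_k f_k (r / sigma_k^2) exp(-r^2 / (2 sigma_k^2))` with
#' `sigma_k^2 = 2 D_k t_lag + 2 epsilon^2`, to binned displacement
#' lengths (multinomial likelihood on the bins; the last bin absorbs the
#' upper tail). `K = "auto"` selects among 1-3 states by BIC. States are
#' returned in ascending order of D with 95% confidence intervals from
#' the observed information (delta method).
#'
#' @param dist A [displacement_distribution()] (ideally
#'   confinement-corrected; an uncorrected input is fitted as-is and the
#'   result notes `corrected = FALSE`).
#' @param K Number of states, or `"auto"`.
#' @param epsilon Localization error, µm; defaults to the distribution's
#'   own metadata (0 after deconvolution, which absorbs the error).
#' @param n_restarts Random restarts of the optimizer.
#' @param min_fraction,min_separation Resolvability constraints applied
#'   during `"auto"` selection only: candidate models with any state
#'   below `min_fraction` population or with adjacent diffusion
#'   constants closer than a factor `min_separation` are inadmissible
#'   (deconvolved histograms carry small correlated artefacts that plain
#'   BIC can mistake for additional tiny states).
#' @param seed Optional integer seed for the restarts.
#' @return An object of class `diffusion_fit` with elements `D`, `f`,
#'   `ci_D`, `ci_f` (95%), `epsilon`, `K`, `logLik`, `bic`, `n`,
#'   `corrected`. See [tidy.diffusion_fit()].
#' @examples
#' trk <- simulate_membrane_tracks(cell_geometry(),
#'   diffusion_states(0.15, 1, epsilon = 0), n_tracks = 60, seed = 2)
#' dd <- displacement_distribution(trk)
#' fit_diffusion_states(dd, K = 1)
#' @export
fit_diffusion_states <- function(dist, K = "auto", epsilon = NULL,
                                 n_restarts = 10, min_fraction = 0.05,
                                 min_separation = 3, seed = NULL) {
  stopifnot(inherits(dist, "displacement_distribution"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(epsilon)) epsilon <- dist$epsilon
  counts <- dist$counts
  edges <- dist$edges
  t_lag <- dist$t_lag
  n <- sum(counts)
  if (n <= 0) stop("empty displacement distribution")
  if (identical(K, "auto")) {
    fits <- lapply(1:3, function(k)
      tryCatch(fit_k_states(counts, edges, t_lag, epsilon, k, n_restarts),
               error = function(e) NULL))
    bics <- vapply(fits, function(f) if (is.null(f)) Inf else f$bic,
                   numeric(1))
    admissible <- vapply(fits, function(f) {
      if (is.null(f)) return(FALSE)
      if (any(f$f < min_fraction)) return(FALSE)
      if (f$K > 1 &&
          any(f$sigma2[-1] / f$sigma2[-f$K] < min_separation))
        return(FALSE)
      TRUE
    }, logical(1))
    if (any(admissible)) bics[!admissible] <- Inf
    if (all(!is.finite(bics))) stop("mixture fit failed for K = 1..3")
    fit <- fits[[which.min(bics)]]
  } else {
    fit <- fit_k_states(counts, edges, t_lag, epsilon, as.integer(K),
                        n_restarts)
  }
  fit$corrected <- isTRUE(dist$corrected)
  fit
}

#' @noRd
fit_k_states <- function(counts, edges, t_lag, epsilon, K, n_restarts) {
  nb <- length(counts)
  n <- sum(counts)
  # bin probabilities: Rayleigh CDF differences; last bin extends to Inf
  lo2 <- edges[-(nb + 1)]^2
  hi2 <- c(edges[2:nb], Inf)^2
  bin_prob <- function(sig2) {
    p <- exp(-lo2 / (2 * sig2)) - exp(-hi2 / (2 * sig2))
    pmax(p, 1e-300)
  }
  # parameters: log sigma2_k (K), then K-1 softmax weights
  npar <- 2 * K - 1
  unpack <- function(par) {
    sig2 <- exp(par[1:K])
    w <- if (K == 1) 1 else {
      e <- exp(c(par[(K + 1):npar], 0))
      e / sum(e)
    }
    list(sig2 = sig2, w = w)
  }
  nll <- function(par) {
    u <- unpack(par)
    p <- rep(0, nb)
    for (k in seq_len(K)) p <- p + u$w[k] * bin_prob(u$sig2[k])
    -sum(counts * log(p))
  }
  # moment-based anchor for sigma2, spread across decades for K > 1
  m2 <- sum(counts * ((edges[-1] + edges[-(nb + 1)]) / 2)^2) / n
  sig2_anchor <- m2 / 2
  best <- NULL
  for (r in seq_len(n_restarts)) {
    s0 <- if (r == 1) {
      log(sig2_anchor * 4^(seq_len(K) - (K + 1) / 2))
    } else {
      log(sig2_anchor) + stats::rnorm(K, 0, 1.5)
    }
    par0 <- c(sort(s0), rep(0, K - 1))
    opt <- tryCatch(
      stats::optim(par0, nll, method = "BFGS",
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value))
      best <- opt
  }
  if (is.null(best)) stop("mixture optimization failed across restarts")
  u <- unpack(best$par)
  ord <- order(u$sig2)
  sig2 <- u$sig2[ord]
  w <- u$w[ord]
  D <- pmax((sig2 - 2 * epsilon^2) / (2 * t_lag), 0)
  # delta-method CIs from the observed information
  H <- tryCatch(stats::optimHess(best$par, nll), error = function(e) NULL)
  ci_D <- matrix(NA_real_, K, 2)
  ci_f <- matrix(NA_real_, K, 2)
  se_par <- rep(NA_real_, npar)
  if (!is.null(H)) {
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V) && all(diag(V) > 0)) {
      se_par <- sqrt(diag(V))
      z <- stats::qnorm(0.975)
      se_logsig <- se_par[1:K][ord]
      ci_sig2 <- cbind(sig2 * exp(-z * se_logsig), sig2 * exp(z * se_logsig))
      ci_D <- (ci_sig2 - 2 * epsilon^2) / (2 * t_lag)
      if (K > 1) {
        # numeric delta method for the weights
        J <- numeric_jacobian(function(p) unpack(p)$w[ord], best$par)
        se_w <- sqrt(pmax(diag(J %*% V %*% t(J)), 0))
        ci_f <- cbind(pmax(w - z * se_w, 0), pmin(w + z * se_w, 1))
      } else {
        ci_f <- matrix(c(1, 1), 1, 2)
      }
    }
  }
  structure(list(D = D, f = w, sigma2 = sig2, ci_D = ci_D, ci_f = ci_f,
                 epsilon = epsilon, t_lag = t_lag, K = K,
                 logLik = -best$value,
                 bic = 2 * best$value + npar * log(n), n = n,
                 edges = edges, counts = counts),
            class = "diffusion_fit")
}

#' @noRd
numeric_jacobian <- function(fn, x, h = 1e-5) {
  f0 <- fn(x)
  J <- matrix(0, length(f0), length(x))
  for (i in seq_along(x)) {
    xp <- x
    xp[i] <- xp[i] + h
    J[, i] <- (fn(xp) - f0) / h
  }
  J
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("<diffusion_fit> K = %d states, n = %g displacements, BIC %.1f\n",
              x$K, x$n, x$bic))
  for (k in seq_len(x$K))
    cat(sprintf("  D%d = %.4g um^2/s (95%% CI %.3g-%.3g), f%d = %.3f\n",
                k, x$D[k], x$ci_D[k, 1], x$ci_D[k, 2], k, x$f[k]))
  invisible(x)
}

#' Tidy a diffusion-state mixture fit
#'
#' One row per state: `state`, `D`, `f`, and 95% CI bounds.
#'
#' @param x A `diffusion_fit`.
#' @param ... Unused.
#' @export
tidy.diffusion_fit <- function(x, ...) {
  tibble::tibble(state = seq_len(x$K), D = x$D, f = x$f,
                 D_lo = x$ci_D[, 1], D_hi = x$ci_D[, 2],
                 f_lo = x$ci_f[, 1], f_hi = x$ci_f[, 2])
}

#' One-row summary of a diffusion fit
#'
#' @param x A `diffusion_fit`.
#' @param ... Unused.
#' @export
glance.diffusion_fit <- function(x, ...) {
  tibble::tibble(K = x$K, logLik = x$logLik, bic = x$bic, n = x$n,
                 epsilon = x$epsilon, corrected = isTRUE(x$corrected))
}
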