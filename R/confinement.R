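#' Monte-Carlo confinement operator
#'
#' Builds the forward operator that maps true (unconfined) Brownian step
#' lengths to observed, cell-confined, image-plane displacement lengths.
#' For each true-length bin, emitters are placed area-uniformly on the
#' spherocylinder surface and walked a geodesic distance equal to the bin
#' midpoint in a random tangent direction (sub-stepped with parallel
#' transport so the walk follows the curved surface); both endpoints are
#' projected orthographically and perturbed by the localization error,
#' and the resulting observed length is binned on the same grid
#' (overflow into the last bin). Column `j` of the matrix is therefore
#' the observed-length distribution given a true step in bin `j`, and
#' every column sums to 1.
#'
#' On the cylindrical body the geodesic forward model is exact for
#' Brownian steps (the cylinder is developable, i.e. flat); the
#' spherical caps introduce a small curvature bias for steps comparable
#' to the cell radius.
#'
#' @param geometry A [cell_geometry()].
#' @param edges Bin edges shared by true and observed lengths (start at 0).
#' @param epsilon Localization error per coordinate, µm.
#' @param n_mc Monte-Carlo samples per true-length bin (>= 1e4
#'   recommended).
#' @param n_substeps Sub-steps per walk.
#' @param project If `TRUE` (default, matching what the microscope
#'   records), observed lengths are orthographic image-plane projections;
#'   if `FALSE`, the 3-D chord length between the endpoints is used
#'   (confinement-only operator, which tends to the identity as the cell
#'   grows much larger than the steps).
#' @param seed Optional integer seed.
#' @return An object of class `confinement_operator`: `M`
#'   (observed x true, column-stochastic), `edges`, `geometry`,
#'   `epsilon`, `n_mc`.
#' @export
build_confinement_operator <- function(geometry, edges, epsilon = 0,
                                       n_mc = 1e4, n_substeps = 10,
                                       project = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(geometry, "cell_geometry"), edges[1] == 0,
            !is.unsorted(edges, strictly = TRUE), n_mc >= 1)
  if (geometry$radius <= 0) stop("degenerate geometry")
  nb <- length(edges) - 1
  mids <- (edges[-1] + edges[-(nb + 1)]) / 2
  M <- matrix(0, nb, nb)
  for (j in seq_len(nb)) {
    start <- sample_surface(geometry, n_mc)
    pos <- start
    # random initial tangent direction, parallel-transported along the walk
    nrm <- surface_normal(geometry, pos)
    tb <- tangent_basis(nrm)
    th <- stats::runif(n_mc, 0, 2 * pi)
    dir <- tb$u1 * cos(th) + tb$u2 * sin(th)
    step <- mids[j] / n_substeps
    if (mids[j] > 0) {
      for (ss in seq_len(n_substeps)) {
        pos_new <- project_to_surface(geometry, pos + dir * step)
        nrm <- surface_normal(geometry, pos_new)
        dp <- rowSums(dir * nrm)
        dir <- dir - nrm * dp
        nr <- sqrt(rowSums(dir^2))
        ok <- nr > 1e-12
        dir[ok, ] <- dir[ok, , drop = FALSE] / nr[ok]
        pos <- pos_new
      }
    }
    if (project) {
      p0 <- local_to_image(geometry, start) +
        matrix(stats::rnorm(2 * n_mc, 0, epsilon), n_mc, 2)
      p1 <- local_to_image(geometry, pos) +
        matrix(stats::rnorm(2 * n_mc, 0, epsilon), n_mc, 2)
      r_obs <- sqrt(rowSums((p1 - p0)^2))
    } else {
      d3 <- pos - start +
        matrix(stats::rnorm(3 * n_mc, 0, epsilon * sqrt(2)), n_mc, 3)
      r_obs <- sqrt(rowSums(d3^2))
    }
    M[, j] <- bin_clamped(r_obs, edges) / n_mc
  }
  structure(list(M = M, edges = edges, geometry = geometry,
                 epsilon = epsilon, n_mc = n_mc),
            class = "confinement_operator")
}

#' @export
print.confinement_operator <- function(x, ...) {
  cat(sprintf(
    "<confinement_operator> %d x %d bins (0-%.3g um), n_mc %g, epsilon %g um\n",
    nrow(x$M), ncol(x$M), max(x$edges), x$n_mc, x$epsilon))
  invisible(x)
}

#' Deconvolve cell-confinement effects from a displacement distribution
#'
#' Inverse transformation of the confinement operator: solves
#' `M x = observed` for the true step-length distribution by nonnegative
#' least squares with a Tikhonov penalty `lambda * ||L x||^2`, then
#' rescales the solution to the observed total count. The default
#' penalty operator `L` is the second difference (a smoothness prior,
#' which suppresses the spiky artefacts typical of unregularized NNLS
#' deconvolution); `penalty = "ridge"` uses the identity instead. With
#' `lambda = 0` and an ill-conditioned operator, a warning is issued and
#' `lambda` is chosen automatically at the corner of the L-curve.
#'
#' Because the operator already accounts for projection and localization
#' error, the corrected distribution approximates the intrinsic Brownian
#' step lengths and carries `epsilon = 0`.
#'
#' @param observed A [displacement_distribution()] binned on the
#'   operator's edges.
#' @param op A [build_confinement_operator()] result.
#' @param lambda Tikhonov regularization parameter (on the scale of the
#'   normalized distribution).
#' @param penalty Penalty operator: `"smooth"` (second difference,
#'   default) or `"ridge"` (identity).
#' @return A corrected `displacement_distribution`.
#' @export
deconvolve_confinement <- function(observed, op, lambda = 0.01,
                                   penalty = c("smooth", "ridge")) {
  penalty <- match.arg(penalty)
  stopifnot(inherits(observed, "displacement_distribution"),
            inherits(op, "confinement_operator"))
  if (length(observed$counts) != ncol(op$M) ||
      max(abs(observed$edges - op$edges)) > 1e-9)
    stop("incompatible binning between distribution and operator")
  total <- sum(observed$counts)
  if (total == 0) {
    out <- observed
    out$epsilon <- 0
    return(out)
  }
  y <- observed$counts / total
  nb <- length(y)
  if (lambda == 0) {
    kap <- kappa(op$M, exact = FALSE)
    if (!is.finite(kap) || kap > 1e8) {
      warning("operator is ill-conditioned; selecting lambda by L-curve")
      lambda <- lcurve_lambda(op$M, y, penalty = penalty)
    }
  }
  x <- nnls_tikhonov(op$M, y, lambda, penalty)
  if (sum(x) <= 0) stop("deconvolution produced an empty distribution")
  out <- observed
  out$counts <- x / sum(x) * total
  out$epsilon <- 0
  out$r <- NULL
  out$corrected <- TRUE
  out
}

#' @noRd
nnls_tikhonov <- function(M, y, lambda, penalty = "smooth") {
  nb <- ncol(M)
  L <- if (penalty == "ridge" || nb < 3) diag(nb)
       else diff(diag(nb), differences = 2)
  A <- rbind(M, sqrt(lambda) * L)
  b <- c(y, rep(0, nrow(L)))
  pracma::lsqnonneg(A, b)$x
}

# L-curve corner by maximum curvature over a log-spaced lambda grid
#' @noRd
lcurve_lambda <- function(M, y, grid = 10^seq(-6, 0, length.out = 13),
                          penalty = "smooth") {
  res <- vapply(grid, function(l) {
    x <- nnls_tikhonov(M, y, l, penalty)
    c(log(sum((M %*% x - y)^2) + 1e-300), log(sum(x^2) + 1e-300))
  }, numeric(2))
  rho <- res[1, ]
  eta <- res[2, ]
  n <- length(grid)
  curv <- rep(-Inf, n)
  for (i in 2:(n - 1)) {
    d1 <- c(rho[i + 1] - rho[i - 1], eta[i + 1] - eta[i - 1]) / 2
    d2 <- c(rho[i + 1] - 2 * rho[i] + rho[i - 1],
            eta[i + 1] - 2 * eta[i] + eta[i - 1])
    denom <- (d1[1]^2 + d1[2]^2)^1.5
    if (denom > 0) curv[i] <- (d1[1] * d2[2] - d2[1] * d1[2]) / denom
  }
  grid[which.max(curv)]
}
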