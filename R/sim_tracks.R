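#' Simulate stroboscopic single-molecule tracks on a cell
#'
#' Generates single-molecule trajectories under a K-state Brownian mixture
#' on a spherocylindrical cell, observed stroboscopically (exposure
#' `t_int` every `t_tl`). Each molecule draws one diffusion state from the
#' state fractions and keeps it for its lifetime. Membrane-mode states
#' diffuse on the envelope surface (tangent-plane steps re-projected to
#' the surface, with sub-stepping so individual steps stay well below the
#' cell radius); volume-mode states (the fast periplasmic population)
#' diffuse in three dimensions inside the cell body. Positions are
#' projected orthographically to the image plane and perturbed by i.i.d.
#' Gaussian localization error. Track length is geometric: bleaching
#' occurs only during the laser exposure, with per-frame survival
#' `exp(-k_bl * t_int)`.
#'
#' @param geometry A [cell_geometry()].
#' @param states A [diffusion_states()] mixture (its `epsilon` is the
#'   localization error applied per coordinate).
#' @param n_tracks Number of molecules to track.
#' @param n_frames Maximum movie length, frames.
#' @param optics An [optics_camera()] (supplies `t_int`, `t_tl`, gain).
#' @param k_bl Photobleaching rate constant during exposure, 1/s.
#' @param brightness Mean photons per localization (intensities are drawn
#'   from the same EMCCD model as rendered images).
#' @param n_substeps Brownian sub-steps per frame (>= 1).
#' @param seed Optional integer seed.
#' @return A tibble with columns `track_id`, `frame` (0-based), `t_s`,
#'   `x_um`, `y_um`, `intensity`, and ground-truth `state` (index into
#'   `states`, ascending D).
#' @examples
#' trk <- simulate_membrane_tracks(cell_geometry(),
#'   diffusion_states(0.15, 1, epsilon = 0.03), n_tracks = 10, seed = 1)
#' @export
simulate_membrane_tracks <- function(geometry, states, n_tracks = 100,
                                     n_frames = 500,
                                     optics = optics_camera(), k_bl = 15,
                                     brightness = 100, n_substeps = 10,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(states, "diffusion_states"), n_tracks >= 0,
            n_substeps >= 1, k_bl >= 0)
  if (n_tracks == 0) {
    return(tibble::tibble(track_id = integer(), frame = integer(),
                          t_s = numeric(), x_um = numeric(),
                          y_um = numeric(), intensity = numeric(),
                          state = integer()))
  }
  t_tl <- optics$t_tl
  t_int <- optics$t_int
  mode <- states$mode %||% rep("membrane", states$K)

  state_id <- sample.int(states$K, n_tracks, replace = TRUE, prob = states$f)
  # geometric track length; bleaching only during exposure
  surv <- exp(-k_bl * t_int)
  len <- if (surv >= 1) rep(as.integer(n_frames), n_tracks)
         else pmin(stats::rgeom(n_tracks, prob = 1 - surv) + 1L, n_frames)

  dt <- t_tl / n_substeps
  out <- vector("list", states$K)
  for (k in seq_len(states$K)) {
    idx <- which(state_id == k)
    if (length(idx) == 0) next
    m <- length(idx)
    maxlen <- max(len[idx])
    D <- states$D[k]
    sd_sub <- sqrt(2 * D * dt)
    pos <- sample_surface(geometry, m)
    if (mode[k] == "volume") {
      # start uniformly inside the body: shrink surface points by a random
      # radial factor with the correct cross-sectional density
      u <- sqrt(stats::runif(m))
      foot <- axis_foot(geometry, pos)
      pos <- foot + (pos - foot) * u
    }
    traj <- array(NA_real_, c(m, maxlen, 3))
    traj[, 1, ] <- pos
    if (sd_sub == 0 && maxlen > 1) {
      # immobile state: position is exactly constant
      for (fr in 2:maxlen) traj[, fr, ] <- pos
    }
    if (maxlen > 1 && sd_sub > 0) {
      for (fr in 2:maxlen) {
        for (ss in seq_len(n_substeps)) {
          if (mode[k] == "volume") {
            pos <- pos + matrix(stats::rnorm(3 * m, 0, sd_sub), m, 3)
            # clamp back inside the body
            foot <- axis_foot(geometry, pos)
            d <- pos - foot
            nr <- sqrt(rowSums(d^2))
            over <- nr > geometry$radius
            if (any(over))
              pos[over, ] <- foot[over, , drop = FALSE] +
                d[over, , drop = FALSE] *
                (geometry$radius / nr[over])
          } else {
            nrm <- surface_normal(geometry, pos)
            tb <- tangent_basis(nrm)
            g1 <- stats::rnorm(m, 0, sd_sub)
            g2 <- stats::rnorm(m, 0, sd_sub)
            pos <- pos + tb$u1 * g1 + tb$u2 * g2
            pos <- project_to_surface(geometry, pos)
          }
        }
        traj[, fr, ] <- pos
      }
    }
    rows <- lapply(seq_len(m), function(j) {
      L <- len[idx[j]]
      tibble::tibble(track_id = idx[j], frame = 0:(L - 1),
                     x3 = traj[j, 1:L, 1], y3 = traj[j, 1:L, 2],
                     state = k)
    })
    df <- dplyr::bind_rows(rows)
    xy <- local_to_image(geometry,
                         cbind(df$x3, df$y3, 0))  # z never projects
    df$x_um <- xy[, 1]
    df$y_um <- xy[, 2]
    out[[k]] <- df
  }
  res <- dplyr::bind_rows(out)
  res <- dplyr::arrange(res, .data$track_id, .data$frame)
  n <- nrow(res)
  eps <- states$epsilon
  res$x_um <- res$x_um + stats::rnorm(n, 0, eps)
  res$y_um <- res$y_um + stats::rnorm(n, 0, eps)
  nph <- stats::rpois(n, brightness)
  inten <- numeric(n)
  posph <- nph > 0
  inten[posph] <- stats::rgamma(sum(posph), shape = nph[posph],
                                scale = optics$em_gain)
  res$t_s <- res$frame * t_tl
  res$intensity <- inten
  tibble::as_tibble(res[, c("track_id", "frame", "t_s", "x_um", "y_um",
                            "intensity", "state")])
}

# Orthonormal tangent basis at surface points with unit normals `n`
# (m x 3). Vectorised Gram-Schmidt against a reference axis chosen per
# point to avoid degeneracy.
#' @noRd
tangent_basis <- function(n) {
  m <- nrow(n)
  # reference: x-axis unless the normal is nearly parallel to it
  ref <- matrix(rep(c(1, 0, 0), each = m), m, 3)
  par <- abs(n[, 1]) > 0.9
  if (any(par)) ref[par, ] <- matrix(rep(c(0, 1, 0), each = sum(par)),
                                     sum(par), 3)
  dotp <- rowSums(ref * n)
  u1 <- ref - n * dotp
  u1 <- u1 / sqrt(rowSums(u1^2))
  u2 <- cbind(n[, 2] * u1[, 3] - n[, 3] * u1[, 2],
              n[, 3] * u1[, 1] - n[, 1] * u1[, 3],
              n[, 1] * u1[, 2] - n[, 2] * u1[, 1])
  list(u1 = u1, u2 = u2)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
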