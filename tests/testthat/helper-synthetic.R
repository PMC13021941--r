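# shared fixtures, built in code

default_geom <- function() cell_geometry(length = 3, radius = 0.4)

# fast optics for rendering tests: fewer pixels than the defaults
test_optics <- function(...) {
  optics_camera(psf_sigma = 0.13, pixel_size = 0.1, background = 5,
                em_gain = 250, read_noise = 10, t_int = 0.004,
                t_tl = 0.06, ...)
}

# near-planar regime: 3-D diffusion deep inside a huge cell, so the
# projected steps follow the unconfined Rayleigh law exactly
planar_tracks <- function(D, n_tracks, epsilon = 0, seed = 1,
                          k_bl = 15, n_frames = 500) {
  g <- cell_geometry(length = 200, radius = 50)
  st <- diffusion_states(D, 1, epsilon = epsilon, mode = "volume")
  simulate_membrane_tracks(g, st, n_tracks = n_tracks, k_bl = k_bl,
                           n_frames = n_frames, seed = seed)
}

# brute-force punctum detector used as an independent cross-check for the
# skewness classifier: top-hat statistic = max mean intensity in a disk
# over the cell, relative to the in-cell mean
tophat_stat <- function(img, disk_px = 3) {
  m <- img$image
  mask <- img$mask
  ny <- nrow(m); nx <- ncol(m)
  best <- -Inf
  idx <- which(mask, arr.ind = TRUE)
  offs <- expand.grid(dr = -disk_px:disk_px, dc = -disk_px:disk_px)
  offs <- offs[offs$dr^2 + offs$dc^2 <= disk_px^2, ]
  for (i in seq_len(nrow(idx))) {
    r <- idx[i, 1]; c <- idx[i, 2]
    rr <- r + offs$dr; cc <- c + offs$dc
    ok <- rr >= 1 & rr <= ny & cc >= 1 & cc <= nx
    best <- max(best, mean(m[cbind(rr[ok], cc[ok])]))
  }
  best / mean(m[mask])
}
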