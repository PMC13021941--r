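test_that("punctum Gaussian fit recovers center and width", {
  # noiseless rendered Gaussian spot, sigma = 0.2 um
  px <- 0.05
  xs <- (0:59) * px
  img <- outer(xs, xs, function(y, x)
    50 + 800 * exp(-((x - 1.52)^2 + (y - 1.48)^2) / (2 * 0.2^2)))
  pf <- fit_punctum(img, init_center = c(1.4, 1.4), pixel_size = px)
  expect_lt(abs(pf$x_um - 1.52), 0.01)
  expect_lt(abs(pf$y_um - 1.48), 0.01)
  expect_equal(pf$sigma_um, 0.2, tolerance = 0.05)
  expect_identical(pf$r_um, 2 * pf$sigma_um)
  # flat image is rejected
  expect_error(fit_punctum(matrix(7, 40, 40), init_center = c(1, 1),
                           pixel_size = px), "flat|converge|rejected")
  # two equal spots: converges to the one nearest the initial center
  img2 <- outer(xs, xs, function(y, x)
    10 + 500 * exp(-((x - 0.8)^2 + y^2) / (2 * 0.15^2)) +
      500 * exp(-((x - 2.2)^2 + y^2) / (2 * 0.15^2)))
  pf2 <- fit_punctum(img2, init_center = c(0.9, 0.1), pixel_size = px)
  expect_lt(abs(pf2$x_um - 0.8), 0.1)
})

test_that("residence extraction thresholds distance trajectories correctly", {
  pc <- list(x_um = 0, y_um = 0, r_um = 0.3)
  # track always inside: one censored dwell of the full duration
  inside <- tibble::tibble(frame = 0:9, x_um = 0.1, y_um = 0)
  rs <- residence_times(inside, pc, t_tl = 0.06, gap_tolerance = 0)
  expect_identical(nrow(rs), 1L)
  expect_equal(rs$tau_in, 10 * 0.06)
  expect_true(rs$censored)
  # alternating in/out with zero gap tolerance: all dwells 1 frame
  alt <- tibble::tibble(frame = 0:9, x_um = rep(c(0, 1), 5), y_um = 0)
  rs2 <- residence_times(alt, pc, t_tl = 0.06, gap_tolerance = 0)
  expect_identical(nrow(rs2), 5L)
  expect_true(all(rs2$tau_in == 0.06))
  # gap tolerance 1 merges the alternating runs into one dwell
  rs3 <- residence_times(alt, pc, t_tl = 0.06, gap_tolerance = 1)
  expect_identical(nrow(rs3), 1L)
  # rigid translation + rotation of the frame leaves dwells unchanged
  th <- 0.6
  rot <- function(x, y) list(x = cos(th) * x - sin(th) * y + 3,
                             y = sin(th) * x + cos(th) * y - 1)
  altr <- rot(alt$x_um, alt$y_um)
  pcr <- rot(pc$x_um, pc$y_um)
  rs4 <- residence_times(tibble::tibble(frame = alt$frame, x_um = altr$x,
                                        y_um = altr$y),
                         list(x_um = pcr$x, y_um = pcr$y, r_um = 0.3),
                         t_tl = 0.06, gap_tolerance = 0)
  expect_equal(rs4, rs2)
})

test_that("constructed exchange trajectories return their ground-truth dwells", {
  set.seed(51)
  pc <- list(x_um = 0, y_um = 0, r_um = 0.3)
  dwell_frames <- rgeom(200, prob = 0.2) + 1
  out_frames <- rgeom(200, prob = 0.5) + 2   # > gap tolerance
  pos <- integer(0)
  for (i in 1:200) pos <- c(pos, rep(0L, dwell_frames[i]),
                            rep(1L, out_frames[i]))
  trk <- tibble::tibble(frame = seq_along(pos) - 1L,
                        x_um = ifelse(pos == 0, 0.1, 1.5), y_um = 0)
  rs <- residence_times(trk, pc, t_tl = 0.06, gap_tolerance = 1)
  got <- rs$tau_in[!rs$censored]
  expect_identical(length(got), 200L)
  expect_equal(sort(got), sort(dwell_frames * 0.06))
  # geometric MLE on these dwells recovers the generating rate
  kr <- fit_escape_rate(rs, k_bl = 0)
  expect_equal(kr$k_eff, -log(1 - 0.2) / 0.06, tolerance = 0.15)
})

test_that("bleaching correction identity and failure modes", {
  opt <- optics_camera()
  rs <- simulate_punctum_residence(3.1, 15, opt, 1500, seed = 52)
  kr <- fit_escape_rate(rs, k_bl = 15, optics = opt)
  # identity k_eff = k_bl t_int/t_tl + k_e holds exactly
  expect_identical(kr$k_eff, kr$k_bl * kr$t_int / kr$t_tl + kr$k_e)
  expect_equal(kr$k_e, 3.1, tolerance = 0.35)
  # k_bl = 0 leaves k_e = k_eff
  kr0 <- fit_escape_rate(rs, k_bl = 0, optics = opt)
  expect_identical(kr0$k_e, kr0$k_eff)
  # over-correction is an error
  expect_error(fit_escape_rate(rs, k_bl = 500, optics = opt), "invalid")
  # all-censored input is an error
  expect_error(fit_escape_rate(tibble::tibble(tau_in = c(1, 2),
                                              censored = c(TRUE, TRUE))),
               "censored|uncensored")
})

test_that("escape-rate CIs achieve nominal coverage across conditions", {
  # 150 replicates per condition: at the nominal 95% coverage the
  # binomial noise on the observed rate is ~1.8 points, so the 90%
  # bound discriminates real undercoverage from sampling noise
  opt <- optics_camera()
  for (pars in list(c(0.5, 0), c(3.1, 15), c(10, 15))) {
    k_e <- pars[1]; k_bl <- pars[2]
    hits <- vapply(1:150, function(i) {
      rs <- simulate_punctum_residence(k_e, k_bl, opt, 400,
                                       seed = 5200 + i)
      kr <- fit_escape_rate(rs, k_bl = k_bl, optics = opt)
      kr$k_e_ci[1] <= k_e && k_e <= kr$k_e_ci[2]
    }, logical(1))
    expect_gte(mean(hits), 0.9)
  }
})

test_that("bleach-rate estimation recovers the generator value", {
  g <- default_geom()
  st <- diffusion_states(0.15, 1)
  trk <- simulate_membrane_tracks(g, st, n_tracks = 1000, k_bl = 15,
                                  n_frames = 500, seed = 53)
  kb <- estimate_bleach_rate(trk, max_frames = 500)
  expect_equal(as.numeric(kb), 15, tolerance = 0.1)
  # no bleaching: every track is movie-limited, estimate 0
  trk0 <- simulate_membrane_tracks(g, st, n_tracks = 150, k_bl = 0,
                                   n_frames = 50, seed = 54)
  expect_identical(as.numeric(estimate_bleach_rate(trk0,
                                                   max_frames = 50)), 0)
  expect_error(estimate_bleach_rate(trk[trk$track_id <= 10, ]), "tracks")
})

test_that("entry rate follows the quasi-equilibrium balance", {
  expect_identical(entry_rate(3.1, 100, 100), 3.1)
  expect_identical(entry_rate(3.1, 0, 50), 0)
  expect_error(entry_rate(3.1, 10, 0), "positive")
  # two-state telegraph occupancy: k_c recovered from time-averaged counts
  set.seed(55)
  k_e <- 3.1; k_c_true <- 0.6
  state <- logical(8e4)  # TRUE = inside
  dt <- 0.01
  s <- FALSE
  for (i in seq_along(state)) {
    p_switch <- if (s) k_e * dt else k_c_true * dt
    if (runif(1) < p_switch) s <- !s
    state[i] <- s
  }
  k_c_hat <- entry_rate(k_e, sum(state), sum(!state))
  expect_equal(k_c_hat, k_c_true, tolerance = 0.15)
})
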