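test_that("displacement distribution counts every pair and honors lags", {
  trk <- tibble::tibble(track_id = 1, frame = 0:1, t_s = c(0, 0.06),
                        x_um = c(1, 1), y_um = c(2, 2),
                        intensity = c(10, 10))
  dd <- displacement_distribution(trk, bins = c(0, 0.1, 0.2))
  expect_identical(dd$counts, c(1L, 0L))
  expect_identical(dd$n, 1L)
  expect_error(displacement_distribution(trk, lag_frames = 5), "no displacement")
  # lag 2 doubles the mean squared displacement for Brownian motion
  trk2 <- planar_tracks(0.15, n_tracks = 400, seed = 41)
  d1 <- displacement_distribution(trk2, lag_frames = 1)
  d2 <- displacement_distribution(trk2, lag_frames = 2)
  expect_equal(mean(d2$r^2) / mean(d1$r^2), 2, tolerance = 0.06)
  # a displacement across a gap is excluded
  gappy <- tibble::tibble(track_id = 1, frame = c(0, 1, 3),
                          t_s = c(0, 0.06, 0.18),
                          x_um = c(0, 1, 2), y_um = 0, intensity = 1)
  expect_identical(displacement_distribution(gappy,
                                             bins = c(0, 2, 4))$n, 1L)
})

test_that("projected steps follow the Rayleigh law in the unconfined regime", {
  trk <- planar_tracks(0.15, n_tracks = 700, epsilon = 0, seed = 42)
  dd <- displacement_distribution(trk)
  expect_gte(dd$n, 1e4)
  sigma <- sqrt(2 * 0.15 * 0.06)
  ks <- stats::ks.test(dd$r, function(q) 1 - exp(-q^2 / (2 * sigma^2)))
  expect_gt(ks$p.value, 0.01)
})

test_that("confinement operator is column-stochastic and tends to identity unconfined", {
  g <- default_geom()
  edges <- seq(0, 1, length.out = 21)
  op <- build_confinement_operator(g, edges, epsilon = 0.03, n_mc = 2000,
                                   seed = 43)
  expect_lt(max(abs(colSums(op$M) - 1)), 1e-12)
  expect_true(all(op$M >= 0))
  # cell much larger than any step: chord-length operator ~ identity
  gbig <- cell_geometry(length = 400, radius = 100)
  opb <- build_confinement_operator(gbig, edges, epsilon = 0,
                                    n_mc = 2000, project = FALSE,
                                    seed = 44)
  expect_lt(1 - mean(diag(opb$M)), 0.05)
  expect_error(build_confinement_operator(g, c(0.1, 0.2)), "edges")
})

test_that("deconvolution inverts the forward operator", {
  g <- default_geom()
  set.seed(45)
  trk <- simulate_membrane_tracks(g, diffusion_states(0.15, 1,
                                                      epsilon = 0.03),
                                  n_tracks = 200, seed = 45)
  dd <- displacement_distribution(trk, bins = 40, epsilon = 0.03)
  op <- build_confinement_operator(g, dd$edges, epsilon = 0.03,
                                   n_mc = 5000, seed = 46)
  # M = identity -> output = input
  op_id <- op
  op_id$M <- diag(length(dd$counts))
  out <- deconvolve_confinement(dd, op_id, lambda = 0)
  expect_equal(out$counts, dd$counts, tolerance = 1e-6)
  # all-zero observed -> all-zero output
  zero <- dd
  zero$counts <- rep(0L, length(dd$counts))
  expect_identical(sum(deconvolve_confinement(zero, op)$counts), 0L)
  # forward-applied then deconvolved single-state distribution round-trips
  nb <- length(dd$counts)
  lo <- dd$edges[-(nb + 1)]
  hi <- c(dd$edges[2:nb], Inf)
  s2 <- 2 * 0.15 * 0.06
  p_true <- exp(-lo^2 / (2 * s2)) - exp(-hi^2 / (2 * s2))
  fwd <- dd
  fwd$counts <- as.numeric(op$M %*% (p_true * 1e5))
  dc <- deconvolve_confinement(fwd, op)
  tv <- 0.5 * sum(abs(dc$counts / sum(dc$counts) - p_true / sum(p_true)))
  expect_lte(tv, 0.05)
  # counts conserved
  expect_equal(sum(dc$counts), sum(fwd$counts))
})

test_that("two-state mixture and localization-error bookkeeping are exact where closed-form", {
  trk <- planar_tracks(0.15, n_tracks = 500, epsilon = 0, seed = 47)
  dd <- displacement_distribution(trk)
  fit <- fit_diffusion_states(dd, K = "auto", seed = 48)
  expect_identical(fit$K, 1L)
  expect_equal(fit$D[1], 0.15, tolerance = 0.1)
  # same data refitted with a declared epsilon shifts D by exactly
  # 2 eps^2 / (2 t): sigma^2 identity
  fit0 <- fit_diffusion_states(dd, K = 1, epsilon = 0, seed = 48)
  fit1 <- fit_diffusion_states(dd, K = 1, epsilon = 0.03, seed = 48)
  expect_equal(fit0$D[1] - fit1$D[1], 2 * 0.03^2 / (2 * 0.06),
               tolerance = 1e-6)
  # states come out ordered by D with fractions summing to 1
  expect_equal(sum(fit$f), 1)
})

test_that("displacement filter enriches the slow state in super-resolution rendering", {
  g <- cell_geometry(length = 200, radius = 50)
  st <- diffusion_states(c(0.15, 6), c(0.5, 0.5), epsilon = 0,
                         mode = c("volume", "volume"))
  trk <- simulate_membrane_tracks(g, st, n_tracks = 600, seed = 49)
  sr_all <- render_super_resolution(trk, r_max = Inf)
  expect_identical(sr_all$n_kept, nrow(trk))
  sr <- render_super_resolution(trk, r_max = 0.3)
  kept_state <- trk$state[sr$kept]
  # Rayleigh CDF per state at r = 0.3 um (either adjacent step passes):
  # slow retention high, fast retention low
  expect_gt(mean(sr$kept[trk$state == 1]), 0.9)
  expect_lt(mean(sr$kept[trk$state == 2]), 0.2)
  expect_identical(sum(sr$image), as.numeric(sr$n_kept))
  # empty result warns
  still <- tibble::tibble(track_id = 1, frame = 0:4, t_s = 0:4 * 0.06,
                          x_um = (0:4) * 2, y_um = 0, intensity = 1)
  expect_warning(render_super_resolution(still, r_max = 0.001), "filter")
})

test_that("punctum segmentation splits diffusion consistently", {
  g <- default_geom()
  st <- diffusion_states(0.12, 1, epsilon = 0.02)
  trk <- simulate_membrane_tracks(g, st, n_tracks = 700, seed = 50)
  pc <- list(x_um = 1.1, y_um = 0, r_um = 0.3)
  seg <- segment_by_punctum(trk, pc, t_tl = 0.06, epsilon = 0.02)
  # boundary point at exactly R is inside (closed ball); coordinates
  # chosen exactly representable in binary so the distance is exact
  pcb <- list(x_um = 1, y_um = 0, r_um = 0.25)
  bnd <- tibble::tibble(track_id = 1L, frame = 0L, t_s = 0,
                        x_um = 1.25, y_um = 0, intensity = 1)
  expect_true(segment_by_punctum(bnd, pcb, fit = FALSE)$labels$inside)
  # punctum covering the whole cell -> all inside
  seg_all <- segment_by_punctum(trk, list(x_um = 0, y_um = 0, r_um = 10),
                                fit = FALSE)
  expect_true(all(seg_all$labels$inside))
  # identical D in and out: fitted ratio within [0.8, 1.25]
  ratio <- seg$fit_in$D[1] / seg$fit_out$D[1]
  expect_gt(ratio, 0.8)
  expect_lt(ratio, 1.25)
})
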