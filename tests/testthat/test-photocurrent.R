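test_that("windowed dual-linear extraction is exact on clean traces", {
  tr <- simulate_current_trace(noise_sd = 0, drift_slope = 0,
                               i_photo_step = -0.4)
  ph <- extract_photocurrent(tr)
  expect_identical(ph$n_cycles, 3L)
  expect_equal(ph$cycles$i_ph_nA, rep(-0.4, 3), tolerance = 1e-10)
  # pure drift, no step: i_ph = 0 (both windows fit the same line)
  trd <- simulate_current_trace(noise_sd = 0, drift_slope = 0.02,
                                i_photo_step = 0)
  expect_equal(extract_photocurrent(trd)$mean_i_ph, 0, tolerance = 1e-10)
})

test_that("the estimator is linear and drift-invariant", {
  tr <- simulate_current_trace(noise_sd = 0.05, i_photo_step = -0.4,
                               drift_slope = 0.005, seed = 61)
  base <- extract_photocurrent(tr)$mean_i_ph
  # scaling the current scales i_ph
  tr2 <- tr
  tr2$current_nA <- 3 * tr$current_nA
  expect_equal(extract_photocurrent(tr2)$mean_i_ph, 3 * base,
               tolerance = 1e-10)
  # adding any global linear function changes nothing
  tr3 <- tr
  tr3$current_nA <- tr$current_nA + 7.5 - 0.3 * tr$t_s
  expect_equal(extract_photocurrent(tr3)$mean_i_ph, base,
               tolerance = 1e-10)
})

test_that("noisy extraction is unbiased with 1/sqrt(n) Monte-Carlo error", {
  est <- vapply(1:50, function(i) {
    tr <- simulate_current_trace(noise_sd = 0.05, i_photo_step = -0.4,
                                 drift_slope = 0, seed = 600 + i)
    extract_photocurrent(tr)$mean_i_ph
  }, numeric(1))
  expect_equal(mean(est), -0.4, tolerance = 3 * sd(est) / sqrt(50) / 0.4)
  # doubling the sampling rate (samples per window) shrinks the spread
  est_hi <- vapply(1:50, function(i) {
    tr <- simulate_current_trace(noise_sd = 0.05, i_photo_step = -0.4,
                                 sample_rate = 40, seed = 700 + i)
    extract_photocurrent(tr)$mean_i_ph
  }, numeric(1))
  expect_lt(sd(est_hi), sd(est))
})

test_that("truncated windows are skipped with a warning", {
  tr <- simulate_current_trace(noise_sd = 0, lead_s = 5)
  tr_cut <- tr[tr$t_s > 3.5, ]   # first pre-window now truncated
  expect_warning(ph <- extract_photocurrent(tr_cut), "truncated")
  expect_identical(ph$n_cycles, 2L)
})

test_that("delta_i compares on- and off-cell means with the cathodic sign convention", {
  on <- extract_photocurrent(simulate_current_trace(noise_sd = 0,
                                                    i_photo_step = -0.6))
  off <- extract_photocurrent(simulate_current_trace(noise_sd = 0,
                                                     i_photo_step = -0.2))
  expect_equal(delta_i(on, off), -0.4, tolerance = 1e-10)
  expect_lt(delta_i(on, off), 0)   # extra cathodic current on-cell
  expect_equal(delta_i(on, on), 0)
  # cycle-count mismatch warns but still returns the mean difference
  off2 <- extract_photocurrent(simulate_current_trace(noise_sd = 0,
                                                      i_photo_step = -0.2,
                                                      cycles = 2))
  expect_warning(dv <- delta_i(on, off2), "mismatch")
  expect_equal(dv, -0.4, tolerance = 1e-10)
})

test_that("Welch comparison matches the textbook formula and null behavior", {
  cg <- compare_groups(a = c(0, 1, 2), b = c(1, 2, 3))
  # hand computation: means 1 and 2, each var 1, n 3
  t_hand <- (1 - 2) / sqrt(1 / 3 + 1 / 3)
  df_hand <- (1 / 3 + 1 / 3)^2 / ((1 / 3)^2 / 2 + (1 / 3)^2 / 2)
  expect_equal(cg$tests$statistic, t_hand)
  expect_equal(cg$tests$df, df_hand)
  expect_equal(cg$tests$p.value, 2 * pt(t_hand, df_hand))
  # identical groups: zero difference, p = 1
  cg2 <- compare_groups(x = c(1, 2, 3, 4), y = c(1, 2, 3, 4))
  expect_equal(unname(diff(cg2$groups$mean)), 0)
  expect_equal(cg2$tests$p.value, 1)
  expect_error(compare_groups(a = 1, b = c(1, 2)), "n >= 2")
})

test_that("group comparison power matches its analytic expectation on realistic groups", {
  # per-cell delta_i drawn with group means -0.40 (punctum cells),
  # -0.20 (no-punctum cells), -0.20 (blank film); per-cell s.d. implied
  # by the reported s.e.m. (sd = sem * sqrt(n)), n = 53/47/48
  sd_w <- 0.07 * sqrt(53); sd_n <- 0.06 * sqrt(47); sd_b <- 0.06 * sqrt(48)
  set.seed(62)
  sig <- replicate(100, {
    w <- rnorm(53, -0.40, sd_w)
    no <- rnorm(47, -0.20, sd_n)
    bl <- rnorm(48, -0.20, sd_b)
    cg <- compare_groups(with_puncta = w, without = no, blank = bl)
    p_wb <- cg$tests$p.value[cg$tests$group1 == "with_puncta" &
                               cg$tests$group2 == "blank"]
    p_nb <- cg$tests$p.value[cg$tests$group1 == "without" &
                               cg$tests$group2 == "blank"]
    c(p_wb < 0.05, p_nb < 0.05)
  })
  # analytic Welch power for the with-vs-blank contrast
  se_d <- sqrt(sd_w^2 / 53 + sd_b^2 / 48)
  power <- pnorm(abs(-0.2) / se_d - qnorm(0.975))
  expect_equal(mean(sig[1, ]), power, tolerance = 0.2)
  expect_gt(mean(sig[1, ]), 5 * mean(sig[2, ]) - 0.05)
  # the null contrast rejects at ~ the nominal rate
  expect_lte(mean(sig[2, ]), 0.15)
})

test_that("display smoothing is centered, impulse-preserving, and never feeds analysis", {
  tr <- simulate_current_trace(noise_sd = 0, i_photo_step = 0,
                               drift_slope = 0)
  const <- tr
  const$current_nA <- rep(2.5, nrow(const))
  expect_equal(smooth_for_display(const)$current_nA,
               rep(2.5, nrow(const)))
  imp <- const
  imp$current_nA <- rep(0, nrow(imp))
  imp$current_nA[100] <- 1
  sm <- smooth_for_display(imp, window = 20)
  expect_equal(max(sm$current_nA), 1 / 20)
  expect_identical(sum(abs(sm$current_nA) > 1e-12), 20L)
  expect_error(smooth_for_display(const[1:5, ], window = 20), "window")
  # regression guard: analysis reads the raw samples, so smoothing first
  # gives a measurably different answer on noisy data
  trs <- simulate_current_trace(noise_sd = 0.05, i_photo_step = -0.4,
                                seed = 63)
  raw_iph <- extract_photocurrent(trs)$cycles$i_ph_nA
  sm_iph <- extract_photocurrent(smooth_for_display(trs))$cycles$i_ph_nA
  expect_false(isTRUE(all.equal(sm_iph, raw_iph, tolerance = 1e-12)))
})
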