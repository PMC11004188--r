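test_that("closed-form variances evaluate correctly", {
  expect_equal(closed_form_variance(process_spec("wiener", diffusion_sd = 2), 3), 12)
  ou <- process_spec("ornstein_uhlenbeck", diffusion_sd = sqrt(2), reversion_rate = 1)
  expect_equal(closed_form_variance(ou, 1e9), 1)
  ou2 <- process_spec("ornstein_uhlenbeck", diffusion_sd = 1, reversion_rate = 0.5)
  expect_equal(closed_form_variance(ou2, 1), (1 - exp(-1)), tolerance = 1e-12)
  expect_error(closed_form_variance(process_spec("integrated_noise"), 1), "wiener")
})

test_that("Wiener ensembles track the closed form within chi-square envelopes", {
  n <- 400
  sp <- process_spec("wiener", diffusion_sd = 1.5, duration = 20, dt = 0.01,
                     n_trials = n, seed = 31)
  vc <- ensemble_variance(generate_process(sp))
  sel <- vc$time >= 2
  expected <- closed_form_variance(sp, vc$time[sel])
  # sample variance of N normals: (N-1) s^2 / sigma^2 ~ chi^2(N-1); 99% envelope
  lo <- stats::qchisq(0.005, n - 1) / (n - 1)
  hi <- stats::qchisq(0.995, n - 1) / (n - 1)
  ratio <- vc$variance[sel] / expected
  # pointwise band violated only rarely (samples are correlated across time)
  expect_lt(mean(ratio < lo | ratio > hi), 0.05)
})

test_that("OU ensembles reach the stationary variance sigma^2/(2 theta)", {
  sp <- process_spec("ornstein_uhlenbeck", diffusion_sd = sqrt(2),
                     reversion_rate = 1, duration = 12, dt = 0.01,
                     n_trials = 500, seed = 32)
  vc <- ensemble_variance(generate_process(sp))
  late <- vc$time >= 8   # >> 1/theta
  expect_equal(mean(vc$variance[late]), 1.0, tolerance = 0.15)
})

test_that("integration order n gives a -20n dB/dec spectral slope", {
  sp <- process_spec("integrated_noise", integration_order = 2L,
                     duration = 400, dt = 0.01, n_trials = 60, seed = 33)
  e <- generate_process(sp)
  fit <- psd_pipeline(e, c(0.01, 1), "remove_mean")$slope
  expect_equal(fit$slope_db_per_decade, -40, tolerance = 2)
})

test_that("bounded walks plateau while free walks do not", {
  bw <- process_spec("bounded_walk", diffusion_sd = 1, bound_threshold = 2,
                     duration = 40, dt = 0.02, n_trials = 60, seed = 34)
  bp <- detect_breakpoint(ensemble_variance(generate_process(bw)))
  expect_true(bp$plateau)
  w <- process_spec("wiener", duration = 40, dt = 0.02, n_trials = 60, seed = 35)
  expect_false(detect_breakpoint(ensemble_variance(generate_process(w)))$plateau)
})

test_that("a detrended ramp-plus-Wiener ensemble is spectrally Brownian", {
  dur <- 100
  rp <- process_spec("ramp_plus_wiener", diffusion_sd = 1, ramp_velocity = 0.5,
                     duration = dur, dt = 0.01, n_trials = 100, seed = 36)
  w <- process_spec("wiener", diffusion_sd = 1,
                    duration = dur, dt = 0.01, n_trials = 100, seed = 36)
  band <- c(4 / dur, 5)
  s_ramp <- psd_pipeline(generate_process(rp), band,
                         "remove_ensemble_mean_trajectory")$slope
  s_wien <- psd_pipeline(generate_process(w), band,
                         "remove_ensemble_mean_trajectory")$slope
  expect_equal(s_ramp$slope_db_per_decade, s_wien$slope_db_per_decade,
               tolerance = 1)
})

test_that("OU spectra show the Lorentzian limits (flat below, -20 above the corner)", {
  theta <- 2 * pi          # corner at 1 Hz
  sp <- process_spec("ornstein_uhlenbeck", diffusion_sd = 1,
                     reversion_rate = theta, duration = 200, dt = 0.01,
                     n_trials = 100, seed = 37)
  est <- average_psd(trial_psd(generate_process(sp), "remove_mean"))
  low <- fit_psd_slope(est, c(0.02, 0.1))    # well below the corner
  high <- fit_psd_slope(est, c(5, 40))       # well above the corner
  expect_gt(low$slope_db_per_decade, -5)
  expect_equal(high$slope_db_per_decade, -20, tolerance = 3)
})

test_that("process specs validate their fields", {
  expect_error(process_spec("ornstein_uhlenbeck"), "theta")
  expect_error(process_spec("integrated_noise", integration_order = 4), "order")
  expect_error(process_spec("bounded_walk"), "bound_threshold")
  expect_error(process_spec("wiener", diffusion_sd = 0), "diffusion_sd")
  expect_error(process_spec("ramp_plus_wiener"), "ramp_velocity")
})
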