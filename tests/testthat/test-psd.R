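test_that("a sinusoid concentrates its power at its own frequency bin", {
  fs <- 200
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 1 * t)
  e <- make_ensemble(t, matrix(x, 1))
  p <- trial_psd(e, "remove_mean")
  expect_equal(p$frequency[which.max(p$power[1, ])], 1.0)
})

test_that("a constant signal has no power after mean removal", {
  t <- seq(0, 5, by = 0.01)
  e <- make_ensemble(t, matrix(3.7, 2, length(t)))
  p <- trial_psd(e, "remove_mean")
  expect_lt(max(p$power), 1e-20)
})

test_that("white noise has a flat averaged log-log spectrum", {
  set.seed(5)
  fs <- 100
  n <- 2048
  t <- (0:(n - 1)) / fs
  e <- make_ensemble(t, matrix(rnorm(100 * n), 100, n))
  est <- average_psd(trial_psd(e, "remove_mean"))
  # two decades ending at Nyquist-ish
  fit <- fit_psd_slope(est, c(0.4, 40))
  expect_lt(abs(fit$slope_db_per_decade), 2)
})

test_that("the periodogram satisfies Parseval and matches spec.pgram", {
  set.seed(6)
  fs <- 50
  n <- 1000
  x <- cumsum(rnorm(n, 0, 0.3))
  e <- make_ensemble((0:(n - 1)) / fs, matrix(x, 1))
  p <- trial_psd(e, "remove_mean")
  df <- p$frequency[2] - p$frequency[1]
  xc <- x - mean(x)
  expect_equal(sum(p$power[1, ]) * df, mean(xc^2), tolerance = 0.2)

  # independent oracle: R's raw periodogram (different scaling convention:
  # spec.pgram normalizes by the sampling frequency differently)
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), taper = 0,
                          detrend = FALSE, demean = TRUE, fast = FALSE,
                          plot = FALSE)
  # spec.pgram is two-sided per unit frequency; ours is one-sided (x2),
  # except at the Nyquist bin, which one-sided scaling does not double
  interior <- seq_len(length(sp$freq) - 1)
  expect_equal(p$power[1, interior], 2 * sp$spec[interior], tolerance = 1e-8,
               ignore_attr = TRUE)
  nyq <- length(sp$freq)
  expect_equal(p$power[1, nyq], sp$spec[nyq], tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("averaging across trials is the arithmetic mean with 3 bins dropped", {
  f <- (1:100) / 100
  P <- matrix(rep(2^(1:100 %% 5 + 1), 2), 2, byrow = TRUE)
  est <- average_psd(list(frequency = f, power = rbind(P[1, ], 3 * P[1, ])))
  expect_equal(est$power, 2 * P[1, -(1:3)])
  expect_equal(est$frequency, f[-(1:3)])
  expect_identical(est$dropped_low_bins, 3)

  same <- average_psd(list(frequency = f, power = rbind(P[1, ], P[1, ])))
  expect_equal(same$power, P[1, -(1:3)])
})

test_that("slope fitting is exact on pure power laws", {
  f <- seq(0.01, 10, length.out = 500)
  for (alpha in 0:4) {
    fit <- fit_psd_slope(list(frequency = f, power = f^(-alpha)), c(0.01, 10))
    expect_equal(fit$slope_db_per_decade, -10 * alpha, tolerance = 1e-9)
    if (alpha > 0) expect_equal(fit$r_squared, 1, tolerance = 1e-12)
    expect_lte(fit$ci95[1], fit$slope_db_per_decade)
    expect_gte(fit$ci95[2], fit$slope_db_per_decade)
  }
  expect_error(fit_psd_slope(list(frequency = f, power = f^-2), c(20, 30)),
               "3 retained bins")
})

test_that("degenerate PSD inputs are rejected", {
  t <- seq(0, 5, by = 0.01)
  bad <- make_ensemble(t, matrix(c(NA, rnorm(length(t) - 1)), 1))
  expect_error(trial_psd(bad, "remove_mean"), "NaN/NA")
  short <- make_ensemble(seq(0, 0.3, by = 0.01), matrix(rnorm(31), 1))
  expect_error(trial_psd(short, "remove_mean"), "64 samples")
})
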