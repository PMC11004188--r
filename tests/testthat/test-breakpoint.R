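test_that("breakpoint detection recovers an exact piecewise curve", {
  t <- seq(0, 120, by = 0.5)
  k <- 0.03
  curve <- structure(list(time = t, variance = k * pmin(t, 60), n_trials = 50),
                     class = "variance_curve")
  # with every sample a candidate, the exact break time is recovered
  bp <- detect_breakpoint(curve, n_grid = length(t))
  expect_true(bp$plateau)
  expect_equal(bp$t_bp, 60, tolerance = 1e-9)
  expect_equal(bp$pre_slope, k, tolerance = 1e-9)
  expect_equal(bp$post_level, k * 60, tolerance = 1e-9)
  # the default coarser candidate grid lands within one grid step
  coarse <- detect_breakpoint(curve)
  grid_step <- diff(range(t)) / 200
  expect_lt(abs(coarse$t_bp - 60), grid_step + 0.5)
})

test_that("a pure ramp yields the no-plateau flag", {
  t <- seq(0, 100, by = 0.5)
  curve <- structure(list(time = t, variance = 0.02 * t, n_trials = 50),
                     class = "variance_curve")
  bp <- detect_breakpoint(curve)
  expect_false(bp$plateau)
  expect_equal(bp$t_bp, 100)
})

test_that("breakpoints are never earlier than the 5% variance guard", {
  set.seed(4)
  t <- seq(0, 100, by = 0.1)
  for (Tb in c(30, 60)) {
    v <- 0.05 * pmin(t, Tb) + rnorm(length(t), 0, 0.02)
    v <- pmax(v, 0)
    curve <- structure(list(time = t, variance = v, n_trials = 100),
                       class = "variance_curve")
    bp <- detect_breakpoint(curve)
    final_level <- mean(v[t >= 95])
    t_guard <- t[which(v > 0.05 * final_level)[1]]
    expect_gte(bp$t_bp, t_guard)
    expect_equal(bp$t_bp, Tb, tolerance = 0.25)
  }
})

test_that("bounded walks plateau at the saturation time of a larger oracle ensemble", {
  sp <- function(n, seed) process_spec("bounded_walk", diffusion_sd = 1,
                                       bound_threshold = 3, duration = 60,
                                       dt = 0.02, n_trials = n, seed = seed)
  bp <- detect_breakpoint(ensemble_variance(generate_process(sp(80, 21))))
  expect_true(bp$plateau)
  # oracle: effective saturation time measured on a 10x-larger ensemble as
  # the first time its variance reaches 90% of the plateau level (where the
  # linear ramp meets the plateau, the quantity the two-segment fit estimates)
  vc_big <- ensemble_variance(generate_process(sp(800, 22)))
  plateau_level <- mean(vc_big$variance[vc_big$time >= 45])
  t_sat <- vc_big$time[which(vc_big$variance >= 0.9 * plateau_level)[1]]
  expect_equal(bp$t_bp, t_sat, tolerance = 0.25)

  # a free Wiener ensemble of the same geometry has no plateau
  wf <- process_spec("wiener", duration = 60, dt = 0.02, n_trials = 80, seed = 23)
  expect_false(detect_breakpoint(ensemble_variance(generate_process(wf)))$plateau)
})
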