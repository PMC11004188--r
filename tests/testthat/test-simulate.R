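test_that("noiseless crank tracking reaches the ramp within its steady-state lag", {
  v_ref <- 0.075 * 2 * pi
  tr <- simulate_trial(arm_plant(), controller_spec("model_iii", k_c = arm_gain()),
                       task_spec("crank", duration = 26), 1)
  expect_equal(tail(tr$position, 1), v_ref * 26, tolerance = 0.05)
  # type-1 loop with delayed feedback: the loop regulates x(t - tau) to lag
  # x_ref by v*beta/k_c, so the position itself lags by v*(beta/k_c - tau)
  lag <- v_ref * 26 - tail(tr$position, 1)
  expect_equal(lag, v_ref * (30 / 65 - 0.1), tolerance = 0.02)
})

test_that("noiseless postural simulations stay at the origin for all architectures", {
  task <- task_spec("hand_posture", duration = 3)
  # model ii's velocity loop adds a fast pole, so it gets a finer step
  task_fine <- task_spec("hand_posture", duration = 3, dt = 1e-4)
  cases <- list(
    list(ctl = controller_spec("model_iii", k_c = arm_gain()), task = task),
    list(ctl = controller_spec("model_i", k_c = arm_gain(),
                               leak_time_constant = 20), task = task),
    list(ctl = controller_spec("model_ii", k_c = 0,
                               velocity_gain = 20), task = task_fine)
  )
  for (case in cases) {
    tr <- simulate_trial(arm_plant(), case$ctl, case$task, 7)
    expect_lt(max(abs(tr$position)), 1e-9)
  }
})

test_that("halving dt leaves a fixed-seed noiseless trajectory essentially unchanged", {
  run <- function(dt) {
    tr <- simulate_trial(arm_plant(), controller_spec("model_iii", k_c = arm_gain()),
                         task_spec("crank", duration = 10, dt = dt), 1)
    tail(tr$position, 1)
  }
  x1 <- run(5e-4)
  x2 <- run(2.5e-4)
  expect_lt(abs(x2 - x1) / abs(x1), 1e-3)
})

test_that("the simulator refuses unstable or under-resolved configurations", {
  # inverted pendulum with too little stiffness: unstable closed loop
  expect_error(
    simulate_trial(stance_plant(), controller_spec("model_iii", k_c = 700),
                   task_spec("quiet_standing", duration = 1), 1),
    "mgL")
  # dt too coarse for the fast arm pole
  expect_error(
    simulate_trial(arm_plant(), controller_spec("model_iii", k_c = arm_gain()),
                   task_spec("crank", duration = 1, dt = 2e-3,
                             output_rate = 100), 1),
    "coarse")
  expect_error(
    simulate_trial(arm_plant(),
                   controller_spec("model_iii", k_c = arm_gain(),
                                   intermittent = intermittent_spec(0.1)),
                   task_spec("crank", duration = 1), 1),
    "intermittent")
})

test_that("ensembles are deterministic per seed and aligned at the origin", {
  cond <- crank_condition(n_trials = 3, seed = 42, duration = 5)
  e1 <- simulate_ensemble(cond$plant, cond$controller, cond$task)
  e2 <- simulate_ensemble(cond$plant, cond$controller, cond$task)
  expect_identical(e1$positions, e2$positions)
  expect_true(all(e1$positions[, 1] == 0))
  # different trials get independent noise
  expect_gt(max(abs(e1$positions[1, ] - e1$positions[2, ])), 0)
  expect_error(
    simulate_ensemble(cond$plant, cond$controller,
                      task_spec("crank", duration = 5, n_trials = 1)),
    "n_trials")
})

test_that("free-integrator loop (model ii) shows the steady-state velocity error", {
  # closed-form oracle: proportional velocity loop has DC gain k_v/(k_v + beta)
  arm <- arm_plant()
  kv <- 20
  dc <- kv / (kv + arm$damping)
  ctl <- controller_spec("model_ii", k_c = 0, velocity_gain = kv,
                         noise_force_sd = 0.1)
  task <- task_spec("crank", duration = 26, dt = 1e-4, n_trials = 20, seed = 3)
  ens <- simulate_ensemble(arm, ctl, task)
  mean_traj <- colMeans(ens$positions)
  sel <- ens$time >= 13
  fitted_v <- unname(coef(lm(mean_traj[sel] ~ ens$time[sel]))[2])
  expect_equal(fitted_v / task$reference_velocity, dc, tolerance = 0.05)
  # hence a tracked velocity clearly below the reference
  expect_gt(abs(fitted_v - task$reference_velocity) / task$reference_velocity, 0.05)
})

test_that("leaky-integrator disturbance (model i) saturates position variance", {
  ctl <- controller_spec("model_i", k_c = arm_gain(), leak_time_constant = 20,
                         noise_force_sd = 0.25)
  task <- task_spec("crank", duration = 26, n_trials = 60, seed = 11)
  ens <- simulate_ensemble(arm_plant(), ctl, task)
  vc <- ensemble_variance(ens)
  # initial-slope extrapolation: fit over the first 5 s, extrapolate to 26 s
  early <- fit_variance_growth(vc, c(0.2, 5))
  v26 <- vc$variance[length(vc$variance)]
  extrapolated <- early$intercept + early$slope * 26
  expect_lt(v26 / extrapolated, 0.8)
})
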