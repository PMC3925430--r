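make_constant_temps <- function(value, start = 700L, n_bins = 500L) {
  data.frame(bin_start = seq(start, by = 50L, length.out = n_bins),
             temp = value)
}

test_that("a trajectory started at equilibrium under constant forcing stays there", {
  spec <- model_spec("ricker_lateral", 0L)
  p <- ricker_params(0.3, 0.7, -2.0, 1.5)
  temps <- make_constant_temps(-0.2)
  Xstar <- equilibrium(p, -0.2)
  traj <- simulate_trajectory(spec, p, Xstar, temps, 800L, 10L)
  expect_close(traj$X_sim, rep(Xstar, 11), 1e-12)
  expect_close(traj$R_sim, rep(0, 10), 1e-12)
})

test_that("free-running iteration matches a two-step hand computation", {
  spec <- model_spec("ricker_lateral", 0L)
  p <- ricker_params(0.2, 0.5, -3.0, 0)
  temps <- make_constant_temps(0)
  traj <- simulate_trajectory(spec, p, 5, temps, 800L, 2L)
  X1 <- 5 + 0.2 - exp(0.5 * 5 - 3)        # 4.593466...
  X2 <- X1 + 0.2 - exp(0.5 * X1 - 3)
  expect_equal(traj$X_sim, c(5, X1, X2))
  expect_equal(traj$R_sim, diff(traj$X_sim))
  expect_equal(X1, 4.5934693, tolerance = 1e-7)
})

test_that("a zero-noise synthetic series reproduces itself under its own parameters", {
  spec <- model_spec("ricker_lateral", c(0L, 1L))
  p <- ricker_params(0.2, 0.5, -3.0, c(1, 0.5))
  scn_t <- temperature_scenario(
    data.frame(start = 750, end = 1800, from = 0.1, to = -0.5), seed = 6L)
  scn_p <- population_scenario(spec, p, X0 = 2.8, noise_sd = 0,
                               window = c(800L, 1650L), seed = 12L)
  annual <- gen_temperature(scn_t)
  out <- gen_population(scn_p, annual)
  traj <- simulate_trajectory(spec, p, 2.8, out$temps, 800L, 17L)
  expect_close(traj$X_sim, out$pop$X, 1e-12)
  expect_close(traj$R_sim, out$true_R$R, 1e-12)
})

test_that("simulation is deterministic and flags temperature coverage gaps", {
  spec <- model_spec("ricker_lateral", c(0L, 1L))
  p <- ricker_params(0.2, 0.5, -3.0, c(1, 0.5))
  temps <- make_constant_temps(0.1)
  t1 <- simulate_trajectory(spec, p, 3, temps, 800L, 5L)
  t2 <- simulate_trajectory(spec, p, 3, temps, 800L, 5L)
  expect_identical(t1, t2)
  short <- temps[temps$bin_start >= 800, ]  # lag bin for 800 missing
  expect_error(simulate_trajectory(spec, p, 3, short, 800L, 5L),
               class = "popclim_coverage_error")
})

test_that("trajectories converge to equilibrium inside the Ricker stability window", {
  spec <- model_spec("ricker_lateral", 0L)
  set.seed(17)
  for (i in 1:15) {
    R_m <- runif(1, 0.05, 1.5)
    a <- runif(1, 0.05, 1.9 / R_m)  # 0 < a * R_m < 1.9
    p <- ricker_params(R_m, a, rnorm(1), 0.8)
    temps <- make_constant_temps(0.1)
    Xstar <- equilibrium(p, 0.1)
    traj <- simulate_trajectory(spec, p, Xstar + 0.4, temps, 800L, 400L)
    expect_lt(abs(traj$X_sim[length(traj$X_sim)] - Xstar), 1e-4)
  }
})

test_that("prediction correlation is Pearson's r with guardrails", {
  expect_equal(prediction_correlation(c(0, 1, 2), c(0, 1, 2)), 1)
  x <- c(0.1, -0.4, 0.3, 0.2)
  expect_equal(prediction_correlation(x, -x), -1)
  expect_equal(prediction_correlation(c(0, 1, 2), c(0, 2, 1)), 0.5)
  expect_error(prediction_correlation(c(1, 1, 1), c(0, 1, 2)), "constant")
  expect_error(prediction_correlation(1:2, 1:2), "length")
})

test_that("one-step predictions are the NLS fitted values", {
  spec <- model_spec("ricker_lateral", c(0L, 1L))
  truth <- ricker_params(0.2, 0.5, -3.0, c(4, 2))
  frame <- make_frame(spec, truth, n = 17L, noise_sd = 0.05)
  fit <- fit_model(spec, frame, multistart = 8)
  rhat <- one_step_predictions(spec, fit$params, frame)
  expect_equal(sum((frame$R - rhat)^2), fit$rss, tolerance = 1e-10)

  # exponential one-step predictions at constant temperature are constant
  sp_e <- model_spec("exponential_additive", 0L)
  fr_const <- frame
  fr_const$temp_lag0 <- 0.2
  rhat_e <- one_step_predictions(sp_e, exponential_params(0.3, 0.1), fr_const)
  expect_equal(rhat_e, rep(0.32, nrow(frame)))

  # on noise-free data the one-step predictions equal the observations
  fr0 <- make_frame(spec, truth, n = 17L, noise_sd = 0)
  expect_close(one_step_predictions(spec, truth, fr0), fr0$R, 1e-12)
})

test_that("free-running predictions do not beat one-step predictions on average", {
  spec <- model_spec("ricker_lateral", c(0L, 1L))
  truth <- ricker_params(0.2, 0.5, -3.0, c(4, 2))
  diffs <- vapply(1:20, function(r) {
    frame <- make_frame(spec, truth, n = 40L, X0 = 2.5, noise_sd = 0.05,
                        seed = 300L + r, temp_seed = 400L + r)
    one <- prediction_correlation(frame$R,
                                  one_step_predictions(spec, truth, frame))
    free <- prediction_correlation(frame$R,
                                   popclim:::simulate_frame(spec, truth,
                                                            frame)$R_sim)
    one - free
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})
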