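test_that("temperature generator: exact mean path at zero noise, seeded, AR(1)", {
  scn0 <- temperature_scenario(
    data.frame(start = c(800, 1000), end = c(1000, 1200),
               from = c(0.2, 0.2), to = c(0.2, -0.4)),
    phi = 0.7, sd = 0, seed = 1L)
  ann <- gen_temperature(scn0)
  expect_equal(ann$year, 800:1200)
  expect_equal(ann$anomaly[ann$year <= 1000], rep(0.2, 201))
  expect_equal(ann$anomaly[ann$year == 1100], -0.1)
  expect_equal(ann$anomaly[ann$year == 1200], -0.4)

  scn <- temperature_scenario(
    data.frame(start = 0, end = 10000, from = 0, to = 0),
    phi = 0.7, sd = 0.15, seed = 42L)
  a1 <- gen_temperature(scn)
  a2 <- gen_temperature(scn)
  expect_identical(a1, a2)

  # sample lag-1 autocorrelation over 10,000 years approximates phi
  rho <- stats::acf(a1$anomaly, lag.max = 1, plot = FALSE)$acf[2]
  expect_lt(abs(rho - 0.7), 0.03)
  # marginal sd close to the scenario sd
  expect_lt(abs(sd(a1$anomaly) - 0.15), 0.02)
})

test_that("population generator is seeded and nests the deterministic skeleton", {
  spec <- model_spec("ricker_lateral", c(0L, 1L))
  p <- ricker_params(0.2, 0.5, -3.0, c(1, 0.5))
  scn_t <- temperature_scenario(
    data.frame(start = 750, end = 1700, from = 0.1, to = -0.4), seed = 2L)
  annual <- gen_temperature(scn_t)

  scn0 <- population_scenario(spec, p, X0 = 2.8, noise_sd = 0,
                              window = c(800L, 1650L), seed = 3L)
  out0 <- gen_population(scn0, annual)
  traj <- simulate_trajectory(spec, p, 2.8, out0$temps, 800L, 17L)
  expect_close(out0$pop$X, traj$X_sim, 1e-12)

  scn <- population_scenario(spec, p, X0 = 2.8, noise_sd = 0.05,
                             window = c(800L, 1650L), seed = 3L)
  o1 <- gen_population(scn, annual)
  o2 <- gen_population(scn, annual)
  expect_identical(o1$pop$X, o2$pop$X)
  expect_false(identical(o1$pop$X, out0$pop$X))
})

test_that("census resampling round-trips at zero noise and is seeded", {
  pop <- regular_population(800L, 50L, log(c(12, 14, 19, 22, 30)))
  census <- gen_census(pop, pop_years(pop), obs_noise_cv = 0)
  expect_equal(census$population, exp(pop$X))

  c1 <- gen_census(pop, pop_years(pop), obs_noise_cv = 0.1, seed = 9L)
  c2 <- gen_census(pop, pop_years(pop), obs_noise_cv = 0.1, seed = 9L)
  expect_identical(c1$population, c2$population)
  expect_error(gen_census(pop, c(800L, 825L)), "not on the population grid")
})

test_that("sparser census anchors bound interpolation error by local curvature", {
  spec <- model_spec("ricker_lateral", c(0L, 1L))
  p <- ricker_params(0.2, 0.5, -3.0, c(1, 0.5))
  scn_t <- temperature_scenario(
    data.frame(start = 750, end = 1700, from = 0.1, to = -0.4), seed = 4L)
  scn_p <- population_scenario(spec, p, X0 = 2.8, noise_sd = 0.04,
                               window = c(800L, 1650L), seed = 5L)
  out <- gen_population(scn_p, gen_temperature(scn_t))
  years <- pop_years(out$pop)
  anchors <- unique(c(years[seq(1, length(years), 2)], years[length(years)]))
  census <- gen_census(out$pop, anchors, obs_noise_cv = 0)
  back <- interpolate_log_linear(census, 800, 1650, 50)
  err <- abs(back$X - out$pop$X)
  # midpoint error of linear interpolation = half the second difference
  second_diff <- abs(diff(out$pop$X, differences = 2))
  expect_lte(max(err), max(second_diff) / 2 + 1e-12)
  expect_equal(err[match(anchors, years)], rep(0, length(anchors)))
})

test_that("temperature and population noise streams are seed-isolated", {
  scn <- preset("great_famine")
  annual <- gen_temperature(scn$temperature)
  out1 <- gen_population(scn$population, annual)
  scn2 <- scn
  scn2$population$seed <- 777L
  out2 <- gen_population(scn2$population, annual)
  # same temperature input, different population noise
  expect_identical(out1$temps, out2$temps)
  expect_false(identical(out1$pop$X, out2$pop$X))
  # changing the temperature seed does not touch the population stream:
  # the generated noise increments (X diffs minus true R) are unchanged
  scn3 <- scn
  scn3$temperature$seed <- 888L
  out3 <- gen_population(scn$population, gen_temperature(scn3$temperature))
  eps1 <- diff(out1$pop$X) - out1$true_R$R
  eps3 <- diff(out3$pop$X) - out3$true_R$R
  expect_equal(eps1, eps3)
})

test_that("presets are fully specified, deterministic and window-consistent", {
  expect_error(preset("nope"), "great_famine")
  p1 <- preset("great_famine")
  p2 <- preset("great_famine")
  expect_identical(p1, p2)

  annual <- gen_temperature(p1$temperature)
  out <- gen_population(p1$population, annual)
  frame <- build_model_frame(out$pop, out$temps, p1$population$window)
  expect_equal(nrow(frame), 17L)

  pn <- preset("null_exponential")
  expect_equal(pn$population$spec$family, "exponential_additive")
})

test_that("the warm-cold preset rises during the warm regime and declines after cooling", {
  scn <- preset("great_famine")
  mean_R <- vapply(1:50, function(r) {
    st <- scn$temperature; st$seed <- 1000L + r
    sp <- scn$population; sp$seed <- 2000L + r
    out <- gen_population(sp, gen_temperature(st))
    gr <- out$true_R
    warm <- gr$R[gr$interval_start < 1250]
    cold <- gr$R[gr$interval_start >= 1300]
    c(mean(warm), mean(cold))
  }, numeric(2))
  expect_gt(mean(mean_R[1, ]), 0)   # growth during the warm regime
  expect_lt(mean(mean_R[2, ]), 0)   # decline after the cooling onset
})
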