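# Shared fixtures, built in code.

# A small noise-free frame generated from known parameters of either family.
make_frame <- function(spec, params, n = 17L, X0 = 3.4, noise_sd = 0,
                       seed = 42L, temp_seed = 7L) {
  scn_t <- temperature_scenario(
    data.frame(start = 750L, end = 800L + 50L * n, from = 0.1, to = -0.4),
    phi = 0.6, sd = 0.12, seed = temp_seed)
  scn_p <- population_scenario(spec, params, X0 = X0, noise_sd = noise_sd,
                               window = c(800L, 800L + 50L * n), step = 50L,
                               seed = seed)
  annual <- gen_temperature(scn_t)
  out <- gen_population(scn_p, annual)
  build_model_frame(out$pop, out$temps, scn_p$window)
}

# Closed-form ordinary least squares via the normal equations (independent
# oracle for the exponential-family fit; deliberately avoids lm()).
ols_oracle <- function(y, Xmat) {
  A <- cbind(1, Xmat)
  solve(t(A) %*% A, t(A) %*% y)[, 1L]
}

expect_close <- function(x, y, tol = 1e-8) {
  expect_true(all(abs(x - y) <= tol),
              label = sprintf("max|diff| = %.3g <= %.3g", max(abs(x - y)), tol))
}
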