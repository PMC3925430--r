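test_that("gaussian log-likelihood follows its closed form", {
  # n = 1 with rss/n = 1/(2*pi) gives exactly -1/2
  expect_equal(gaussian_loglik(1 / (2 * pi), 1), -0.5)
  # doubling rss at fixed n lowers loglik by (n/2) log 2
  ll1 <- gaussian_loglik(0.37, 17)
  ll2 <- gaussian_loglik(0.74, 17)
  expect_equal(ll1 - ll2, (17 / 2) * log(2))
  # depends on residuals only through their sum of squares
  set.seed(4)
  res <- rnorm(17)
  expect_equal(gaussian_loglik(sum(res^2), 17),
               gaussian_loglik(sum(sample(res)^2), 17))
  expect_warning(gaussian_loglik(0, 5), "unbounded")
})

test_that("BIC reproduces published comparison rows from printed inputs", {
  # n = 17 growth intervals on the 800-1650 window; tolerance is the
  # printed rounding of the source table
  expect_equal(bic(20.70, 3, 17), -32.89, tolerance = 0.05 / 32.89)
  expect_equal(bic(36.17, 6, 17), -55.33, tolerance = 0.05 / 55.33)
  expect_equal(bic(0, 1, 1), 0)
  # strictly increasing in p at fixed loglik and n
  expect_true(all(diff(vapply(1:6, function(p) bic(2.5, p, 17), 0)) > 0))
})

test_that("delta BIC and Schwarz weights behave as a candidate-set summary", {
  eur <- c(-32.89, -31.81, -33.77, -39.83)
  expect_equal(delta_bic(eur), c(6.94, 8.02, 6.06, 0.00))
  expect_equal(delta_bic(eur + 100), delta_bic(eur))
  expect_equal(delta_bic(-3.2), 0)

  expect_equal(bic_weights(0), 1)
  expect_equal(bic_weights(c(0, 0)), c(0.5, 0.5))
  w <- bic_weights(c(6.94, 8.02, 6.06, 0))
  expect_equal(w, c(0.0284, 0.0165, 0.0441, 0.9110), tolerance = 2e-3)

  set.seed(8)
  for (i in 1:25) {
    w <- bic_weights(abs(rnorm(sample(2:8, 1), 0, 10)))
    expect_lt(abs(sum(w) - 1), 1e-12)
    expect_true(all(w >= 0))
  }
})

test_that("r-squared matches its definition on hand-checkable cases", {
  obs <- c(0, 1, 2)
  expect_equal(r_squared(obs, obs), 1)
  expect_equal(r_squared(obs, rep(mean(obs), 3)), 0)
  expect_equal(r_squared(obs, c(0, 1, 1)), 0.5)
  expect_error(r_squared(c(1, 1, 1), c(1, 2, 1)), "constant")
})

test_that("noise-free exponential data are recovered exactly", {
  spec <- model_spec("exponential_additive", c(0L, 1L))
  truth <- exponential_params(0.25, c(0.31, 0.12))
  frame <- make_frame(spec, truth, n = 17L, noise_sd = 0)
  fit <- fit_model(spec, frame)
  expect_close(c(fit$params$R_m, fit$params$b), c(0.25, 0.31, 0.12), 1e-8)
  expect_lt(fit$rss, 1e-16)
  expect_equal(fit$p, 4L)  # 3 mean coefficients + residual variance
})

test_that("noise-free ricker-lateral data are recovered to 1e-6", {
  spec <- model_spec("ricker_lateral", 0L)
  truth <- ricker_params(0.2, 0.5, -3.0, 4.0)
  frame <- make_frame(spec, truth, n = 30L, X0 = 2.5, noise_sd = 0)
  fit <- fit_model(spec, frame, multistart = 8, seed = 2)
  expect_close(c(fit$params$R_m, fit$params$a, fit$params$beta0,
                 fit$params$beta),
               c(0.2, 0.5, -3.0, 4.0), 1e-6)
  expect_lt(fit$rss, 1e-12)
  expect_true(fit$converged)
})

test_that("exponential fits equal the closed-form OLS oracle on random frames", {
  set.seed(14)
  spec <- model_spec("exponential_additive", c(0L, 1L))
  for (i in 1:10) {
    truth <- exponential_params(rnorm(1, 0.2, 0.1), rnorm(2, 0.3, 0.2))
    frame <- make_frame(spec, truth, n = 17L, noise_sd = 0.05,
                        seed = 100L + i, temp_seed = 200L + i)
    fit <- fit_model(spec, frame)
    oracle <- ols_oracle(frame$R, cbind(frame$temp_lag0, frame$temp_lag1))
    expect_close(c(fit$params$R_m, fit$params$b), oracle, 1e-10)
  }
})

test_that("fit_result satisfies the BIC identity and frame-size guard", {
  spec <- model_spec("ricker_lateral", c(0L, 1L))
  truth <- ricker_params(0.2, 0.5, -3.0, c(4, 2))
  frame <- make_frame(spec, truth, n = 17L, noise_sd = 0.05)
  fit <- fit_model(spec, frame, multistart = 8)
  expect_equal(fit$bic, -2 * fit$loglik + fit$p * log(fit$n))
  expect_equal(fit$sigma2_hat, fit$rss / fit$n)
  expect_lte(fit$r2, 1)
  expect_error(fit_model(spec, frame[1:6, ]), "identify")
})

test_that("fits are reproducible given the seed", {
  spec <- model_spec("ricker_lateral", c(0L, 1L))
  truth <- ricker_params(0.2, 0.5, -3.0, c(4, 2))
  frame <- make_frame(spec, truth, n = 17L, noise_sd = 0.08)
  f1 <- fit_model(spec, frame, multistart = 8, seed = 5)
  f2 <- fit_model(spec, frame, multistart = 8, seed = 5)
  expect_identical(unlist(f1$params), unlist(f2$params))
})

test_that("rank_models produces a normalized, sorted comparison table", {
  spec <- model_spec("ricker_lateral", c(0L, 1L))
  truth <- ricker_params(0.2, 0.5, -3.0, c(4, 2))
  frame <- make_frame(spec, truth, n = 17L, noise_sd = 0.05)

  single <- rank_models(frame, list(model_spec("exponential_additive", 0L)),
                        pred_r = FALSE)
  expect_equal(single$table$delta_bic, 0)
  expect_equal(single$table$weight, 1)
  expect_true(single$table$best)

  tbl <- rank_models(frame, multistart = 8, seed = 3)
  expect_equal(nrow(tbl$table), 4L)
  expect_equal(min(tbl$table$delta_bic), 0)
  expect_equal(sum(tbl$table$weight), 1, tolerance = 1e-12)
  expect_false(is.unsorted(tbl$table$bic))
  expect_equal(sum(tbl$table$best), 1L)
  expect_s3_class(best_fit(tbl), "fit_result")
})

test_that("a per-fit p override reproduces alternative parameter-count conventions", {
  spec <- model_spec("ricker_lateral", c(0L, 1L))
  truth <- ricker_params(0.2, 0.5, -3.0, c(4, 2))
  frame <- make_frame(spec, truth, n = 17L, noise_sd = 0.05)
  f_default <- fit_model(spec, frame, multistart = 8)
  f_five <- fit_model(spec, frame, multistart = 8, p = 5)
  expect_equal(f_default$p, 6L)
  expect_equal(f_five$p, 5L)
  expect_equal(f_default$bic - f_five$bic, log(17))
})
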