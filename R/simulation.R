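# Free-running trajectory simulation and prediction diagnostics.

#' Simulate a free-running population trajectory
#'
#' Iterates the deterministic skeleton `X_{i+1} = X_i + R(X_i, temps_i)`
#' forward from a single initial log population, using the supplied
#' temperature bins as exogenous forcing. No observed population data are
#' used after the initial value; this is the free-running prediction, as
#' opposed to one-step-ahead fitted values ([one_step_predictions()]).
#'
#' @param spec a [model_spec()].
#' @param params the matching parameter object.
#' @param X0 initial log population at `start_year`.
#' @param temps a [bin_temperature()] result covering bins
#'   `start_year, ..., start_year + (n_steps-1)*step` and, if the spec uses
#'   lag 1, the bin at `start_year - step`.
#' @param start_year calendar year of the initial value.
#' @param n_steps number of growth intervals to simulate.
#' @param step grid step in years (default 50).
#' @return A `simulated_trajectory`: `years` (length `n_steps + 1`),
#'   `X_sim` (log population path, `X_sim[1] == X0`) and `R_sim`
#'   (per-interval growth rates, `R_sim[i] = X_sim[i+1] - X_sim[i]`).
#' @export
simulate_trajectory <- function(spec, params, X0, temps, start_year,
                                n_steps, step = 50L) {
  check_number(X0, "X0")
  n_steps <- as.integer(n_steps)
  if (n_steps < 1L) stop_input("`n_steps` must be >= 1")
  step <- as.integer(step)
  starts <- start_year + step * (seq_len(n_steps) - 1L)
  need <- sort(unique(c(starts, if (1L %in% spec$lags) starts - step)))
  missing_bins <- setdiff(need, temps$bin_start)
  if (length(missing_bins)) {
    stop_coverage("temperature bins missing for interval start(s) ",
                  paste(missing_bins, collapse = ", "))
  }
  t0 <- temps$temp[match(starts, temps$bin_start)]
  t1 <- temps$temp[match(starts - step, temps$bin_start)]
  X <- numeric(n_steps + 1L)
  R <- numeric(n_steps)
  X[1L] <- X0
  for (i in seq_len(n_steps)) {
    tv <- c(if (0L %in% spec$lags) t0[i], if (1L %in% spec$lags) t1[i])
    R[i] <- if (spec$family == "exponential_additive") {
      eval_exponential(params, tv)
    } else {
      eval_ricker_lateral(params, X[i], tv)
    }
    X[i + 1L] <- X[i] + R[i]
  }
  structure(list(years = c(starts, starts[n_steps] + step),
                 X_sim = X, R_sim = R, step = step),
            class = "simulated_trajectory")
}

#' @export
print.simulated_trajectory <- function(x, ...) {
  cat(sprintf("Simulated trajectory: %d intervals, %d-%d AD, X from %.3f to %.3f\n",
              length(x$R_sim), x$years[1L], x$years[length(x$years)],
              x$X_sim[1L], x$X_sim[length(x$X_sim)]))
  invisible(x)
}

# Free-running simulation over the rows of a model frame (internal):
# uses the frame's own temperature columns, starting from its first X.
simulate_frame <- function(spec, params, frame, X0 = frame$X[1L]) {
  n <- nrow(frame)
  X <- numeric(n + 1L)
  R <- numeric(n)
  X[1L] <- X0
  cols <- c("temp_lag0", "temp_lag1")[spec$lags + 1L]
  tm <- as.matrix(frame[, cols, drop = FALSE])
  for (i in seq_len(n)) {
    R[i] <- if (spec$family == "exponential_additive") {
      eval_exponential(params, tm[i, ])
    } else {
      eval_ricker_lateral(params, X[i], tm[i, ])
    }
    X[i + 1L] <- X[i] + R[i]
  }
  list(X_sim = X, R_sim = R)
}

#' Pearson correlation between observed and predicted series
#'
#' The headline agreement statistic between an observed growth-rate series
#' and a model prediction (free-running or one-step).
#'
#' @param obs_R observed values.
#' @param sim_R predicted values, same length.
#' @return Pearson correlation in `[-1, 1]`.
#' @export
prediction_correlation <- function(obs_R, sim_R) {
  if (length(obs_R) != length(sim_R) || length(obs_R) < 3L) {
    stop_input("`obs_R` and `sim_R` must have equal length >= 3")
  }
  if (stats::sd(obs_R) == 0 || stats::sd(sim_R) == 0) {
    stop_input("correlation undefined for a constant series")
  }
  stats::cor(obs_R, sim_R)
}

#' One-step-ahead predicted growth rates
#'
#' Evaluates the R-function at each observed row of the frame (observed
#' log population and temperatures): the fitted values of the
#' least-squares objective, used for r-squared, as opposed to the
#' free-running simulation.
#'
#' @inheritParams simulate_trajectory
#' @param frame a [build_model_frame()] result.
#' @return Numeric vector of predicted growth rates, one per frame row.
#' @export
one_step_predictions <- function(spec, params, frame) {
  eval_on_frame(spec, params, frame)
}
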