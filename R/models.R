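# The two competing growth-rate (R-function) families and their analytic
# structure: density-independent exponential growth with additive climate
# effects, and the Ricker logistic with climate as a lateral perturbation
# of the carrying capacity.

#' Model specification
#'
#' Identifies a member of the two model families by family and temperature
#' lag set. `k_mean` is the number of mean-function coefficients:
#' `1 + n_lags` for the exponential family (intercept plus one slope per
#' lag), `3 + n_lags` for the Ricker-lateral family (maximum growth rate,
#' density-dependence coefficient, exponent constant, one climate
#' coefficient per lag).
#'
#' @param family `"exponential_additive"` or `"ricker_lateral"`.
#' @param lags temperature lags used, in grid steps: `0` (contemporaneous
#'   bin only) or `c(0, 1)` (plus the previous bin).
#' @return A `model_spec` object.
#' @export
model_spec <- function(family = c("exponential_additive", "ricker_lateral"),
                       lags = 0L) {
  family <- match.arg(family)
  lags <- sort(unique(as.integer(lags)))
  if (!all(lags %in% c(0L, 1L)) || length(lags) < 1L) {
    stop_input("supported lag sets are {0} and {0, 1}")
  }
  k_mean <- if (family == "exponential_additive") 1L + length(lags)
            else 3L + length(lags)
  structure(list(family = family, lags = lags, k_mean = k_mean),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s, lags {%s}, %d mean parameters\n",
              x$family, paste(x$lags, collapse = ", "), x$k_mean))
  invisible(x)
}

#' Exponential-family parameters
#'
#' The density-independent model `R = R_m + sum_j b_j * Temp_lag_j`:
#' exponential growth at maximum rate `R_m` perturbed additively by
#' temperature anomalies.
#'
#' @param R_m maximum per-capita growth rate per grid step (dimensionless).
#' @param b climate coefficients, one per lag (per degree C).
#' @return An `exponential_params` object.
#' @export
exponential_params <- function(R_m, b) {
  check_number(R_m, "R_m")
  if (!is.numeric(b) || length(b) < 1L || any(!is.finite(b))) {
    stop_input("`b` must be a finite coefficient vector (one per lag)")
  }
  structure(list(R_m = as.numeric(R_m), b = as.numeric(b)),
            class = "exponential_params")
}

#' Ricker-lateral parameters
#'
#' The density-dependent model `R = R_m - exp(a*X + beta0 + sum_j
#' beta_j * Temp_lag_j)`. Temperature enters inside the exponent, so it
#' shifts the equilibrium (carrying capacity) laterally along the
#' log-population axis without changing the slope of the R-function at
#' equilibrium. `beta0` is the composite exponent constant (it absorbs the
#' log of the competition constant).
#'
#' @param R_m maximum per-capita growth rate per grid step.
#' @param a density-dependence coefficient (per log-population unit); may
#'   take either sign in fitted tables, but only `a != 0` admits an
#'   equilibrium and only `a > 0` a stable one.
#' @param beta0 exponent constant.
#' @param beta climate coefficients in the exponent (per degree C); may be
#'   a zero-length vector for the climate-free Ricker model.
#' @return A `ricker_params` object.
#' @export
ricker_params <- function(R_m, a, beta0, beta = numeric()) {
  check_number(R_m, "R_m"); check_number(a, "a"); check_number(beta0, "beta0")
  if (length(beta) && (!is.numeric(beta) || any(!is.finite(beta)))) {
    stop_input("`beta` must be finite")
  }
  structure(list(R_m = as.numeric(R_m), a = as.numeric(a),
                 beta0 = as.numeric(beta0), beta = as.numeric(beta)),
            class = "ricker_params")
}

temps_matrix <- function(temps, n_coef, n_obs) {
  if (n_coef == 0L) {
    if (length(temps)) stop_input("model takes no temperature terms")
    return(matrix(numeric(), nrow = n_obs, ncol = 0L))
  }
  if (is.null(dim(temps))) {
    if (length(temps) != n_coef) {
      stop_input("expected ", n_coef, " temperature value(s), got ",
                 length(temps))
    }
    matrix(rep(as.numeric(temps), each = n_obs), nrow = n_obs)
  } else {
    if (ncol(temps) != n_coef) {
      stop_input("expected ", n_coef, " temperature column(s), got ",
                 ncol(temps))
    }
    if (nrow(temps) != n_obs) stop_input("temperature rows must match X")
    as.matrix(temps)
  }
}

#' Evaluate the exponential-additive R-function
#'
#' @param params an [exponential_params()] set.
#' @param temps lag-ordered temperature anomalies: a vector with one value
#'   per coefficient, or a matrix with one row per observation.
#' @return Growth rate(s) `R = R_m + sum_j b_j * temps_j`; independent of
#'   population size.
#' @export
eval_exponential <- function(params, temps) {
  n_obs <- if (is.null(dim(temps))) 1L else nrow(temps)
  tm <- temps_matrix(temps, length(params$b), n_obs)
  as.numeric(params$R_m + tm %*% params$b)
}

#' Evaluate the Ricker-lateral R-function
#'
#' @param params a [ricker_params()] set.
#' @param X log population size(s) at the interval start.
#' @param temps lag-ordered temperature anomalies: a vector (recycled over
#'   `X`) or a matrix with `length(X)` rows.
#' @return Growth rate(s) `R = R_m - exp(a*X + beta0 + sum_j beta_j*temps_j)`.
#' @export
eval_ricker_lateral <- function(params, X, temps = numeric()) {
  X <- as.numeric(X)
  tm <- temps_matrix(temps, length(params$beta), length(X))
  expo <- params$a * X + params$beta0 +
    if (length(params$beta)) as.numeric(tm %*% params$beta) else 0
  params$R_m - exp(expo)
}

#' Equilibrium (carrying capacity) of the Ricker-lateral model
#'
#' Solves `R = 0` for log population at the given temperatures:
#' `X* = (ln(R_m) - beta0 - sum_j beta_j*temps_j) / a`. Temperature moves
#' `X*` linearly (the lateral shift) while the R-function slope at `X*`,
#' `-a * R_m`, does not depend on temperature.
#'
#' @inheritParams eval_ricker_lateral
#' @param temps lag-ordered temperature anomalies, one per coefficient.
#' @return Equilibrium log population `X*`.
#' @export
equilibrium <- function(params, temps = numeric()) {
  if (params$R_m <= 0) {
    stop_input("no equilibrium exists for R_m <= 0 (R is negative everywhere)")
  }
  if (params$a == 0) {
    stop_input("a = 0 is degenerate: the R-function does not cross zero in X")
  }
  shift <- if (length(params$beta)) sum(params$beta * temps) else 0
  (log(params$R_m) - params$beta0 - shift) / params$a
}

#' Evaluate an R-function over a grid of population sizes
#'
#' Diagnostic helper: applies the family evaluator elementwise over a log
#' population grid at fixed temperatures (flat in `X` for the exponential
#' family).
#'
#' @param spec a [model_spec()].
#' @param params the matching parameter object.
#' @param X_grid log population values.
#' @param temps lag-ordered temperature anomalies.
#' @return Numeric vector of growth rates, one per grid point.
#' @export
r_function_curve <- function(spec, params, X_grid, temps = numeric()) {
  X_grid <- as.numeric(X_grid)
  if (any(!is.finite(X_grid))) stop_input("X grid must be finite")
  if (spec$family == "exponential_additive") {
    rep(eval_exponential(params, temps), length(X_grid))
  } else {
    eval_ricker_lateral(params, X_grid, temps)
  }
}

# Dispatch an evaluator over model-frame columns (internal).
eval_on_frame <- function(spec, params, frame, X = frame$X) {
  tm <- frame_temps(spec, frame)
  if (spec$family == "exponential_additive") {
    eval_exponential(params, tm)
  } else {
    eval_ricker_lateral(params, X, tm)
  }
}

frame_temps <- function(spec, frame) {
  cols <- c("temp_lag0", "temp_lag1")[spec$lags + 1L]
  as.matrix(frame[, cols, drop = FALSE])
}
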