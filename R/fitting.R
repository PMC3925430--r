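# Nonlinear least-squares fitting of the R-function families and the
# BIC-ranked model-comparison table.

#' Gaussian log-likelihood of a least-squares fit
#'
#' Maximum log-likelihood of the Gaussian residual model with the
#' maximum-likelihood variance `sigma^2 = rss/n`:
#' `loglik = -(n/2) * (log(2*pi*rss/n) + 1)`. This is the convention under
#' which least-squares fits, their likelihoods and BIC are mutually
#' consistent.
#'
#' @param rss residual sum of squares (> 0).
#' @param n number of observations.
#' @return The log-likelihood. A zero `rss` means the Gaussian likelihood
#'   is unbounded; `+Inf` is returned with a warning rather than silently.
#' @export
gaussian_loglik <- function(rss, n) {
  check_number(n, "n")
  if (n < 1) stop_input("`n` must be >= 1")
  if (!is.numeric(rss) || length(rss) != 1L || rss < 0) {
    stop_input("`rss` must be a single non-negative number")
  }
  if (rss == 0) {
    warning("rss = 0: Gaussian likelihood is unbounded (perfect fit)")
    return(Inf)
  }
  -(n / 2) * (log(2 * pi * rss / n) + 1)
}

#' Bayesian information criterion
#'
#' `BIC = -2*loglik + p*log(n)` (Schwarz criterion). Lower is better.
#'
#' @param loglik model log-likelihood.
#' @param p number of estimated parameters (mean coefficients plus the
#'   residual variance, under the default convention of [fit_model()]).
#' @param n number of observations.
#' @return The BIC value.
#' @export
bic <- function(loglik, p, n) {
  check_number(loglik, "loglik"); check_number(p, "p"); check_number(n, "n")
  if (n < 1 || p < 1) stop_input("`n` and `p` must be >= 1")
  -2 * loglik + p * log(n)
}

#' BIC differences to the best model
#'
#' @param bics vector of BIC values for a candidate set.
#' @return `bics - min(bics)`; the best model gets 0.
#' @export
delta_bic <- function(bics) {
  if (!length(bics) || any(!is.finite(bics))) {
    stop_input("`bics` must be a non-empty finite vector")
  }
  bics - min(bics)
}

#' Schwarz (BIC) weights
#'
#' Normalized model probabilities `w_i = exp(-delta_i/2) / sum_j
#' exp(-delta_j/2)` over a candidate set.
#'
#' @param delta BIC differences as from [delta_bic()].
#' @return Weights summing to 1.
#' @export
bic_weights <- function(delta) {
  if (!length(delta) || any(!is.finite(delta))) {
    stop_input("`delta` must be a non-empty finite vector")
  }
  w <- exp(-delta / 2)
  w / sum(w)
}

#' Proportion of variance explained
#'
#' `r^2 = 1 - RSS/TSS` with the total sum of squares about the mean of the
#' observed growth rates.
#'
#' @param obs_R observed growth rates.
#' @param fitted_R model-predicted growth rates at the same rows.
#' @return The coefficient of determination (at most 1; can be negative
#'   for a model worse than the mean).
#' @export
r_squared <- function(obs_R, fitted_R) {
  if (length(obs_R) != length(fitted_R) || length(obs_R) < 2L) {
    stop_input("`obs_R` and `fitted_R` must have equal length >= 2")
  }
  tss <- sum((obs_R - mean(obs_R))^2)
  if (tss == 0) stop_input("observed growth rates are constant: r^2 undefined")
  1 - sum((obs_R - fitted_R)^2) / tss
}

# Log-linearized starting values for the Ricker-lateral family (internal).
# With a guess R_m0 above every observed R, log(R_m0 - R) is linear in X
# and the temperature columns.
ricker_start <- function(frame, tm, R_m0) {
  z <- log(R_m0 - frame$R)
  dat <- data.frame(z = z, X = frame$X)
  if (ncol(tm)) dat <- cbind(dat, as.data.frame(tm))
  cf <- stats::coef(stats::lm(z ~ ., data = dat))
  list(R_m = R_m0, a = unname(cf["X"]), beta0 = unname(cf["(Intercept)"]),
       beta = unname(cf[setdiff(names(cf), c("(Intercept)", "X"))]))
}

fit_exponential <- function(spec, frame) {
  tm <- frame_temps(spec, frame)
  dat <- data.frame(R = frame$R, as.data.frame(tm))
  fit <- stats::lm(R ~ ., data = dat)
  cf <- stats::coef(fit)
  params <- exponential_params(unname(cf[1L]), unname(cf[-1L]))
  list(params = params, fitted = unname(stats::fitted(fit)),
       rss = sum(stats::residuals(fit)^2), converged = TRUE, n_starts = 1L)
}

fit_ricker <- function(spec, frame, multistart, seed, tol) {
  tm <- frame_temps(spec, frame)
  n_beta <- ncol(tm)
  dat <- data.frame(R = frame$R, X = frame$X)
  rhs <- "Rm - exp(a * X + b0"
  start_names <- c("Rm", "a", "b0")
  for (j in seq_len(n_beta)) {
    col <- paste0("T", j)
    dat[[col]] <- tm[, j]
    rhs <- paste0(rhs, " + b", j, " * ", col)
    start_names <- c(start_names, paste0("b", j))
  }
  form <- stats::as.formula(paste("R ~", rhs, ")"))

  anchor <- ricker_start(frame, tm, max(frame$R) + max(0.1, 0.5 * stats::sd(frame$R)))
  anchor_vec <- c(anchor$R_m, anchor$a, anchor$beta0, anchor$beta)

  starts <- with_seed(seed, {
    lapply(seq_len(multistart), function(i) {
      if (i == 1L) return(anchor_vec)
      jitter_sd <- 0.3 * pmax(abs(anchor_vec), 0.2)
      s <- anchor_vec + stats::rnorm(length(anchor_vec), 0, jitter_sd)
      s[1L] <- max(frame$R) + abs(s[1L] - anchor_vec[1L]) + 0.01
      s
    })
  })

  best <- NULL
  n_ok <- 0L
  for (s in starts) {
    names(s) <- start_names
    fit <- tryCatch(
      minpack.lm::nlsLM(form, data = dat, start = as.list(s),
                        control = minpack.lm::nls.lm.control(
                          ftol = tol, ptol = 1e-10, maxiter = 500L)),
      error = function(e) NULL)
    if (is.null(fit)) next
    n_ok <- n_ok + 1L
    rss <- sum(stats::residuals(fit)^2)
    cand <- list(fit = fit, rss = rss, norm = sqrt(sum(stats::coef(fit)^2)))
    if (is.null(best) || rss < best$rss - 1e-14 ||
        (abs(rss - best$rss) <= 1e-14 && cand$norm < best$norm)) {
      best <- cand
    }
  }
  if (is.null(best)) {
    stop_convergence("no Ricker-lateral start converged (", multistart,
                     " starts, n = ", nrow(frame), ")")
  }
  cf <- stats::coef(best$fit)
  params <- ricker_params(unname(cf["Rm"]), unname(cf["a"]), unname(cf["b0"]),
                          if (n_beta) unname(cf[paste0("b", seq_len(n_beta))])
                          else numeric())
  list(params = params, fitted = unname(stats::fitted(best$fit)),
       rss = best$rss, converged = TRUE, n_starts = n_ok)
}

#' Fit one model specification to a regression frame
#'
#' Minimizes the residual sum of squares of observed vs model growth rates.
#' The exponential-additive family is linear in its coefficients and is
#' solved exactly by ordinary least squares. The Ricker-lateral family is
#' fitted by Levenberg-Marquardt nonlinear least squares from `multistart`
#' seeded starting points (a log-linearized anchor start plus jittered
#' copies); the converged start with the lowest residual sum of squares
#' wins, ties broken by the smaller coefficient norm.
#'
#' @param spec a [model_spec()].
#' @param frame a [build_model_frame()] result.
#' @param multistart number of starting points for the nonlinear family.
#' @param seed integer seed for the start jitter (reproducible fits).
#' @param tol convergence tolerance on relative rss improvement.
#' @param p parameter count used in the BIC; defaults to
#'   `k_mean + 1` (mean coefficients plus residual variance). Supply a
#'   value to replicate tables using another convention.
#' @return A `fit_result` with the fitted parameter object, `rss`,
#'   `sigma2_hat = rss/n`, Gaussian `loglik`, `n`, `p`, `bic`, `r2`,
#'   fitted values, convergence flag and the number of starts that
#'   converged.
#' @export
fit_model <- function(spec, frame, multistart = 32L, seed = 1L,
                      tol = 1e-10, p = NULL) {
  if (!inherits(spec, "model_spec")) stop_input("`spec` must be a model_spec")
  n <- nrow(frame)
  if (is.null(n) || n == 0L) stop_input("`frame` is empty")
  if (n <= spec$k_mean + 1L) {
    stop_input("n = ", n, " rows cannot identify ", spec$k_mean,
               " mean parameters plus a residual variance")
  }
  res <- if (spec$family == "exponential_additive") {
    fit_exponential(spec, frame)
  } else {
    fit_ricker(spec, frame, multistart, seed, tol)
  }
  p_used <- if (is.null(p)) spec$k_mean + 1L else as.integer(p)
  ll <- if (res$rss > 0) gaussian_loglik(res$rss, n) else {
    warning("perfect fit (rss = 0): likelihood unbounded"); Inf
  }
  structure(list(
    spec = spec, params = res$params, rss = res$rss,
    sigma2_hat = res$rss / n, loglik = ll, n = n, p = p_used,
    bic = if (is.finite(ll)) bic(ll, p_used, n) else -Inf,
    r2 = r_squared(frame$R, res$fitted), fitted = res$fitted,
    converged = res$converged, n_starts_used = res$n_starts
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s, lags {%s}\n", x$spec$family,
              paste(x$spec$lags, collapse = ", ")))
  pr <- unlist(x$params[names(x$params)])
  cat("  coefficients:",
      paste(sprintf("%s = %.4g", names(pr), pr), collapse = ", "), "\n")
  cat(sprintf("  n = %d, rss = %.4g, loglik = %.3f, BIC = %.3f (p = %d), r2 = %.3f\n",
              x$n, x$rss, x$loglik, x$bic, x$p, x$r2))
  invisible(x)
}

#' The four-model candidate set
#'
#' Both families with contemporaneous-only and contemporaneous-plus-lagged
#' temperature terms: the standard comparison set for one region.
#'
#' @return List of four [model_spec()] objects.
#' @export
default_model_set <- function() {
  list(model_spec("exponential_additive", 0L),
       model_spec("exponential_additive", c(0L, 1L)),
       model_spec("ricker_lateral", 0L),
       model_spec("ricker_lateral", c(0L, 1L)))
}

#' Fit and rank a candidate model set
#'
#' Fits every specification to the same frame, computes BIC differences
#' and Schwarz weights across the set, and flags the minimum-BIC model as
#' best. A specification whose fit fails is kept as a flagged row with
#' missing statistics rather than dropped.
#'
#' @inheritParams fit_model
#' @param specs list of [model_spec()] objects (default: the four-model
#'   set of [default_model_set()]).
#' @param region,window_label labels carried into the output table.
#' @param pred_r also compute, per model, the Pearson correlation between
#'   observed growth rates and a free-running simulation started from the
#'   frame's first log population (see [simulate_trajectory()]).
#' @return A `model_table`: the per-model statistics table (sorted by BIC)
#'   plus the underlying `fit_result` objects.
#' @export
rank_models <- function(frame, specs = default_model_set(),
                        multistart = 32L, seed = 1L, tol = 1e-10, p = NULL,
                        region = "", window_label = NULL, pred_r = TRUE) {
  if (!length(specs)) stop_input("`specs` must be non-empty")
  if (is.null(window_label)) {
    w <- attr(frame, "window")
    window_label <- if (is.null(w)) "" else paste0(w[1L], "-", w[2L])
  }
  fits <- vector("list", length(specs))
  rows <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    f <- tryCatch(
      fit_model(sp, frame, multistart = multistart, seed = seed + i - 1L,
                tol = tol, p = p),
      error = function(e) e)
    lag_lab <- paste(sp$lags, collapse = "+")
    if (inherits(f, "error")) {
      rows[[i]] <- data.frame(
        region = region, window = window_label, family = sp$family,
        lags = lag_lab, loglik = NA_real_, p = NA_integer_,
        n = nrow(frame), bic = NA_real_, r2 = NA_real_, pred_r = NA_real_,
        converged = FALSE)
      fits[[i]] <- f
    } else {
      pr <- NA_real_
      if (pred_r) {
        pr <- tryCatch({
          sim <- simulate_frame(sp, f$params, frame)
          prediction_correlation(frame$R, sim$R_sim)
        }, error = function(e) NA_real_)
      }
      rows[[i]] <- data.frame(
        region = region, window = window_label, family = sp$family,
        lags = lag_lab, loglik = f$loglik, p = f$p, n = f$n, bic = f$bic,
        r2 = f$r2, pred_r = pr, converged = f$converged)
      fits[[i]] <- f
    }
  }
  tab <- do.call(rbind, rows)
  ok <- is.finite(tab$bic)
  tab$delta_bic <- NA_real_
  tab$weight <- NA_real_
  if (any(ok)) {
    tab$delta_bic[ok] <- delta_bic(tab$bic[ok])
    tab$weight[ok] <- bic_weights(tab$delta_bic[ok])
  }
  tab$best <- ok & tab$bic == suppressWarnings(min(tab$bic[ok]))
  ord <- order(tab$bic, na.last = TRUE)
  tab <- tab[ord, c("region", "window", "family", "lags", "loglik", "p",
                    "n", "bic", "delta_bic", "weight", "r2", "pred_r",
                    "converged", "best")]
  rownames(tab) <- NULL
  structure(list(table = tab, fits = fits[ord], region = region,
                 window = window_label),
            class = "model_table")
}

#' @export
print.model_table <- function(x, digits = 3, ...) {
  cat(sprintf("Model comparison%s%s (n = %s)\n",
              if (nzchar(x$region)) paste0(" for ", x$region) else "",
              if (nzchar(x$window)) paste0(", window ", x$window) else "",
              x$table$n[1L]))
  print(format(x$table[, setdiff(names(x$table), c("region", "window"))],
               digits = digits), ...)
  invisible(x)
}

#' Best fit of a ranked model table
#' @param tbl a `model_table` from [rank_models()].
#' @return The minimum-BIC `fit_result`.
#' @export
best_fit <- function(tbl) {
  stopifnot(inherits(tbl, "model_table"))
  i <- which(tbl$table$best)[1L]
  if (is.na(i)) stop_convergence("no model in the table converged")
  tbl$fits[[i]]
}
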