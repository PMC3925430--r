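# File interchange (headed CSV throughout), parameter blocks, run
# configuration and the command-layer functions binding the pipeline
# stages together.

#' Read a census CSV
#'
#' Expects a header row and columns `year,population`, one row per census
#' anchor. Schema violations are reported with row numbers.
#'
#' @param path file path.
#' @return A [census_series()].
#' @export
read_population_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("year", "population") %in% names(d))) {
    stop_input("'", path, "': expected columns year,population")
  }
  bad <- which(!is.finite(d$year) | !is.finite(d$population) |
                 d$population <= 0)
  if (length(bad)) {
    stop_input("'", path, "': invalid year/population at data row(s) ",
               paste(bad, collapse = ", "))
  }
  census_series(d$year, d$population)
}

#' Read an annual temperature-anomaly CSV
#'
#' Expects a header row and columns `year,anomaly` (degrees C), one row
#' per consecutive calendar year.
#'
#' @param path file path.
#' @return An [annual_temperature()] series.
#' @export
read_temperature_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("year", "anomaly") %in% names(d))) {
    stop_input("'", path, "': expected columns year,anomaly")
  }
  bad <- which(!is.finite(d$year) | !is.finite(d$anomaly))
  if (length(bad)) {
    stop_input("'", path, "': invalid year/anomaly at data row(s) ",
               paste(bad, collapse = ", "))
  }
  annual_temperature(d$year, d$anomaly)
}

#' Write a model frame to CSV
#' @param frame a [build_model_frame()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model_frame_csv <- function(frame, path) {
  utils::write.csv(frame[, c("interval_start", "R", "X", "temp_lag0",
                             "temp_lag1")], path, row.names = FALSE)
  invisible(path)
}

#' Write a ranked model table to CSV
#'
#' Fixed column order
#' `region,window,family,lags,loglik,p,n,bic,delta_bic,weight,r2,pred_r,converged`
#' for diffing across runs.
#'
#' @param tbl a `model_table` from [rank_models()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model_table_csv <- function(tbl, path) {
  cols <- c("region", "window", "family", "lags", "loglik", "p", "n", "bic",
            "delta_bic", "weight", "r2", "pred_r", "converged")
  utils::write.csv(tbl$table[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Write a simulated trajectory to CSV
#'
#' Columns `interval_start,X_sim,R_sim`; the final row carries the end
#' state with an empty growth rate.
#'
#' @param traj a [simulate_trajectory()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(data.frame(interval_start = traj$years,
                              X_sim = traj$X_sim,
                              R_sim = c(traj$R_sim, NA)),
                   path, row.names = FALSE, na = "")
  invisible(path)
}

#' Serialize model parameters to a flat text block
#'
#' Writes `name=value` lines (family, lags, then coefficients) so a fitted
#' model can be re-simulated without refitting.
#'
#' @param spec a [model_spec()].
#' @param params the matching parameter object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_params <- function(spec, params, path) {
  lines <- c(paste0("family=", spec$family),
             paste0("lags=", paste(spec$lags, collapse = ",")))
  if (spec$family == "exponential_additive") {
    lines <- c(lines, paste0("R_m=", format(params$R_m, digits = 17)),
               paste0("b", seq_along(params$b) - 1L, "=",
                      vapply(params$b, format, "", digits = 17)))
  } else {
    lines <- c(lines, paste0("R_m=", format(params$R_m, digits = 17)),
               paste0("a=", format(params$a, digits = 17)),
               paste0("beta0=", format(params$beta0, digits = 17)),
               if (length(params$beta)) {
                 paste0("beta", seq_along(params$beta), "=",
                        vapply(params$beta, format, "", digits = 17))
               })
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a serialized parameter block
#'
#' @param path file written by [write_params()].
#' @return A list with `spec` and `params`.
#' @export
read_params <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, `[`, "", 2L)
  get1 <- function(k) {
    i <- match(k, keys)
    if (is.na(i)) stop_input("'", path, "': missing key '", k, "'")
    vals[i]
  }
  family <- get1("family")
  lags <- as.integer(strsplit(get1("lags"), ",", fixed = TRUE)[[1L]])
  spec <- model_spec(family, lags)
  if (family == "exponential_additive") {
    b <- as.numeric(vals[match(paste0("b", seq_along(lags) - 1L), keys)])
    params <- exponential_params(as.numeric(get1("R_m")), b)
  } else {
    beta <- as.numeric(vals[match(paste0("beta", seq_along(lags)), keys)])
    params <- ricker_params(as.numeric(get1("R_m")), as.numeric(get1("a")),
                            as.numeric(get1("beta0")), beta)
  }
  list(spec = spec, params = params)
}

#' Read a run configuration file
#'
#' A single YAML file holding the window, step, seed, multistart count,
#' tolerance, model set and input paths. Missing keys take the defaults
#' below; keys supplied as `...` override the file (documented precedence:
#' call arguments > file > defaults).
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param ... named overrides.
#' @return A named list: `window`, `step`, `seed`, `multistart`, `tol`,
#'   `region`, `population_csv`, `temperature_csv`, `lag_sets`.
#' @export
read_run_config <- function(path = NULL, ...) {
  defaults <- list(window = c(800L, 1650L), step = 50L, seed = 1L,
                   multistart = 32L, tol = 1e-10, region = "",
                   population_csv = NULL, temperature_csv = NULL,
                   lag_sets = list(0L, c(0L, 1L)))
  cfg <- defaults
  if (!is.null(path)) {
    file_cfg <- yaml::read_yaml(path)
    cfg[names(file_cfg)] <- file_cfg
  }
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  cfg$window <- as.integer(cfg$window)
  cfg$step <- as.integer(cfg$step)
  if ((cfg$window[2L] - cfg$window[1L]) %% cfg$step != 0L) {
    stop_input("config window span must be divisible by step")
  }
  cfg
}

#' Run the fit pipeline end to end
#'
#' Reads the census and temperature CSVs, builds the regression frame for
#' the configured window, fits and ranks the candidate model set, and
#' optionally writes the table CSV plus a structured run report
#' (seed, multistart count, tolerance, package version). Deterministic
#' given the config seed.
#'
#' @param config a list from [read_run_config()] (or a YAML path).
#' @param out_table optional path for the ranked-table CSV.
#' @param out_report optional path for the run report.
#' @return The `model_table`, invisibly.
#' @export
run_fit <- function(config, out_table = NULL, out_report = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  if (is.null(config$population_csv) || is.null(config$temperature_csv)) {
    stop_input("config must name population_csv and temperature_csv")
  }
  census <- read_population_csv(config$population_csv)
  annual <- read_temperature_csv(config$temperature_csv)
  pop <- interpolate_log_linear(census, config$window[1L], config$window[2L],
                                config$step)
  temps <- bin_temperature(annual, config$window[1L], config$window[2L],
                           config$step)
  frame <- build_model_frame(pop, temps, config$window)
  specs <- unlist(lapply(config$lag_sets, function(l) {
    list(model_spec("exponential_additive", l),
         model_spec("ricker_lateral", l))
  }), recursive = FALSE)
  tbl <- rank_models(frame, specs, multistart = config$multistart,
                     seed = config$seed, tol = config$tol,
                     region = config$region)
  if (!is.null(out_table)) write_model_table_csv(tbl, out_table)
  if (!is.null(out_report)) {
    writeLines(c(
      paste0("popclim_version=", as.character(utils::packageVersion("popclim"))),
      paste0("seed=", config$seed),
      paste0("multistart=", config$multistart),
      paste0("tol=", format(config$tol)),
      paste0("window=", config$window[1L], "-", config$window[2L]),
      paste0("step=", config$step),
      paste0("n_rows=", nrow(frame))), out_report)
  }
  invisible(tbl)
}

#' Run a free-running simulation from serialized parameters
#'
#' @param params_file a [write_params()] block.
#' @param temperature_csv annual temperature CSV forcing the simulation.
#' @param X0 initial log population.
#' @param start_year calendar year of `X0`.
#' @param n_steps number of growth intervals.
#' @param step grid step in years.
#' @param out optional trajectory CSV path.
#' @param obs_R optional observed growth-rate vector; when supplied the
#'   Pearson prediction correlation is computed and returned.
#' @return A list with the `trajectory` and (if `obs_R` given) `pred_r`.
#' @export
run_simulate <- function(params_file, temperature_csv, X0, start_year,
                         n_steps, step = 50L, out = NULL, obs_R = NULL) {
  pb <- read_params(params_file)
  annual <- read_temperature_csv(temperature_csv)
  temps <- bin_temperature(annual, start_year,
                           start_year + step * as.integer(n_steps), step)
  traj <- simulate_trajectory(pb$spec, pb$params, X0, temps, start_year,
                              n_steps, step)
  if (!is.null(out)) write_trajectory_csv(traj, out)
  res <- list(trajectory = traj)
  if (!is.null(obs_R)) {
    res$pred_r <- prediction_correlation(obs_R, traj$R_sim)
  }
  res
}

#' Generate and write a synthetic data set
#'
#' Runs a [preset()] scenario pair and writes `population.csv` (census
#' anchors at every grid point), `temperature.csv` and `truth.txt` (the
#' generating parameters and seeds) into a directory.
#'
#' @param name preset name.
#' @param dir output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
run_synth <- function(name, dir) {
  scn <- preset(name)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  annual <- gen_temperature(scn$temperature)
  out <- gen_population(scn$population, annual)
  census <- gen_census(out$pop, pop_years(out$pop), obs_noise_cv = 0)
  paths <- c(population = file.path(dir, "population.csv"),
             temperature = file.path(dir, "temperature.csv"),
             truth = file.path(dir, "truth.txt"))
  utils::write.csv(data.frame(year = census$year,
                              population = census$population),
                   paths[["population"]], row.names = FALSE)
  utils::write.csv(data.frame(year = annual$year, anomaly = annual$anomaly),
                   paths[["temperature"]], row.names = FALSE)
  write_params(scn$population$spec, scn$population$params, paths[["truth"]])
  cat(paste0("temperature_seed=", scn$temperature$seed, "\n",
             "population_seed=", scn$population$seed, "\n",
             "noise_sd=", scn$population$noise_sd, "\n",
             "X0=", format(scn$population$X0, digits = 17), "\n"),
      file = paths[["truth"]], append = TRUE)
  invisible(paths)
}
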