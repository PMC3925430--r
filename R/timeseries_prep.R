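# Preparation of the 50-year regression frame: census interpolation,
# growth-rate computation, temperature binning, frame assembly.

#' Irregular census series
#'
#' Constructs a census series from irregular (year, population) anchor
#' records, the raw demographic input of the pipeline. Historical sources
#' report population sizes at irregular times; all downstream analysis
#' happens on a regular grid built by [interpolate_log_linear()].
#'
#' @param year integer calendar years (AD), strictly increasing.
#' @param population population size at each anchor (same unit throughout,
#'   e.g. thousands or millions); must be strictly positive.
#' @return A `census_series` data frame with columns `year` and `population`.
#' @examples
#' census_series(c(800, 1000, 1300), c(29, 36, 79))
#' @export
census_series <- function(year, population) {
  if (length(year) != length(population)) {
    stop_input("`year` and `population` must have equal length")
  }
  if (length(year) < 2L) stop_input("a census series needs at least 2 records")
  year <- as.integer(year)
  if (anyNA(year) || any(diff(year) <= 0L)) {
    stop_input("census years must be strictly increasing integers")
  }
  if (!is.numeric(population) || any(!is.finite(population)) ||
      any(population <= 0)) {
    stop_input("census population values must be finite and > 0")
  }
  structure(data.frame(year = year, population = as.numeric(population)),
            class = c("census_series", "data.frame"))
}

#' Annual temperature-anomaly series
#'
#' A gap-free series of annual temperature anomalies (degrees C relative to
#' a reference period), one value per consecutive calendar year, as produced
#' by tree-ring reconstructions or by [gen_temperature()].
#'
#' @param year consecutive integer calendar years (AD).
#' @param anomaly finite anomaly values in degrees C.
#' @return An `annual_temperature` data frame with columns `year`, `anomaly`.
#' @export
annual_temperature <- function(year, anomaly) {
  if (length(year) != length(anomaly)) {
    stop_input("`year` and `anomaly` must have equal length")
  }
  year <- as.integer(year)
  if (length(year) == 0L || anyNA(year) || any(diff(year) != 1L)) {
    stop_input("temperature years must be consecutive (no gaps)")
  }
  if (!is.numeric(anomaly) || any(!is.finite(anomaly))) {
    stop_input("anomalies must be finite numbers")
  }
  structure(data.frame(year = year, anomaly = as.numeric(anomaly)),
            class = c("annual_temperature", "data.frame"))
}

#' Regular log-population series
#'
#' @param start_year first grid year (AD).
#' @param step grid step in years.
#' @param X natural-log population values, one per grid year.
#' @return A `regular_population` object.
#' @seealso [interpolate_log_linear()] which builds one from a census.
#' @export
regular_population <- function(start_year, step, X) {
  if (length(X) < 2L || any(!is.finite(X))) {
    stop_input("X must hold at least 2 finite log-population values")
  }
  structure(list(start_year = as.integer(start_year), step = as.integer(step),
                 X = as.numeric(X)),
            class = "regular_population")
}

#' Grid years of a regular population series
#' @param pop a `regular_population` object.
#' @return Integer vector of grid years.
#' @export
pop_years <- function(pop) {
  pop$start_year + pop$step * (seq_along(pop$X) - 1L)
}

#' @export
print.regular_population <- function(x, ...) {
  cat("Regular log-population series:", length(x$X), "grid points,",
      x$start_year, "-", max(pop_years(x)), "AD, step", x$step, "y\n")
  invisible(x)
}

#' Interpolate an irregular census onto a regular grid (log-linear)
#'
#' Population is interpolated linearly on the natural-log scale between
#' census anchors (equivalently: geometric interpolation of population),
#' and evaluated at the regular grid years. No extrapolation is performed:
#' the grid must lie within the census span.
#'
#' @param census a [census_series()].
#' @param grid_start,grid_end first and last grid year (AD).
#' @param step grid step in years (default 50).
#' @return A [regular_population()] holding log population `X` at each
#'   grid year. At a grid year coinciding with a census anchor,
#'   `exp(X)` equals the anchor population exactly.
#' @examples
#' cs <- census_series(c(800, 1000), c(1000, 4000))
#' pop <- interpolate_log_linear(cs, 800, 900, 50)
#' exp(pop$X)  # 1000, 2000 (geometric midpoint), 4000 at 1000 AD
#' @export
interpolate_log_linear <- function(census, grid_start, grid_end, step = 50L) {
  if (!inherits(census, "census_series")) {
    census <- census_series(census$year, census$population)
  }
  grid_start <- as.integer(grid_start); grid_end <- as.integer(grid_end)
  step <- as.integer(step)
  if (step <= 0L) stop_input("`step` must be a positive number of years")
  if (grid_end <= grid_start) stop_input("`grid_end` must exceed `grid_start`")
  if ((grid_end - grid_start) %% step != 0L) {
    stop_input("`step` must divide the grid span ", grid_start, "-", grid_end)
  }
  if (grid_start < census$year[1L] || grid_end > census$year[nrow(census)]) {
    stop_input("grid ", grid_start, "-", grid_end,
               " extends outside the census span ", census$year[1L], "-",
               census$year[nrow(census)], "; no extrapolation is performed")
  }
  grid <- seq.int(grid_start, grid_end, by = step)
  X <- stats::approx(census$year, log(census$population), xout = grid,
                     method = "linear", rule = 1L)$y
  regular_population(grid_start, step, X)
}

#' Per-capita growth rates on the regular grid
#'
#' The realized per-capita growth rate of the interval starting at grid
#' year t is `R_t = X_{t+step} - X_t = ln(N_{t+step}/N_t)`, attached to the
#' interval's start year. The rates telescope: their sum equals the total
#' log change over the series.
#'
#' @param pop a [regular_population()].
#' @return A `growth_rates` data frame with columns `interval_start`, `R`.
#' @export
compute_growth_rates <- function(pop) {
  if (!inherits(pop, "regular_population")) {
    stop_input("`pop` must be a regular_population")
  }
  years <- pop_years(pop)
  structure(data.frame(interval_start = years[-length(years)],
                       R = diff(pop$X)),
            class = c("growth_rates", "data.frame"))
}

#' Bin annual temperature anomalies into grid-step means
#'
#' Each bin labelled by its start year t holds the arithmetic mean anomaly
#' over calendar years t, ..., t+step-1 (half-open 50-year windows by
#' default). Bins are produced from `grid_start - step` (the lag bin of the
#' first growth interval) through `grid_end - step`.
#'
#' @param annual an [annual_temperature()] series; must cover every calendar
#'   year in `[grid_start - step, grid_end)`.
#' @inheritParams interpolate_log_linear
#' @return A `binned_temperature` data frame with columns `bin_start`, `temp`.
#' @export
bin_temperature <- function(annual, grid_start, grid_end, step = 50L) {
  if (!inherits(annual, "annual_temperature")) {
    annual <- annual_temperature(annual$year, annual$anomaly)
  }
  grid_start <- as.integer(grid_start); grid_end <- as.integer(grid_end)
  step <- as.integer(step)
  if (step <= 0L) stop_input("`step` must be positive")
  need_first <- grid_start - step
  need_last <- grid_end - 1L
  have <- range(annual$year)
  if (need_first < have[1L] || need_last > have[2L]) {
    miss_lo <- if (need_first < have[1L]) paste0(need_first, "-", have[1L] - 1L)
    miss_hi <- if (need_last > have[2L]) paste0(have[2L] + 1L, "-", need_last)
    stop_coverage("temperature series does not cover the span ",
                  need_first, "-", need_last, " (missing: ",
                  paste(c(miss_lo, miss_hi), collapse = ", "), ")")
  }
  bin_start <- seq.int(need_first, grid_end - step, by = step)
  temp <- vapply(bin_start, function(t) {
    mean(annual$anomaly[annual$year >= t & annual$year < t + step])
  }, numeric(1L))
  structure(data.frame(bin_start = bin_start, temp = temp),
            class = c("binned_temperature", "data.frame"))
}

#' Assemble the model regression frame
#'
#' Joins growth rates, log population at interval start, and the
#' contemporaneous and one-step-lagged temperature-bin means into one row
#' per growth interval within the analysis window. This is the frame the
#' model families are fitted to: a window 800-1650 at 50-year steps has 18
#' grid points and hence 17 rows.
#'
#' @param pop a [regular_population()].
#' @param temps a [bin_temperature()] result covering the window plus the
#'   bin one step before its start.
#' @param window length-2 integer vector `(start, end)` in calendar years;
#'   defaults to the population series span.
#' @return A `model_frame` data frame with columns `interval_start`, `R`,
#'   `X`, `temp_lag0`, `temp_lag1`; window and step stored as attributes.
#' @export
build_model_frame <- function(pop, temps, window = NULL) {
  if (!inherits(pop, "regular_population")) {
    stop_input("`pop` must be a regular_population")
  }
  step <- pop$step
  years <- pop_years(pop)
  if (is.null(window)) window <- c(years[1L], years[length(years)])
  window <- as.integer(window)
  if (window[2L] - window[1L] < step) {
    stop_input("window ", window[1L], "-", window[2L],
               " is shorter than one grid step (", step, " y)")
  }
  if (window[1L] < years[1L] || window[2L] > years[length(years)]) {
    stop_input("window outside the population series span")
  }
  starts <- seq.int(window[1L], window[2L] - step, by = step)
  gr <- compute_growth_rates(pop)
  t0 <- temps$temp[match(starts, temps$bin_start)]
  t1 <- temps$temp[match(starts - step, temps$bin_start)]
  if (anyNA(t0) || anyNA(t1)) {
    miss <- sort(unique(c(starts[is.na(t0)], (starts - step)[is.na(t1)])))
    stop_coverage("missing temperature bin(s) starting at ",
                  paste(miss, collapse = ", "))
  }
  X <- pop$X[match(starts, years)]
  R <- gr$R[match(starts, gr$interval_start)]
  if (anyNA(X) || anyNA(R)) {
    stop_input("population grid does not cover the window ",
               window[1L], "-", window[2L])
  }
  structure(data.frame(interval_start = starts, R = R, X = X,
                       temp_lag0 = t0, temp_lag1 = t1),
            window = window, step = step,
            class = c("model_frame", "data.frame"))
}
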