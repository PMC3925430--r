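# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("popclim_input_error", "error")))
}

stop_coverage <- function(...) {
  stop(errorCondition(paste0(...), class = c("popclim_coverage_error", "error")))
}

stop_convergence <- function(...) {
  stop(errorCondition(paste0(...), class = c("popclim_convergence_error", "error")))
}

check_number <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x))) {
    stop_input("`", name, "` must be a single finite number")
  }
  invisible(x)
}
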