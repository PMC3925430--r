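# Internal-consistency check of a published model-comparison table
# against the package's BIC machinery.

#' Printed model-comparison statistics for the 800-1650 window
#'
#' The published per-region comparison table (log-likelihood, parameter
#' count, BIC, delta BIC) for the four-model set on the 800-1650 window
#' (17 growth intervals), shipped as a plain-text fixture.
#'
#' @return Data frame with columns `region`, `row`, `family`, `lags`,
#'   `loglik`, `p`, `bic`, `delta_bic`.
#' @export
table1_printed <- function() {
  path <- system.file("extdata", "table1_printed.csv", package = "popclim",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Recompute a printed comparison table's BIC and delta-BIC columns
#'
#' For every printed row, recomputes `BIC = -2*loglik + p*log(n)` from the
#' printed log-likelihood and parameter count with `n = 17` observations,
#' and recomputes delta BIC within each region's candidate set from the
#' printed BIC column. Each recomputed value is compared with the printed
#' one at the given tolerance; at the default `tol = 0.05` discrepancies
#' reflect printed rounding only, while a much tighter tolerance flags
#' them — which is how the report distinguishes rounding from logic
#' errors.
#'
#' @param tol comparison tolerance (absolute).
#' @param n observation count behind the printed statistics.
#' @return A `table1_check` data frame: the fixture plus `bic_calc`,
#'   `bic_diff`, `bic_ok`, `delta_calc`, `delta_diff`, `delta_ok`; overall
#'   pass/fail in attribute `"pass"`.
#' @export
check_table1 <- function(tol = 0.05, n = 17L) {
  d <- table1_printed()
  d$bic_calc <- vapply(seq_len(nrow(d)),
                       function(i) bic(d$loglik[i], d$p[i], n), numeric(1L))
  d$bic_diff <- d$bic_calc - d$bic
  d$bic_ok <- abs(d$bic_diff) <= tol
  d$delta_calc <- stats::ave(d$bic, d$region, FUN = delta_bic)
  d$delta_diff <- d$delta_calc - d$delta_bic
  d$delta_ok <- abs(d$delta_diff) <= tol
  structure(d, pass = all(d$bic_ok & d$delta_ok), tol = tol,
            class = c("table1_check", "data.frame"))
}

#' @export
print.table1_check <- function(x, ...) {
  pass <- attr(x, "pass")
  cat(sprintf(
    "Printed-table consistency at tolerance %.3g: %s (max |BIC diff| %.4f, max |dBIC diff| %.4f)\n",
    attr(x, "tol"), if (pass) "PASS" else "FAIL",
    max(abs(x$bic_diff)), max(abs(x$delta_diff))))
  bad <- x[!(x$bic_ok & x$delta_ok), c("region", "row", "bic", "bic_calc",
                                       "delta_bic", "delta_calc")]
  if (nrow(bad)) {
    cat("Rows outside tolerance:\n")
    print(as.data.frame(bad), row.names = FALSE)
  }
  invisible(x)
}
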