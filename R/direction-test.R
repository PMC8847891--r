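# Common container for test results: statistic, p-value, null moments and
# provenance (Monte Carlo iterations and seed whenever randomness was used).
direction_test <- function(method, statistic, p_value, null_mean = NA_real_,
                           null_sd = NA_real_, n = NA_integer_,
                           k = NA_integer_, mc_iterations = NULL,
                           seed = NULL, notes = character(),
                           details = list()) {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(
    list(method = method, statistic = statistic, p_value = p_value,
         null_mean = null_mean, null_sd = null_sd,
         n = n, k = k, mc_iterations = mc_iterations, seed = seed,
         notes = notes, details = details),
    class = "direction_test")
}

#' Print a direction test result
#'
#' @param x a `direction_test` object.
#' @param ... ignored.
#' @return `x`, invisibly.
#' @export
print.direction_test <- function(x, ...) {
  cat("\n\t", x$method, "\n\n", sep = "")
  if (!is.null(x$details$theta_rad)) {
    cat(sprintf("angle = %.4g rad (%.4g°), r = %.4g\n",
                x$details$theta_rad, x$details$theta_deg, x$details$r))
  } else {
    cat(sprintf("statistic = %.6g\n", x$statistic))
  }
  if (is.finite(x$null_mean) || is.finite(x$null_sd))
    cat(sprintf("null mean = %.4g, null sd = %.4g\n", x$null_mean, x$null_sd))
  if (!is.na(x$n) || !is.na(x$k))
    cat(sprintf("n = %s, k = %s\n", x$n, x$k))
  if (!is.null(x$mc_iterations))
    cat(sprintf("Monte Carlo iterations = %d (seed %s)\n",
                x$mc_iterations, x$seed))
  cat(sprintf("p-value %s\n",
              if (x$p_value < 1e-10) "< 1e-10"
              else sprintf("= %.4g", x$p_value)))
  for (nt in x$notes) cat("note: ", nt, "\n", sep = "")
  invisible(x)
}
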