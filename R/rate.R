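#' Exact Poisson (Garwood) confidence interval for an event count
#'
#' Chi-square construction of the two-sided interval for the mean of a
#' Poisson count `k`:
#' lower `= qchisq(alpha/2, 2k)/2` (0 when `k = 0`),
#' upper `= qchisq(1 - alpha/2, 2k + 2)/2`.
#'
#' @param k observed event count (integer >= 0).
#' @param alpha two-sided error level (default 0.05 for a 95% interval).
#' @return numeric `c(lower, upper)` on the event-count scale.
#' @examples
#' poisson_exact_ci(3)  # (0.6187, 8.7673)
#' @export
poisson_exact_ci <- function(k, alpha = 0.05) {
  stopifnot(k >= 0, k == round(k), alpha > 0, alpha < 1)
  lower <- if (k == 0) 0 else stats::qchisq(alpha / 2, 2 * k) / 2
  upper <- stats::qchisq(1 - alpha / 2, 2 * k + 2) / 2
  c(lower = lower, upper = upper)
}

#' FNR-corrected mutation rate per site per generation
#'
#' The point estimate is
#' \deqn{\mu = \frac{m}{C} \times \frac{\mathrm{inserted}}{\mathrm{detected}}}
#' where `m` is the number of confirmed de novo mutations, `C` the total
#' callable sites (diploid-doubled), and inserted/detected are the
#' synthetic spike-in counts whose ratio corrects for false negatives.
#' The 95% interval treats the correction factor and `1/C` as constants
#' and applies the exact Poisson (Garwood) interval to `m`.
#'
#' @param m confirmed mutation count (integer >= 0).
#' @param callable total callable sites C (> 0).
#' @param inserted synthetic mutations inserted at callable sites.
#' @param detected synthetic mutations detected (> 0).
#' @param alpha two-sided error level (default 0.05).
#' @return object of class `rate_estimate`: `m`, `callable`, `inserted`,
#'   `detected`, `correction`, `fnr`, `mu`, `ci_low`, `ci_high`, `alpha`.
#' @examples
#' estimate_rate(3, 3.89e9, 9914, 7658)   # ~1.0e-9 (2.1e-10, 2.9e-9)
#' @export
estimate_rate <- function(m, callable, inserted, detected, alpha = 0.05) {
  stopifnot(m >= 0, m == round(m), callable > 0, inserted >= detected)
  if (detected <= 0) stop("correction undefined: no synthetic mutations detected")
  correction <- inserted / detected
  scale <- correction / callable
  ci <- poisson_exact_ci(m, alpha) * scale
  structure(list(m = m, callable = callable, inserted = inserted,
                 detected = detected, correction = correction,
                 fnr = (inserted - detected) / inserted,
                 mu = m * scale,
                 ci_low = unname(ci["lower"]), ci_high = unname(ci["upper"]),
                 alpha = alpha),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf(
    "mutation rate: mu = %s per site per generation\n  %d%% CI (%s, %s)\n",
    format(signif(x$mu, 3), scientific = TRUE),
    round(100 * (1 - x$alpha)),
    format(signif(x$ci_low, 3), scientific = TRUE),
    format(signif(x$ci_high, 3), scientific = TRUE)))
  cat(sprintf("  m = %d, C = %s, FNR correction = %d/%d = %.4f\n",
              x$m, format(x$callable, big.mark = ","),
              x$inserted, x$detected, x$correction))
  invisible(x)
}

#' Assemble the final analysis report
#'
#' Bundles every stage output -- paternity, filter funnel, candidate table,
#' per-trio callable counts, FNR and the rate estimate -- into one
#' machine-readable structure, optionally written as JSON. Every input
#' number of the rate formula is carried with its provenance so the final
#' estimate can be audited line by line.
#'
#' @param funnel a `filter_funnel` from [detect_candidates()].
#' @param candidates the candidates data.frame.
#' @param callable a [callable_summary()].
#' @param fnr an `fnr_estimate`.
#' @param rate a `rate_estimate`.
#' @param paternity optional `paternity_result`.
#' @param path optional path to write the JSON bundle.
#' @return a list of class `dnm_report` (invisibly written to `path` if
#'   given). Fails naming the stage if a required stage output is missing.
#' @export
render_report <- function(funnel, candidates, callable, fnr, rate,
                          paternity = NULL, path = NULL) {
  stages <- list(funnel = funnel, candidates = candidates,
                 callable = callable, fnr = fnr, rate = rate)
  for (nm in names(stages))
    if (is.null(stages[[nm]]))
      stop("missing stage output: ", nm)
  report <- list(
    schema = "pedmut-report-1",
    paternity = if (!is.null(paternity)) list(
      father = paternity$father,
      mendelian = paternity$mendelian$table,
      rank_test = if (!is.null(paternity$rank_test)) paternity$rank_test$table),
    funnel = as.data.frame(funnel),
    candidates = candidates,
    callable = list(per_trio = callable$per_trio, total = callable$total,
                    doubling_factor = callable$doubling_factor),
    fnr = list(callable_inserted = fnr$callable_inserted,
               detected = fnr$detected, missed = fnr$missed, fnr = fnr$fnr),
    rate = list(m = rate$m, callable = rate$callable,
                inserted = rate$inserted, detected = rate$detected,
                correction = rate$correction, mu = rate$mu,
                ci_low = rate$ci_low, ci_high = rate$ci_high,
                alpha = rate$alpha))
  class(report) <- c("dnm_report", "list")
  if (!is.null(path))
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
  invisible(report)
}

#' @export
print.dnm_report <- function(x, ...) {
  cat("de novo mutation rate report\n")
  if (!is.null(x$paternity)) cat("  father:", x$paternity$father, "\n")
  cat("  candidates:", nrow(x$candidates), " callable C:",
      format(x$callable$total, big.mark = ","), "\n")
  cat(sprintf("  FNR: %d/%d = %.1f%%\n", x$fnr$missed,
              x$fnr$callable_inserted, 100 * x$fnr$fnr))
  cat(sprintf("  mu = %s (%s, %s)\n",
              format(signif(x$rate$mu, 3), scientific = TRUE),
              format(signif(x$rate$ci_low, 3), scientific = TRUE),
              format(signif(x$rate$ci_high, 3), scientific = TRUE)))
  invisible(x)
}
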