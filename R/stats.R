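#' Linear regression and R-squared
#'
#' Ordinary least squares of `y` on `x`; the coefficient of determination
#' equals the squared Pearson correlation for a simple linear fit.
#'
#' @param x,y Numeric vectors of equal length (n >= 3; `x` not constant).
#' @return list with `slope`, `intercept`, `r_squared`.
#' @export
linear_fit_r2 <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  if (length(x) < 3) stopf("need at least 3 observations")
  if (stats::sd(x) == 0) stopf("x is constant; slope undefined")
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  list(slope = unname(co[2]), intercept = unname(co[1]),
       r_squared = summary(fit)$r.squared)
}

#' Bland-Altman agreement analysis
#'
#' Differences are oriented `y - x`: `x` is the reference condition and `y`
#' the condition of interest, so a positive bias means the condition of
#' interest reads higher. Limits of agreement are `bias +/- 1.96 * sd` of
#' the differences.
#'
#' @param x Reference measurements.
#' @param y Condition-of-interest measurements (same length, n >= 2).
#' @return list with `bias`, `sd_diff`, `loa_low`, `loa_high`, `n` and a
#'   data.frame `points` of per-pair means and differences for plotting.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  if (length(x) < 2) stopf("need at least 2 pairs")
  d <- y - x
  bias <- mean(d)
  sdd <- stats::sd(d)
  list(bias = bias, sd_diff = sdd,
       loa_low = bias - 1.96 * sdd, loa_high = bias + 1.96 * sdd,
       n = length(x),
       points = data.frame(mean = (x + y) / 2, diff = d))
}

#' Root-mean-square coefficient of variation
#'
#' Reproducibility over repeated measurements: per subject the coefficient
#' of variation is the sample standard deviation (n-1) over the mean; the
#' RMSCV is `100 * sqrt(mean(CV^2))` in percent.
#'
#' @param repeated_measurements List of numeric vectors, one per subject,
#'   each with >= 2 repeats and positive mean.
#' @return RMSCV in percent.
#' @export
rmscv <- function(repeated_measurements) {
  if (!is.list(repeated_measurements) || length(repeated_measurements) == 0)
    stopf("need a non-empty list of per-subject repeat vectors")
  cv <- vapply(repeated_measurements, function(v) {
    if (length(v) < 2) stopf("each subject needs at least 2 repeats")
    m <- mean(v)
    if (m <= 0) stopf("subject mean must be positive for a CV")
    stats::sd(v) / m
  }, numeric(1))
  100 * sqrt(mean(cv^2))
}

#' Two-tailed t-tests with degenerate-case handling
#'
#' Paired tests use difference scores; unpaired tests use Welch's unequal
#' variance form. Degenerate inputs are handled by convention: zero variance
#' with identical means gives `t = 0, p = 1`; zero variance with a non-zero
#' mean difference is reported as `p = 0` with `degenerate = TRUE`.
#'
#' @param a,b Numeric vectors (equal length when `paired`).
#' @param paired Paired test?
#' @return list with `t`, `p`, `df`, per-group `mean`/`sd`, `paired` and
#'   `degenerate`.
#' @export
t_tests <- function(a, b, paired = FALSE) {
  if (paired && length(a) != length(b))
    stopf("paired test needs equal lengths")
  if (length(a) < 2 || length(b) < 2) stopf("need n >= 2 per group")
  out <- list(mean_a = mean(a), sd_a = stats::sd(a),
              mean_b = mean(b), sd_b = stats::sd(b),
              paired = paired, degenerate = FALSE)
  degen <- if (paired) stats::sd(a - b) == 0 else
    stats::sd(a) == 0 && stats::sd(b) == 0
  if (degen) {
    same <- if (paired) all(a == b) else mean(a) == mean(b)
    out$t <- if (same) 0 else sign(mean(a) - mean(b)) * Inf
    out$p <- if (same) 1 else 0
    out$df <- NA_real_
    out$degenerate <- !same
    return(out)
  }
  tt <- stats::t.test(a, b, paired = paired, var.equal = FALSE,
                      alternative = "two.sided")
  out$t <- unname(tt$statistic)
  out$p <- tt$p.value
  out$df <- unname(tt$parameter)
  out
}

#' Percent difference relative to a reference
#'
#' `100 * (with - without) / without`; note the asymmetry of the measure
#' (a 5% increase is not the negation of the reverse direction's 4.76%).
#'
#' @param with_val Value in the condition of interest.
#' @param without_val Reference value (> 0).
#' @return Percent difference (vectorised).
#' @export
percent_difference <- function(with_val, without_val) {
  if (any(without_val <= 0)) stopf("reference value must be positive")
  100 * (with_val - without_val) / without_val
}

#' Full agreement report between two measurement conditions
#'
#' Combines the linear fit ([linear_fit_r2()]) and Bland-Altman analysis
#' ([bland_altman()]) of paired failure loads measured under a reference
#' condition `x` and a condition of interest `y`.
#'
#' @param x,y Paired measurements (reference, condition of interest).
#' @return list of class `agreement_report`: `slope`, `intercept`,
#'   `r_squared`, `bias`, `loa_low`, `loa_high`, `n`, `points`.
#' @export
agreement_report <- function(x, y) {
  fit <- linear_fit_r2(x, y)
  ba <- bland_altman(x, y)
  structure(c(fit, ba), class = "agreement_report")
}

#' @rdname agreement_report
#' @param report An `agreement_report`.
#' @param json_path,csv_path Output paths (either may be `NULL`); the CSV
#'   holds the per-pair means and differences so any front end can draw the
#'   correlation and Bland-Altman panels.
#' @export
write_agreement_report <- function(report, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(report, "agreement_report"))
  if (!is.null(json_path))
    jsonlite::write_json(report[c("slope", "intercept", "r_squared", "bias",
                                  "sd_diff", "loa_low", "loa_high", "n")],
                         json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(csv_path))
    utils::write.csv(report$points, csv_path, row.names = FALSE)
  invisible(report)
}

#' @export
#' @method print agreement_report
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> n=%d  R^2=%.3f  slope=%.3f  bias=%.1f  LoA=[%.1f, %.1f]\n",
              x$n, x$r_squared, x$slope, x$bias, x$loa_low, x$loa_high))
  invisible(x)
}
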