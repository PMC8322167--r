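#' Signal-to-noise ratio in dB
#'
#' `SNR = 20 * log10(|mean| / sd)`, with the unbiased (n-1) sample standard
#' deviation -- the monitor's precision metric, computed over a stationary
#' stretch of the impedance series. Scale-invariant: multiplying the series
#' by a positive constant leaves the SNR unchanged.
#'
#' @param series Numeric vector (>= 2 values, nonzero mean).
#' @return SNR in dB; `Inf` with a warning when the series has zero spread.
#' @export
#' @examples
#' snr_db(rep(c(99, 101), 50))  # ~40 dB
snr_db <- function(series) {
  series <- series[is.finite(series)]
  if (length(series) < 2) stop("need at least 2 values", call. = FALSE)
  m <- mean(series)
  if (m == 0) stop("zero-mean series has undefined SNR", call. = FALSE)
  s <- stats::sd(series)
  if (s == 0) {
    warning("zero standard deviation: SNR is infinite", call. = FALSE)
    return(Inf)
  }
  20 * log10(abs(m) / s)
}

#' Temporal coefficient of variation
#'
#' `CV = 100 * sd / mean` over a time window (canonically ~3 min), the
#' monitor's temporal-stability metric.
#'
#' @param series Numeric values.
#' @param t_s Optional timestamps; with `window_s`, restricts to the first
#'   `window_s` seconds of the series.
#' @param window_s Optional window length, seconds.
#' @return CV in percent.
#' @export
coefficient_of_variation <- function(series, t_s = NULL, window_s = NULL) {
  if (!is.null(t_s) && !is.null(window_s)) {
    keep <- t_s <= min(t_s, na.rm = TRUE) + window_s
    series <- series[keep]
  }
  series <- series[is.finite(series)]
  if (length(series) < 2) stop("need at least 2 values in window",
                               call. = FALSE)
  m <- mean(series)
  if (m == 0) stop("zero mean: CV undefined", call. = FALSE)
  100 * stats::sd(series) / abs(m)
}

#' Linear calibration of measured against true loads
#'
#' Fits the least-squares line mapping measured impedance to true load
#' resistance across the calibration points (canonically five resistors
#' spanning 10 ohm to 2 kohm).
#'
#' @param measured Measured impedances, ohms.
#' @param truth True load resistances, ohms.
#' @return Object of class `bim_calibration` with `slope`, `intercept`,
#'   `residuals` and the calibration data.
#' @export
calibrate_linear <- function(measured, truth) {
  if (length(measured) != length(truth) || length(measured) < 2) {
    stop("need >= 2 paired calibration points", call. = FALSE)
  }
  if (stats::sd(measured) == 0) {
    stop("identical calibration loads: fit undefined", call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(1, measured), truth)
  structure(list(intercept = unname(fit$coefficients[1]),
                 slope = unname(fit$coefficients[2]),
                 residuals = unname(fit$residuals),
                 measured = measured, truth = truth),
            class = "bim_calibration")
}

#' @export
#' @rdname calibrate_linear
#' @param object A `bim_calibration`.
#' @param newdata Measured impedances to calibrate.
#' @param ... Unused.
predict.bim_calibration <- function(object, newdata, ...) {
  object$intercept + object$slope * newdata
}

#' Held-out calibration accuracy
#'
#' `100 * (1 - mean(|predicted - true| / true))` over held-out loads not used
#' in the fit -- the mean relative prediction accuracy, in percent.
#'
#' @param fit A [calibrate_linear()] fit.
#' @param measured Held-out measured impedances, ohms.
#' @param truth Held-out true resistances, ohms.
#' @return Accuracy in percent (capped below at 0).
#' @export
calibration_accuracy <- function(fit, measured, truth) {
  pred <- predict(fit, measured)
  max(0, 100 * (1 - mean(abs(pred - truth) / truth)))
}

#' @export
print.bim_calibration <- function(x, ...) {
  cat("<bim_calibration> truth = ", signif(x$intercept, 4), " + ",
      signif(x$slope, 6), " * measured, ", length(x$measured),
      " points\n", sep = "")
  invisible(x)
}

#' Power of a paired t-test
#'
#' Exact noncentral-t power for a paired (one-sample difference) t-test with
#' effect size `d = mean_diff / sd_diff` at sample size `n`.
#'
#' @param n Number of pairs (>= 2).
#' @param d Effect size (Cohen's d of the paired differences).
#' @param alpha Significance level (default 0.05).
#' @param tails 1 or 2 (default 2).
#' @return Power in (0, 1).
#' @export
paired_power <- function(n, d, alpha = 0.05, tails = 2) {
  stopifnot(n >= 2, tails %in% c(1, 2))
  df <- n - 1
  ncp <- abs(d) * sqrt(n)
  crit <- stats::qt(1 - alpha / tails, df)
  pow <- stats::pt(crit, df, ncp = ncp, lower.tail = FALSE)
  if (tails == 2) {
    pow <- pow + stats::pt(-crit, df, ncp = ncp)
  }
  pow
}

#' Minimum paired sample size for target power
#'
#' Smallest `n` such that a paired t-test on differences with mean
#' `mean_diff` and standard deviation `sd_diff` attains the target power,
#' computed by iterating the exact noncentral-t power expression (the normal
#' approximation understates the required n at small samples). With the
#' design inputs of a 0.003 V expected difference against a 0.002 V standard
#' deviation (d = 1.5), alpha 0.05, power 0.95, two-sided, this gives n = 8.
#'
#' @param mean_diff Expected mean paired difference (any units, nonzero).
#' @param sd_diff Standard deviation of the differences (same units, > 0).
#' @param alpha Significance level (default 0.05).
#' @param power Target power in (alpha, 1) (default 0.95).
#' @param tails 1 or 2 (default 2).
#' @param n_max Search ceiling (default 1e5).
#' @return Integer sample size (>= 2).
#' @export
#' @examples
#' paired_sample_size(0.003, 0.002)  # 8
paired_sample_size <- function(mean_diff, sd_diff, alpha = 0.05,
                               power = 0.95, tails = 2, n_max = 1e5) {
  stopifnot(mean_diff != 0, sd_diff > 0, alpha > 0, alpha < 1,
            power > alpha, power < 1)
  d <- abs(mean_diff) / sd_diff
  for (n in 2:n_max) {
    if (paired_power(n, d, alpha = alpha, tails = tails) >= power) {
      return(as.integer(n))
    }
  }
  stop("target power unattainable within n_max = ", n_max, call. = FALSE)
}
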