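#' Fit camera sensitivity and effective attenuation from a depth series
#'
#' The calibration measurement images a source of known activity at
#' several depths in an attenuating phantom; count rate falls off as
#' `k * A * exp(-mu * d)`. The model is exactly linearisable, so the fit
#' is unweighted least squares of log(rate) on depth: `mu` is minus the
#' slope and `k` is the extrapolated zero-depth intercept divided by the
#' source activity. R-squared is reported on the log scale.
#'
#' @param series `data.frame` with columns `depth_cm`, `counts`,
#'   `duration_s` (see [make_calibration_series()]).
#' @param source_activity Source activity in MBq; > 0.
#' @return An object of class `calibration_result` with fields
#'   `sensitivity_k` (cps/MBq), `mu` (cm^-1), `fit_r_squared`, `n_points`.
#' @export
fit_depth_series <- function(series, source_activity) {
  stopifnot(is.data.frame(series),
            all(c("depth_cm", "counts", "duration_s") %in% names(series)),
            source_activity > 0)
  if (length(unique(series$depth_cm)) < 3L)
    stop("calibration requires at least 3 distinct depths")
  if (any(series$counts <= 0))
    stop("all counts must be positive for the log-linear fit")
  rate <- series$counts / series$duration_s
  fit <- stats::lm(log(rate) ~ depth_cm, data = series)
  co <- stats::coef(fit)
  k <- exp(co[[1]]) / source_activity
  mu <- max(0, -co[[2]])
  ss_tot <- sum((log(rate) - mean(log(rate)))^2)
  r2 <- if (ss_tot == 0) 1 else
    suppressWarnings(summary(fit)$r.squared)
  structure(list(sensitivity_k = k, mu = mu, fit_r_squared = r2,
                 n_points = nrow(series)),
            class = "calibration_result")
}

#' @rdname fit_depth_series
#' @param sensitivity_k,mu,fit_r_squared,n_points Field values; use to
#'   construct a result from externally known camera constants.
#' @export
calibration_result <- function(sensitivity_k, mu, fit_r_squared = NA_real_,
                               n_points = NA_integer_) {
  stopifnot(sensitivity_k > 0, mu >= 0)
  structure(list(sensitivity_k = sensitivity_k, mu = mu,
                 fit_r_squared = fit_r_squared, n_points = n_points),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("camera calibration: k = %.4g cps/MBq, mu = %.4g cm^-1 (R2 = %.4f, n = %s)\n",
              x$sensitivity_k, x$mu, x$fit_r_squared, x$n_points))
  invisible(x)
}
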