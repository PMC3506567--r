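#' Time-activity series for one kidney
#'
#' @param time_h Strictly increasing times in hours post-administration.
#' @param activity_MBq Non-negative activities.
#' @param decay_corrected Whether the activities have already been
#'   corrected for physical decay back to t = 0.
#' @return A `data.frame` of class `ta_series` with attribute
#'   `decay_corrected`.
#' @export
time_activity_series <- function(time_h, activity_MBq,
                                 decay_corrected = FALSE) {
  stopifnot(length(time_h) == length(activity_MBq),
            all(diff(time_h) > 0), all(activity_MBq >= 0))
  structure(data.frame(time_h = time_h, activity_MBq = activity_MBq),
            decay_corrected = isTRUE(decay_corrected),
            class = c("ta_series", "data.frame"))
}

#' Correct a measured series for physical decay
#'
#' Imaged activities include physical decay; multiplying by
#' `exp(+lambda_phys * t)` recovers the biological retention curve. A
#' series already flagged as decay-corrected is refused so the correction
#' cannot be applied twice.
#'
#' @param series A [time_activity_series()].
#' @param lambda_phys Physical decay constant, h^-1.
#' @return The corrected series, flagged `decay_corrected`.
#' @export
decay_correct <- function(series, lambda_phys = lu177_lambda_phys()) {
  stopifnot(inherits(series, "ta_series"))
  if (isTRUE(attr(series, "decay_corrected")))
    stop("series is already decay-corrected")
  time_activity_series(series$time_h,
                       series$activity_MBq * exp(lambda_phys * series$time_h),
                       decay_corrected = TRUE)
}

#' Fit a mono-exponential retention model
#'
#' Fits `A(t) = A0 * exp(-lambda_bio * t)` to a decay-corrected series by
#' nonlinear least squares on the linear scale (so late, small activities
#' are not over-weighted), initialised from a log-linear regression. The
#' effective decay constant is `lambda_eff = lambda_bio + lambda_phys`;
#' an uptake-dominated series can yield `lambda_bio < 0` and, when
#' `lambda_eff <= 0`, an unbounded retention integral (flagged via
#' `bounded = FALSE`). R-squared is computed on the linear scale.
#'
#' @param series A decay-corrected [time_activity_series()] with >= 2
#'   positive activities.
#' @param lambda_phys Physical decay constant, h^-1.
#' @return An object of class `kinetic_fit` with fields `A0`,
#'   `lambda_bio`, `lambda_eff` (all h^-1 where applicable), `r_squared`,
#'   `bounded`, `n_points`.
#' @export
fit_monoexp <- function(series, lambda_phys = lu177_lambda_phys()) {
  stopifnot(inherits(series, "ta_series"))
  pos <- series$activity_MBq > 0
  if (sum(pos) < 2L)
    stop("need at least 2 time points with positive activity")
  t <- series$time_h[pos]
  a <- series$activity_MBq[pos]
  # log-linear initialisation (exact when the data are exactly exponential)
  init <- stats::lm(log(a) ~ t)
  A0 <- exp(stats::coef(init)[[1]])
  lb <- -stats::coef(init)[[2]]
  if (length(t) > 2L) {
    fit <- tryCatch(
      minpack.lm::nlsLM(a ~ A0 * exp(-lb * t),
                        start = list(A0 = A0, lb = lb),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      A0 <- stats::coef(fit)[["A0"]]
      lb <- stats::coef(fit)[["lb"]]
    }
  }
  pred <- A0 * exp(-lb * series$time_h)
  ss_res <- sum((series$activity_MBq - pred)^2)
  ss_tot <- sum((series$activity_MBq - mean(series$activity_MBq))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  lambda_eff <- lb + lambda_phys
  structure(list(A0 = A0, lambda_bio = lb, lambda_eff = lambda_eff,
                 r_squared = r2, bounded = lambda_eff > 0,
                 n_points = length(t)),
            class = "kinetic_fit")
}

#' Cumulated activity from a mono-exponential fit
#'
#' The cumulated activity is the number of disintegrations in the organ
#' from administration to infinity,
#' \deqn{\tilde A = \int_0^\infty A_0 e^{-\lambda_{eff} t}\,dt
#'       = A_0 / \lambda_{eff},}
#' in MBq h (3.6e9 decays per MBq h). A fit with `lambda_eff <= 0` has an
#' infinite integral; the result is then flagged unbounded and carries no
#' finite value, so cohort code can count such estimations rather than
#' crash.
#'
#' @param fit A [fit_monoexp()] result.
#' @return An object of class `cumulated_activity` with fields
#'   `a_tilde_MBqh`, `decays`, `bounded`.
#' @export
cumulated_activity <- function(fit) {
  stopifnot(inherits(fit, "kinetic_fit"))
  if (fit$bounded) {
    a_tilde <- fit$A0 / fit$lambda_eff
    structure(list(a_tilde_MBqh = a_tilde, decays = a_tilde * MBQH_TO_DECAYS,
                   bounded = TRUE),
              class = "cumulated_activity")
  } else {
    structure(list(a_tilde_MBqh = NA_real_, decays = NA_real_,
                   bounded = FALSE),
              class = "cumulated_activity")
  }
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("mono-exponential fit: A0 = %.4g MBq, lambda_bio = %.4g /h, lambda_eff = %.4g /h, R2 = %.4f%s\n",
              x$A0, x$lambda_bio, x$lambda_eff, x$r_squared,
              if (x$bounded) "" else " [unbounded]"))
  invisible(x)
}
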