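#' Region of interest on a planar image
#'
#' @param pixels Two-column matrix of (row, col) 0-based pixel
#'   coordinates.
#' @param label ROI name.
#' @param kind `"kidney"`, `"background"`, or `"partial-kidney"` (a
#'   sub-region drawn where the kidney is free of overlapping uptake).
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(pixels, label = "roi",
                     kind = c("kidney", "background", "partial-kidney")) {
  kind <- match.arg(kind)
  pixels <- as.matrix(pixels)
  stopifnot(ncol(pixels) == 2L, nrow(pixels) >= 1L, all(pixels >= 0L))
  structure(list(pixels = pixels, label = as.character(label), kind = kind),
            class = "roi_mask")
}

#' @rdname roi_mask
#' @param region A [source_region()]; convenience constructor taking the
#'   region's footprint as the ROI.
#' @export
roi_from_region <- function(region, kind = "kidney") {
  stopifnot(inherits(region, "source_region"))
  roi_mask(region$footprint, label = region$label, kind = kind)
}

#' Count rate inside an ROI
#'
#' Sums image values over the ROI and converts counts to rates using the
#' image dwell time (rate images are already in cps and are summed
#' directly).
#'
#' @param image A `count_image` or `rate_image`.
#' @param roi An [roi_mask()] within the image bounds.
#' @return List with `total_cps` and `mean_cpp` (cps per pixel).
#' @export
roi_rate <- function(image, roi) {
  stopifnot(inherits(image, c("count_image", "rate_image")),
            inherits(roi, "roi_mask"))
  px <- image$pixels
  if (any(roi$pixels[, 1] >= nrow(px)) || any(roi$pixels[, 2] >= ncol(px)))
    stop("ROI '", roi$label, "' extends outside the image")
  vals <- px[roi$pixels[, 1] + 1L + roi$pixels[, 2] * nrow(px)]
  total <- sum(vals)
  if (inherits(image, "count_image")) total <- total / image$dwell_time
  list(total_cps = total, mean_cpp = total / nrow(roi$pixels))
}

#' Mirror an ROI for use on the opposite view
#'
#' Kidney ROIs are drawn on the posterior image and mirrored left-right
#' for the anterior image: column `c` maps to `image_cols - 1 - c`, rows
#' are unchanged. Mirroring is its own inverse.
#'
#' @param roi An [roi_mask()].
#' @param image_cols Number of columns of the target image.
#' @return The mirrored `roi_mask`.
#' @export
mirror_roi <- function(roi, image_cols) {
  stopifnot(inherits(roi, "roi_mask"), all(roi$pixels[, 2] < image_cols))
  out <- roi
  out$pixels[, 2] <- image_cols - 1L - roi$pixels[, 2]
  out
}

#' Extrapolate counts from a partial kidney ROI to the whole kidney
#'
#' When overlapping uptake (liver, spleen, intestine, tumour) obscures
#' part of a kidney, a small ROI is drawn over the unobscured part and
#' its rate is scaled to the full kidney pixel count, assuming similar
#' counts per pixel.
#'
#' @param rate_partial Rate in the partial ROI, cps.
#' @param n_partial Pixels in the partial ROI; >= 1.
#' @param n_total Pixels in the full kidney ROI; >= `n_partial`.
#' @return Extrapolated rate in cps.
#' @export
extrapolate_partial <- function(rate_partial, n_partial, n_total) {
  stopifnot(n_partial >= 1, n_total >= n_partial, rate_partial >= 0)
  rate_partial * n_total / n_partial
}

#' Thickness-scaled background subtraction
#'
#' The mean background rate per pixel is scaled by `(T - x) / T` — the
#' fraction of the body column at the kidney position that is *not*
#' kidney, assuming homogeneous background activity concentration — and
#' subtracted from the mean kidney-ROI rate per pixel. A negative
#' corrected rate is clamped to zero and flagged.
#'
#' @param kidney_mean_cpp Mean kidney-ROI rate, cps/pixel.
#' @param bg_mean_cpp Mean background-ROI rate, cps/pixel.
#' @param trunk_T Body AP thickness at kidney level, cm.
#' @param thickness_x Kidney AP thickness, cm; `0 <= x <= T`.
#' @param n_kidney_pixels Pixel count of the full kidney ROI.
#' @return List with `total_cps`, `per_pixel_cps`, and logical `clamped`.
#' @export
background_correct <- function(kidney_mean_cpp, bg_mean_cpp, trunk_T,
                               thickness_x, n_kidney_pixels) {
  stopifnot(thickness_x >= 0, trunk_T > 0, n_kidney_pixels >= 1)
  if (thickness_x > trunk_T)
    stop("kidney thickness exceeds trunk thickness")
  per_pixel <- kidney_mean_cpp - bg_mean_cpp * (trunk_T - thickness_x) / trunk_T
  clamped <- per_pixel < 0
  if (clamped) per_pixel <- 0
  list(total_cps = per_pixel * n_kidney_pixels,
       per_pixel_cps = per_pixel, clamped = clamped)
}

# thickness factor mu*x / (2*sinh(mu*x/2)), -> 1 as mu*x -> 0
cv_thickness_factor <- function(mu, x) {
  mx <- mu * x
  if (mx < 1e-12) 1 else mx / (2 * sinh(mx / 2))
}

# thickness factor mu*x / (1 - exp(-mu*x)), -> 1 as mu*x -> 0
pa_thickness_factor <- function(mu, x) {
  mx <- mu * x
  if (mx < 1e-12) 1 else mx / (1 - exp(-mx))
}

#' Conjugate-view (CV) activity estimate
#'
#' The geometric mean of the background-corrected anterior and posterior
#' count rates, corrected for body attenuation and source self-
#' attenuation:
#' \deqn{A = \frac{\sqrt{R_A R_P}\, e^{\mu T/2}\, \mu x}
#'            {k\,(e^{\mu x/2} - e^{-\mu x/2})}.}
#' For a uniform slab source the estimate is independent of the source's
#' AP position, which is the method's key advantage. The thickness factor
#' tends to 1 as `x -> 0`.
#'
#' @param R_A,R_P Background-corrected anterior / posterior rates, cps.
#' @param trunk_T Body AP thickness, cm.
#' @param thickness_x Kidney AP thickness, cm; `0 < x <= T` (x = 0 is
#'   accepted as the point-source limit).
#' @param calib A [calibration_result()].
#' @param time_h Imaging time recorded in the estimate.
#' @return An `activity_estimate` with fields `activity` (MBq), `method`,
#'   `time_h`.
#' @export
activity_cv <- function(R_A, R_P, trunk_T, thickness_x, calib,
                        time_h = NA_real_) {
  stopifnot(inherits(calib, "calibration_result"),
            R_A >= 0, R_P >= 0, trunk_T > 0, thickness_x >= 0)
  if (thickness_x > trunk_T)
    stop("kidney thickness exceeds trunk thickness")
  A <- sqrt(R_A * R_P) * exp(calib$mu * trunk_T / 2) *
    cv_thickness_factor(calib$mu, thickness_x) / calib$sensitivity_k
  structure(list(activity = A, method = "CV", time_h = time_h),
            class = "activity_estimate")
}

#' Posterior-only (PA) activity estimate
#'
#' Quantification from the posterior image alone: the background-
#' corrected posterior rate is corrected for attenuation over the kidney
#' depth `a` and for self-attenuation of the kidney slab:
#' \deqn{A = \frac{R_P\, e^{\mu a}\, \mu x}{k\,(1 - e^{-\mu x})}.}
#' Exact for a uniform box source at the true depth; a depth error
#' `da` biases the estimate by the factor `exp(mu * da)`.
#'
#' @param R_P Background-corrected posterior rate, cps.
#' @param depth_a Distance from the back to the posterior kidney edge, cm.
#' @param thickness_x Kidney AP thickness, cm.
#' @param calib A [calibration_result()].
#' @param time_h Imaging time recorded in the estimate.
#' @return An `activity_estimate`.
#' @export
activity_pa <- function(R_P, depth_a, thickness_x, calib,
                        time_h = NA_real_) {
  stopifnot(inherits(calib, "calibration_result"),
            R_P >= 0, depth_a >= 0, thickness_x >= 0)
  A <- R_P * exp(calib$mu * depth_a) *
    pa_thickness_factor(calib$mu, thickness_x) / calib$sensitivity_k
  structure(list(activity = A, method = "PA", time_h = time_h),
            class = "activity_estimate")
}
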