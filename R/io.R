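#' Read and write calibration depth series
#'
#' Delimited text with header `depth_cm`, `counts`, `duration_s`.
#'
#' @param series A depth-series `data.frame`.
#' @param path File path.
#' @return `read_depth_series()` returns the `data.frame`.
#' @export
write_depth_series <- function(series, path) {
  stopifnot(all(c("depth_cm", "counts", "duration_s") %in% names(series)))
  utils::write.table(format(series, digits = 6, trim = TRUE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_depth_series
#' @export
read_depth_series <- function(path) {
  s <- utils::read.delim(path)
  stopifnot(all(c("depth_cm", "counts", "duration_s") %in% names(s)))
  s
}

#' Read and write a calibration result as structured config
#'
#' @param calib A `calibration_result`.
#' @param path YAML file path.
#' @export
write_calibration <- function(calib, path) {
  stopifnot(inherits(calib, "calibration_result"))
  yaml::write_yaml(unclass(calib), path, precision = 15)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- yaml::read_yaml(path)
  calibration_result(x$sensitivity_k, x$mu,
                     fit_r_squared = x$fit_r_squared %||% NA_real_,
                     n_points = x$n_points %||% NA_integer_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write and read planar images as TIFF with a sidecar metadata file
#'
#' Count images are stored as 16-bit unsigned TIFF (exact up to 65535
#' counts per pixel); rate images as 32-bit float TIFF (round-trip at
#' single precision). Scale, view, time and geometry travel in a
#' delimited-text sidecar `<path>.meta.tsv`.
#'
#' @param image A `count_image` or `rate_image`.
#' @param path TIFF file path.
#' @export
write_image <- function(image, path) {
  is_count <- inherits(image, "count_image")
  stopifnot(is_count || inherits(image, "rate_image"))
  mx <- max(image$pixels)
  if (is_count) {
    if (mx > 65535) stop("counts exceed the 16-bit range")
    tiff::writeTIFF(image$pixels / 65535, path, bits.per.sample = 16L)
    scale <- 65535
  } else {
    scale <- if (mx > 0) mx else 1
    tiff::writeTIFF(image$pixels / scale, path, bits.per.sample = 32L)
  }
  meta <- data.frame(key = c("kind", "view", "time_h", "pixel_size",
                             "dwell_time", "scale"),
                     value = c(if (is_count) "counts" else "rate",
                               image$view, image$time_h, image$pixel_size,
                               image$dwell_time, scale))
  utils::write.table(meta, paste0(path, ".meta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  meta <- utils::read.delim(paste0(path, ".meta.tsv"),
                            colClasses = "character")
  get <- function(k) meta$value[meta$key == k]
  px <- tiff::readTIFF(path) * as.numeric(get("scale"))
  args <- list(view = get("view"), time_h = as.numeric(get("time_h")),
               pixel_size = as.numeric(get("pixel_size")),
               dwell_time = as.numeric(get("dwell_time")))
  if (get("kind") == "counts") {
    counts <- matrix(as.integer(round(px)), nrow(px), ncol(px))
    do.call(new_count_image, c(list(pixels = counts), args))
  } else {
    do.call(new_rate_image, c(list(pixels = px), args))
  }
}

#' Write and read ROI masks as delimited pixel lists
#'
#' @param roi An [roi_mask()].
#' @param path File path.
#' @export
write_roi <- function(roi, path) {
  stopifnot(inherits(roi, "roi_mask"))
  df <- data.frame(row = roi$pixels[, 1], col = roi$pixels[, 2])
  attr_line <- sprintf("# label=%s kind=%s", roi$label, roi$kind)
  writeLines(attr_line, path)
  suppressWarnings(
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, append = TRUE))
  invisible(path)
}

#' @rdname write_roi
#' @export
read_roi <- function(path) {
  header <- readLines(path, n = 1L)
  m <- regmatches(header,
                  regexec("# label=(\\S+) kind=(\\S+)", header))[[1]]
  df <- utils::read.delim(path, skip = 1L)
  px <- as.matrix(df[, c("row", "col")])
  dimnames(px) <- NULL
  roi_mask(px, label = m[2], kind = m[3])
}

#' Write a dose result table as delimited text
#'
#' @param results `data.frame` of per-kidney dose results (as produced
#'   by [run_pipeline()]).
#' @param path File path.
#' @export
write_dose_table <- function(results, path) {
  utils::write.table(format(results, digits = 6, trim = TRUE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
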