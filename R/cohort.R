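#' Load a per-patient kidney dose table
#'
#' Reads the delimited-text cohort table shipped with the package (per
#' kidney and treatment cycle: dose per administered activity in Gy/GBq,
#' kidney AP thickness, mass, trunk thickness, sex). Missing-value
#' markers are preserved verbatim: `NA` (kidney not evaluable due to
#' overlapping uptake), `ND` (cycle not given/not done), `NP` (organ not
#' present). Any other non-numeric cell is an error naming the row.
#'
#' @param path Path to the table; defaults to the packaged transcription.
#' @return A long-format `data.frame` of class `cohort_table` with
#'   columns `patient`, `kidney`, `sex`, `kidney_thickness_cm`,
#'   `mass_kg`, `trunk_cm`, `cycle`, `d_per_a` (numeric, `NA` when
#'   missing), `marker` (the verbatim cell). The as-read wide table is
#'   kept in attribute `wide` so writing is lossless.
#' @export
load_cohort_table <- function(path = system.file("extdata",
                                                 "table2_kidney_doses.tsv",
                                                 package = "planardose")) {
  stopifnot(file.exists(path))
  wide <- utils::read.delim(path, colClasses = "character",
                            check.names = FALSE,
                            na.strings = character(0))
  need <- c("patient", "kidney", "sex", "kidney_thickness_cm", "mass_kg",
            "trunk_cm", paste0("cycle", 1:5))
  if (!all(need %in% names(wide)))
    stop("cohort table header does not match the expected schema")
  markers <- c("NA", "ND", "NP")
  parse_num <- function(cell, row, col) {
    if (cell %in% markers) return(NA_real_)
    v <- suppressWarnings(as.numeric(cell))
    if (is.na(v))
      stop("malformed numeric cell '", cell, "' in row ", row,
           " (", col, ")")
    v
  }
  rows <- vector("list", nrow(wide) * 5L)
  idx <- 0L
  for (i in seq_len(nrow(wide))) {
    geom <- vapply(c("kidney_thickness_cm", "mass_kg", "trunk_cm"),
                   function(col) parse_num(wide[i, col], i, col), 0)
    for (cy in 1:5) {
      cell <- wide[i, paste0("cycle", cy)]
      idx <- idx + 1L
      rows[[idx]] <- data.frame(
        patient = as.integer(wide$patient[i]),
        kidney = wide$kidney[i], sex = wide$sex[i],
        kidney_thickness_cm = geom[[1]], mass_kg = geom[[2]],
        trunk_cm = geom[[3]], cycle = cy,
        d_per_a = parse_num(cell, i, paste0("cycle", cy)),
        marker = cell)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "wide") <- wide
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' @rdname load_cohort_table
#' @param table A `cohort_table`.
#' @export
write_cohort_table <- function(table, path) {
  stopifnot(inherits(table, "cohort_table"))
  wide <- attr(table, "wide")
  if (is.null(wide)) stop("table carries no wide-format source")
  utils::write.table(wide, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Summary statistics of dose per administered activity
#'
#' Every numeric per-kidney per-cycle entry is weighted equally (no
#' per-patient averaging first); the standard deviation uses the n-1
#' denominator and the standard error is sd/sqrt(n).
#'
#' @param table A [load_cohort_table()] result.
#' @param cycles `"all"` or `"first"` (treatment cycle 1 only).
#' @return A list of class `summary_stats`: `n`, `mean`, `sd`, `sem`,
#'   `min`, `max`, all in Gy/GBq (`sd`/`sem` are `NA` for n = 1).
#' @export
summarize_doses <- function(table, cycles = c("all", "first")) {
  cycles <- match.arg(cycles)
  stopifnot(inherits(table, "cohort_table"))
  v <- table$d_per_a
  if (cycles == "first") v <- v[table$cycle == 1L]
  v <- v[!is.na(v)]
  if (length(v) == 0L) stop("no numeric dose entries in scope")
  s <- if (length(v) > 1L) stats::sd(v) else NA_real_
  structure(list(n = length(v), mean = mean(v), sd = s,
                 sem = s / sqrt(length(v)), min = min(v), max = max(v)),
            class = "summary_stats")
}

#' Per-cycle deviations from the first treatment cycle
#'
#' For each kidney side, every later-cycle dose is expressed as the
#' percentage deviation from that patient's first-cycle dose,
#' `100 * (D_cycle_n / D_cycle_1 - 1)` for n >= 2. Patients without a
#' numeric cycle-1 dose on a side are excluded for that side and
#' counted.
#'
#' @param table A [load_cohort_table()] result.
#' @return A `data.frame` with one row per side: `kidney`,
#'   `n_deviations`, `mean_pct`, `sd_pct`, `min_pct`, `max_pct`,
#'   `n_excluded_patients`.
#' @export
cycle_deviations <- function(table) {
  stopifnot(inherits(table, "cohort_table"))
  out <- lapply(c("right", "left"), function(side) {
    sub <- table[table$kidney == side, ]
    devs <- numeric(0)
    n_excl <- 0L
    for (p in unique(sub$patient)) {
      d1 <- sub$d_per_a[sub$patient == p & sub$cycle == 1L]
      later <- sub$d_per_a[sub$patient == p & sub$cycle >= 2L]
      later <- later[!is.na(later)]
      if (length(d1) == 0L || is.na(d1)) {
        if (length(later)) n_excl <- n_excl + 1L
        next
      }
      if (length(later))
        devs <- c(devs, 100 * (later / d1 - 1))
    }
    if (length(devs) == 0L) stop("no evaluable cycle pairs for ", side)
    data.frame(kidney = side, n_deviations = length(devs),
               mean_pct = mean(devs),
               sd_pct = if (length(devs) > 1) stats::sd(devs) else NA_real_,
               min_pct = min(devs), max_pct = max(devs),
               n_excluded_patients = n_excl)
  })
  do.call(rbind, out)
}

#' Synthetic cohort of kidney time-activity series
#'
#' Generates decay-corrected time-activity series at the standard imaging
#' schedule (1 h, 1 d, 2 d, 7 d), mixing the two retention patterns seen
#' clinically: a majority with maximal activity at the first scan
#' (mono-exponential clearance) and a minority whose observed maximum
#' occurs at day 1 or 2 (biphasic, with an uptake half-time of a few
#' hours, so the 1-h activity is already substantial). The default
#' mixing fraction 12/33 follows the observed proportion of slow-uptake
#' patients. Measurement error is multiplicative log-normal with
#' coefficient of variation `noise_cv`; the default 5 percent is the
#' within-series repeatability (counting statistics, background-ROI
#' variation) — the error component that does not cancel between the
#' time points of one series, as opposed to systematic calibration and
#' geometry errors which do.
#'
#' @param n Number of series.
#' @param frac_late_peak Fraction with a day 1-2 peak.
#' @param seed Integer seed.
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param times_h Imaging times; default `c(1, 24, 48, 168)`.
#' @return List of [time_activity_series()], each with attribute
#'   `pattern` (`"early"` or `"late"`).
#' @export
make_kinetic_cohort <- function(n = 200, frac_late_peak = 12 / 33,
                                seed = 1L, noise_cv = 0.05,
                                times_h = c(1, 24, 48, 168)) {
  stopifnot(n >= 1, frac_late_peak >= 0, frac_late_peak <= 1,
            noise_cv >= 0)
  set.seed(as.integer(seed))
  sdlog <- sqrt(log(1 + noise_cv^2))
  lapply(seq_len(n), function(i) {
    late <- stats::runif(1) < frac_late_peak
    A0 <- stats::rlnorm(1, meanlog = log(250), sdlog = 0.3)
    kin <- if (late) {
      # clearance half-time ~ 40-150 h, uptake half-time ~ 0.7-4 h
      lc <- log(2) / stats::rlnorm(1, meanlog = log(80), sdlog = 0.35)
      lu <- log(2) / stats::runif(1, 0.7, 4)
      if (lu <= lc) lu <- lc * 3
      biphasic_kinetics(A0, lc, lu)
    } else {
      monoexp_kinetics(A0, log(2) / stats::rlnorm(1, meanlog = log(70),
                                                  sdlog = 0.35))
    }
    act <- kinetic_activity(kin, times_h) *
      exp(stats::rnorm(length(times_h), 0, sdlog))
    s <- time_activity_series(times_h, act, decay_corrected = TRUE)
    attr(s, "pattern") <- if (late) "late" else "early"
    s
  })
}

#' Effect of omitting one imaging time point
#'
#' Refits the mono-exponential model to each series with one of the four
#' standard time points removed and compares the resulting cumulated
#' activity (and hence dose, the mass cancelling) with the all-points
#' value. Refits with a non-positive effective decay constant have an
#' infinite retention integral; they are counted separately and excluded
#' from the ratio statistics, mirroring how such estimations must be
#' excluded in practice.
#'
#' @param series_set List of decay-corrected series, each with exactly
#'   the times in `times_h`.
#' @param lambda_phys Physical decay constant, h^-1.
#' @param times_h The required imaging schedule.
#' @return A `data.frame` with one row per omission: `omit_h`, `n_used`,
#'   `n_unbounded`, `mean_ratio`, `sd_ratio`, `max_ratio`,
#'   `mean_abs_dev` (mean |ratio - 1|). Per-series ratios are kept in
#'   attribute `ratios` (list keyed by omitted time).
#' @export
omit_timepoint_study <- function(series_set,
                                 lambda_phys = lu177_lambda_phys(),
                                 times_h = c(1, 24, 48, 168)) {
  stopifnot(is.list(series_set), length(series_set) >= 1L)
  for (s in series_set) {
    if (!isTRUE(all.equal(s$time_h, times_h)))
      stop("every series must have exactly the times ",
           paste(times_h, collapse = ", "), " h")
  }
  full <- lapply(series_set, function(s) {
    cumulated_activity(fit_monoexp(s, lambda_phys))
  })
  usable <- vapply(full, `[[`, TRUE, "bounded")
  ratios <- list()
  rows <- lapply(seq_along(times_h), function(j) {
    om <- times_h[j]
    r <- rep(NA_real_, length(series_set))
    unb <- 0L
    for (i in seq_along(series_set)) {
      if (!usable[i]) next
      s <- series_set[[i]]
      keep <- s$time_h != om
      sub <- time_activity_series(s$time_h[keep], s$activity_MBq[keep],
                                  decay_corrected = TRUE)
      ca <- cumulated_activity(fit_monoexp(sub, lambda_phys))
      if (!ca$bounded) unb <- unb + 1L else
        r[i] <- ca$a_tilde_MBqh / full[[i]]$a_tilde_MBqh
    }
    ratios[[as.character(om)]] <<- r
    ok <- r[!is.na(r)]
    data.frame(omit_h = om, n_used = length(ok), n_unbounded = unb,
               mean_ratio = if (length(ok)) mean(ok) else NA_real_,
               sd_ratio = if (length(ok) > 1) stats::sd(ok) else NA_real_,
               max_ratio = if (length(ok)) max(ok) else NA_real_,
               mean_abs_dev = if (length(ok)) mean(abs(ok - 1))
                              else NA_real_)
  })
  out <- do.call(rbind, rows)
  attr(out, "ratios") <- ratios
  attr(out, "n_series_excluded") <- sum(!usable)
  out
}

#' Paired comparison of two dose-estimation methods
#'
#' @param cv,pa Paired dose vectors (Gy/GBq), equal length >= 3.
#' @return A list: `mean_difference` (cv - pa), `t_statistic`, `p_value`
#'   (two-sided paired t-test), `slope` and `intercept` of the
#'   least-squares regression of `pa` on `cv`, and the Pearson
#'   `correlation`. Degenerate inputs with zero variance yield `NA`
#'   test statistics.
#' @export
method_comparison <- function(cv, pa) {
  stopifnot(length(cv) == length(pa), length(cv) >= 3L)
  d <- cv - pa
  n <- length(d)
  sd_d <- stats::sd(d)
  if (sd_d > 1e-10 * max(abs(d), 1)) {
    tt <- stats::t.test(cv, pa, paired = TRUE)
    t_stat <- unname(tt$statistic)
    p <- tt$p.value
  } else {
    t_stat <- NA_real_
    p <- NA_real_
  }
  fit <- stats::lm(pa ~ cv)
  corr <- if (stats::sd(cv) > 0 && stats::sd(pa) > 0)
    stats::cor(cv, pa) else NA_real_
  list(mean_difference = mean(d), t_statistic = t_stat, p_value = p,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       correlation = corr)
}

# Simulate one kidney through projection -> quantification -> dose.
# Returns dose per administered activity for the CV method with the
# assumed geometry, and optionally for the PA method with an assumed
# depth. Noiseless unless a seed is given.
simulate_kidney_dose <- function(true_x, true_T, true_a, mass_assumed_kg,
                                 assumed_x = true_x, assumed_T = true_T,
                                 assumed_a = true_a,
                                 kin = monoexp_kinetics(200, log(2) / 70),
                                 camera = camera_model(10.9, 0.119, 20),
                                 administered_GBq = 7.4,
                                 method = c("CV", "PA"),
                                 times_h = c(1, 24, 48, 168),
                                 seed = NULL,
                                 lambda_phys = lu177_lambda_phys(),
                                 constants = dose_constants(lambda_phys =
                                                              lambda_phys)) {
  method <- match.arg(method)
  kidney <- box_region("kidney", 8, 19, 8, 15, thickness_x = true_x,
                       depth_a = true_a, activity = 1)
  spec <- phantom_spec(true_T, pixel_size = 0.5, grid_rows = 28,
                       grid_cols = 24, compartments = list(kidney),
                       camera = camera)
  series <- make_patient_series(spec, list(kidney = kin), times_h,
                                seed = if (is.null(seed)) 1L else seed,
                                lambda_phys = lambda_phys,
                                noiseless = is.null(seed))
  roi <- roi_from_region(kidney)
  acts <- vapply(series, function(fr) {
    rp <- roi_rate(fr$posterior, roi)$total_cps
    if (method == "CV") {
      ra <- roi_rate(fr$anterior, mirror_roi(roi, spec$grid_cols))$total_cps
      activity_cv(ra, rp, assumed_T, assumed_x,
                  calibration_result(camera$sensitivity_k, camera$mu))$activity
    } else {
      activity_pa(rp, assumed_a, assumed_x,
                  calibration_result(camera$sensitivity_k, camera$mu))$activity
    }
  }, 0)
  ta <- decay_correct(time_activity_series(times_h, acts), lambda_phys)
  ca <- cumulated_activity(fit_monoexp(ta, lambda_phys))
  mean_dose(ca, mass_assumed_kg, constants, administered_GBq)
}

#' Default patient selection for the organ-size sub-study
#'
#' Ten patients (four female, six male) spanning the cohort's kidney-mass
#' range per sex, including the patients with the smallest and the
#' largest kidneys, emulating how such a sensitivity sub-study selects
#' its subjects.
#'
#' @return Integer vector of patient ids.
#' @export
substudy_selection <- function() c(3L, 9L, 21L, 28L, 1L, 5L, 6L, 14L, 16L, 17L)

#' Standard- versus patient-specific organ-size sensitivity
#'
#' For each kidney with complete geometry, a noiseless synthetic imaging
#' series is built from the patient's true geometry and quantified twice:
#' once with the patient-specific thicknesses and mass, and once with the
#' sex-specific standard organ sizes ([standard_geometry()]) substituted
#' in both the conjugate-view formula and the dose equation. The reported
#' ratio `D_standard / D_specific` shows how the standard-size shortcut
#' scales the dose: dominated by the inverse-mass term, modulated by the
#' body- and kidney-thickness attenuation corrections.
#'
#' @param geometries `data.frame` with columns `patient`, `kidney`,
#'   `sex` (`"M"`/`"F"` or `"male"`/`"female"`), `kidney_thickness_cm`,
#'   `mass_kg`, `trunk_cm`; e.g. a subset of [load_cohort_table()] rows.
#' @param camera A [camera_model()] used for the simulation.
#' @return The input frame plus columns `ratio` (D_standard /
#'   D_specific), `d_specific_per_GBq`, `d_standard_per_GBq`.
#' @export
size_sensitivity <- function(geometries,
                             camera = camera_model(10.9, 0.119, 20)) {
  need <- c("patient", "kidney", "sex", "kidney_thickness_cm", "mass_kg",
            "trunk_cm")
  stopifnot(all(need %in% names(geometries)))
  g <- unique(geometries[, need])
  g <- g[stats::complete.cases(g), ]
  if (nrow(g) == 0L) stop("no rows with complete geometry")
  res <- lapply(seq_len(nrow(g)), function(i) {
    row <- g[i, ]
    sex <- if (toupper(substr(row$sex, 1, 1)) == "M") "male" else "female"
    std <- standard_geometry(sex)
    true_a <- (row$trunk_cm - row$kidney_thickness_cm) / 2
    d_spec <- simulate_kidney_dose(row$kidney_thickness_cm, row$trunk_cm,
                                   true_a, row$mass_kg, camera = camera)
    d_std <- simulate_kidney_dose(row$kidney_thickness_cm, row$trunk_cm,
                                  true_a, std$mass_kg,
                                  assumed_x = std$thickness_x,
                                  assumed_T = std$trunk_T,
                                  camera = camera)
    cbind(row, data.frame(d_specific_per_GBq = d_spec$dose_per_GBq,
                          d_standard_per_GBq = d_std$dose_per_GBq,
                          ratio = d_std$dose_per_GBq / d_spec$dose_per_GBq))
  })
  do.call(rbind, res)
}

#' Simulate a cohort for the CV-versus-PA method comparison
#'
#' Synthetic patients with varying body and kidney geometry are imaged
#' with Poisson counting noise and quantified with both methods. The
#' posterior-only method is given an assumed kidney depth that is too
#' shallow by `depth_error_cm` (the kidney actually sits deeper), so its
#' attenuation correction is insufficient and it underestimates by the
#' factor `exp(-mu * depth_error)` on average.
#'
#' @param n Number of kidneys.
#' @param depth_error_cm True depth minus assumed depth, cm; >= 0.
#' @param seed Integer seed.
#' @param camera A [camera_model()].
#' @return A `data.frame` with columns `cv_per_GBq`, `pa_per_GBq`.
#' @export
simulate_cv_pa_cohort <- function(n = 16, depth_error_cm = 1.5, seed = 1L,
                                  camera = camera_model(10.9, 0.119, 20)) {
  stopifnot(n >= 3, depth_error_cm >= 0)
  set.seed(as.integer(seed))
  params <- data.frame(
    x = stats::runif(n, 4.5, 6.8),
    T = stats::runif(n, 18, 26),
    A0 = stats::rlnorm(n, log(220), 0.25),
    Tb = stats::rlnorm(n, log(70), 0.3))
  params$a_true <- pmin(stats::runif(n, 3.5, 6.5),
                        (params$T - params$x) / 2 + 2)
  rows <- lapply(seq_len(n), function(i) {
    p <- params[i, ]
    mass <- ellipsoid_mass(1.75 * p$x, 0.75 * p$x, p$x)
    kin <- monoexp_kinetics(p$A0, log(2) / p$Tb)
    cv <- simulate_kidney_dose(p$x, p$T, p$a_true, mass, kin = kin,
                               camera = camera, method = "CV",
                               seed = seed + 37L * i)
    pa <- simulate_kidney_dose(p$x, p$T, p$a_true, mass, kin = kin,
                               assumed_a = max(0, p$a_true - depth_error_cm),
                               camera = camera, method = "PA",
                               seed = seed + 37L * i)
    data.frame(cv_per_GBq = cv$dose_per_GBq, pa_per_GBq = pa$dose_per_GBq)
  })
  do.call(rbind, rows)
}
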