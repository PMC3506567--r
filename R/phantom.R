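#' Gamma-camera model
#'
#' Describes the imaging system used by the forward projector: planar
#' sensitivity `sensitivity_k` (count rate per unit unattenuated activity),
#' effective linear attenuation coefficient `mu` (broad-beam, absorbing
#' both absorption and scatter for the energy window in use), and the
#' effective per-pixel dwell time used to convert count rates to counts.
#' Whole-body scans are modelled as static images with this effective
#' dwell time.
#'
#' @param sensitivity_k Sensitivity in cps/MBq; must be > 0.
#' @param mu Effective linear attenuation coefficient in cm^-1; must be >= 0.
#' @param dwell_time Effective acquisition time per pixel in seconds; > 0.
#' @return An object of class `camera_model`.
#' @examples
#' camera_model(sensitivity_k = 10.9, mu = 0.119, dwell_time = 60)
#' @export
camera_model <- function(sensitivity_k, mu, dwell_time) {
  stopifnot(is.numeric(sensitivity_k), length(sensitivity_k) == 1L,
            sensitivity_k > 0,
            is.numeric(mu), length(mu) == 1L, mu >= 0,
            is.numeric(dwell_time), length(dwell_time) == 1L, dwell_time > 0)
  structure(list(sensitivity_k = sensitivity_k, mu = mu,
                 dwell_time = dwell_time),
            class = "camera_model")
}

#' Uptake compartment of the slab phantom
#'
#' A source region embedded in the slab body: a pixel footprint in the
#' image plane plus an anterior-posterior (AP) extent. `depth_a` is the
#' distance from the back of the body (posterior surface) to the posterior
#' edge of the region, i.e. the depth the posterior-only quantification
#' method must know. For a `box` region every footprint pixel carries the
#' full AP chord `thickness_x`; for an `ellipsoid` the chord varies over
#' the footprint (see [ellipsoid_region()]).
#'
#' @param label Region name used in error messages and bookkeeping.
#' @param footprint Two-column integer matrix of (row, col) pixel
#'   coordinates, 0-based.
#' @param thickness_x AP extent in cm (maximum chord for ellipsoids); > 0.
#' @param depth_a Posterior depth of the region's posterior edge in cm; >= 0.
#' @param activity Total activity in MBq, distributed uniformly in the
#'   region volume; >= 0.
#' @param shape `"box"` or `"ellipsoid"`.
#' @param chords Optional numeric vector of per-pixel AP chords (cm), one
#'   per footprint row; computed automatically by the shape helpers.
#' @return An object of class `source_region`.
#' @seealso [box_region()], [ellipsoid_region()]
#' @export
source_region <- function(label, footprint, thickness_x, depth_a, activity,
                          shape = c("box", "ellipsoid"), chords = NULL) {
  shape <- match.arg(shape)
  footprint <- as.matrix(footprint)
  stopifnot(ncol(footprint) == 2L, nrow(footprint) >= 1L,
            all(footprint >= 0L),
            is.numeric(thickness_x), thickness_x > 0,
            is.numeric(depth_a), depth_a >= 0,
            is.numeric(activity), activity >= 0)
  if (is.null(chords)) {
    chords <- rep(thickness_x, nrow(footprint))
  }
  stopifnot(length(chords) == nrow(footprint), all(chords >= 0),
            max(chords) <= thickness_x + 1e-9)
  structure(list(label = as.character(label), footprint = footprint,
                 shape = shape, thickness_x = thickness_x,
                 depth_a = depth_a, activity = activity, chords = chords),
            class = "source_region")
}

#' @rdname source_region
#' @param row0,row1,col0,col1 Inclusive 0-based pixel bounds of a
#'   rectangular footprint.
#' @export
box_region <- function(label, row0, row1, col0, col1, thickness_x, depth_a,
                       activity) {
  fp <- as.matrix(expand.grid(row = row0:row1, col = col0:col1))
  source_region(label, fp, thickness_x, depth_a, activity, shape = "box")
}

#' @rdname source_region
#' @param center_row,center_col Ellipsoid centre in pixel units (may be
#'   fractional).
#' @param semi_row,semi_col In-plane semi-axes in pixel units.
#' @details Ellipsoid chords are evaluated analytically at each pixel
#'   centre: the AP chord at in-plane offset (u, v) from the centre is
#'   `thickness_x * sqrt(1 - u^2 - v^2)` with u, v normalised by the
#'   semi-axes; pixels whose centre falls outside the ellipse are not part
#'   of the footprint.
#' @export
ellipsoid_region <- function(label, center_row, center_col, semi_row,
                             semi_col, thickness_x, depth_a, activity) {
  stopifnot(semi_row > 0, semi_col > 0)
  rows <- floor(center_row - semi_row):ceiling(center_row + semi_row)
  cols <- floor(center_col - semi_col):ceiling(center_col + semi_col)
  g <- expand.grid(row = rows, col = cols)
  q <- ((g$row - center_row) / semi_row)^2 + ((g$col - center_col) / semi_col)^2
  keep <- q < 1
  if (!any(keep)) stop("ellipsoid footprint is empty: ", label)
  fp <- as.matrix(g[keep, , drop = FALSE])
  chords <- thickness_x * sqrt(1 - q[keep])
  source_region(label, fp, thickness_x, depth_a, activity,
                shape = "ellipsoid", chords = chords)
}

#' Slab-body phantom specification
#'
#' The digital phantom is a homogeneous slab of AP thickness
#' `trunk_thickness_T` (the body thickness at kidney level) containing any
#' number of uptake compartments. Every compartment must fit inside the
#' slab: `depth_a >= 0` and `depth_a + thickness_x <= trunk_thickness_T`.
#'
#' @param trunk_thickness_T AP body thickness in cm; > 0.
#' @param pixel_size Pixel side length in cm; > 0.
#' @param grid_rows,grid_cols Image matrix dimensions.
#' @param compartments List of [source_region()] objects.
#' @param camera A [camera_model()].
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(trunk_thickness_T, pixel_size, grid_rows, grid_cols,
                         compartments, camera) {
  stopifnot(trunk_thickness_T > 0, pixel_size > 0,
            grid_rows >= 1, grid_cols >= 1,
            is.list(compartments),
            inherits(camera, "camera_model"))
  for (comp in compartments) {
    stopifnot(inherits(comp, "source_region"))
    if (comp$depth_a < 0 ||
        comp$depth_a + comp$thickness_x > trunk_thickness_T + 1e-9) {
      stop("compartment '", comp$label, "' does not fit inside the slab: ",
           "depth_a + thickness_x = ", comp$depth_a + comp$thickness_x,
           " cm exceeds trunk thickness ", trunk_thickness_T, " cm")
    }
    if (any(comp$footprint[, 1] >= grid_rows) ||
        any(comp$footprint[, 2] >= grid_cols)) {
      stop("compartment '", comp$label, "' footprint outside the image grid")
    }
  }
  structure(list(trunk_thickness_T = trunk_thickness_T,
                 pixel_size = pixel_size,
                 grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols),
                 compartments = compartments, camera = camera),
            class = "phantom_spec")
}

new_rate_image <- function(pixels, view, time_h, pixel_size, dwell_time) {
  structure(list(pixels = pixels, view = view, time_h = time_h,
                 pixel_size = pixel_size, dwell_time = dwell_time),
            class = "rate_image")
}

new_count_image <- function(pixels, view, time_h, pixel_size, dwell_time) {
  structure(list(pixels = pixels, view = view, time_h = time_h,
                 pixel_size = pixel_size, dwell_time = dwell_time),
            class = "count_image")
}

#' Forward-project the phantom into a planar count-rate image
#'
#' Analytic line-integral projection through the attenuating slab. For a
#' pixel covered by a compartment with volumetric activity concentration
#' rho (MBq/cm^3), AP chord x_pix and near-edge depth d (measured from the
#' detector-side surface), the detected rate is
#' `k * rho * (exp(-mu*d) - exp(-mu*(d + x_pix))) / mu * pixel_area`,
#' the closed form of the attenuated integral over the chord (`mu = 0`
#' reduces to the unattenuated limit). In the posterior view the near-edge
#' depth is `depth_a`; in the anterior view it is
#' `T - depth_a - x_pix`. Contributions are additive across compartments.
#' Anterior images are left-right mirrored relative to posterior images,
#' as when a patient is imaged from both sides.
#'
#' @param spec A [phantom_spec()].
#' @param view `"anterior"` or `"posterior"`.
#' @param time_h Acquisition time post-administration recorded in the
#'   image metadata (does not affect the projection).
#' @return A `rate_image` whose `pixels` matrix is in cps.
#' @export
build_projection <- function(spec, view = c("posterior", "anterior"),
                             time_h = NA_real_) {
  view <- match.arg(view)
  stopifnot(inherits(spec, "phantom_spec"))
  cam <- spec$camera
  px_area <- spec$pixel_size^2
  img <- matrix(0, spec$grid_rows, spec$grid_cols)
  for (comp in spec$compartments) {
    if (comp$activity == 0) next
    chords <- comp$chords
    vol <- sum(chords) * px_area
    if (vol <= 0) next
    rho <- comp$activity / vol
    d_near <- if (view == "posterior") {
      rep(comp$depth_a, length(chords))
    } else {
      spec$trunk_thickness_T - comp$depth_a - chords
    }
    if (cam$mu > 0) {
      rate <- cam$sensitivity_k * rho * px_area *
        (exp(-cam$mu * d_near) - exp(-cam$mu * (d_near + chords))) / cam$mu
    } else {
      rate <- cam$sensitivity_k * rho * px_area * chords
    }
    idx <- comp$footprint[, 1] + 1L +
      comp$footprint[, 2] * spec$grid_rows
    img[idx] <- img[idx] + rate
  }
  if (view == "anterior") img <- img[, ncol(img):1, drop = FALSE]
  new_rate_image(img, view, time_h, spec$pixel_size, cam$dwell_time)
}

#' Draw Poisson counting noise on a rate image
#'
#' Each pixel is an independent Poisson draw with mean
#' `rate * dwell_time`. The same seed always reproduces the same image.
#'
#' @param rate A `rate_image`.
#' @param seed Integer random seed.
#' @return A `count_image` of integer counts.
#' @export
sample_counts <- function(rate, seed) {
  stopifnot(inherits(rate, "rate_image"), rate$dwell_time > 0)
  if (any(rate$pixels < 0)) stop("negative rates cannot be Poisson-sampled")
  set.seed(as.integer(seed))
  counts <- matrix(stats::rpois(length(rate$pixels),
                                lambda = rate$pixels * rate$dwell_time),
                   nrow(rate$pixels), ncol(rate$pixels))
  new_count_image(counts, rate$view, rate$time_h, rate$pixel_size,
                  rate$dwell_time)
}

#' Simulate a camera calibration depth series
#'
#' Emulates the calibration measurement: a small source of known activity
#' imaged at a set of depths in an attenuating phantom, each acquisition
#' lasting `duration` seconds. Noiseless counts at depth d are
#' `k * A * exp(-mu * d) * duration`; the noisy variant Poisson-samples
#' each acquisition.
#'
#' @param camera A [camera_model()] (its `dwell_time` is not used here).
#' @param depths Source depths in cm; all > 0.
#' @param source_activity Source activity in MBq; > 0.
#' @param duration Acquisition time per depth in seconds.
#' @param seed Integer seed for the Poisson draws, or `NULL` for the
#'   noiseless series.
#' @return A `data.frame` with columns `depth_cm`, `counts`, `duration_s`.
#' @export
make_calibration_series <- function(camera, depths, source_activity,
                                    duration = 300, seed = NULL) {
  stopifnot(inherits(camera, "camera_model"),
            length(depths) >= 1L, all(depths > 0),
            source_activity > 0, duration > 0)
  mean_counts <- camera$sensitivity_k * source_activity *
    exp(-camera$mu * depths) * duration
  counts <- if (is.null(seed)) {
    mean_counts
  } else {
    set.seed(as.integer(seed))
    stats::rpois(length(depths), mean_counts)
  }
  data.frame(depth_cm = depths, counts = counts, duration_s = duration)
}

#' Kidney retention models for the simulator
#'
#' Decay-corrected retention as a function of time post-administration.
#' `monoexp_kinetics` is `A0 * exp(-lambda_bio * t)`; `biphasic_kinetics`
#' is `A0 * (exp(-lambda_clear * t) - exp(-lambda_uptake * t))`, which
#' rises from zero and peaks at `log(lambda_uptake / lambda_clear) /
#' (lambda_uptake - lambda_clear)` — the "slow uptake" pattern in which
#' organ activity is maximal on day 1 or 2 rather than at the first scan.
#'
#' @param A0 Amplitude in MBq; > 0.
#' @param lambda_bio,lambda_clear,lambda_uptake Rate constants in h^-1;
#'   `lambda_uptake > lambda_clear > 0` for the biphasic form.
#' @return A kinetics object usable in [make_patient_series()].
#' @export
monoexp_kinetics <- function(A0, lambda_bio) {
  stopifnot(A0 > 0)
  structure(list(model = "monoexp", A0 = A0, lambda_bio = lambda_bio),
            class = "kinetics_model")
}

#' @rdname monoexp_kinetics
#' @export
biphasic_kinetics <- function(A0, lambda_clear, lambda_uptake) {
  stopifnot(A0 > 0, lambda_clear > 0, lambda_uptake > lambda_clear)
  structure(list(model = "biphasic", A0 = A0, lambda_clear = lambda_clear,
                 lambda_uptake = lambda_uptake),
            class = "kinetics_model")
}

#' @rdname monoexp_kinetics
#' @param kin A kinetics object.
#' @param t Time in hours post-administration.
#' @return `kinetic_activity()`: decay-corrected activity in MBq at `t`.
#' @export
kinetic_activity <- function(kin, t) {
  stopifnot(inherits(kin, "kinetics_model"))
  switch(kin$model,
         monoexp = kin$A0 * exp(-kin$lambda_bio * t),
         biphasic = kin$A0 * (exp(-kin$lambda_clear * t) -
                                exp(-kin$lambda_uptake * t)))
}

#' Simulate a multi-time-point patient imaging series
#'
#' For each requested time the compartment activities are set to the
#' kinetic model value times the physical decay factor `exp(-lambda_phys
#' * t)` (the camera sees non-decay-corrected activity), the phantom is
#' forward-projected in both views, and Poisson noise is added unless
#' `noiseless = TRUE`.
#'
#' @param spec A [phantom_spec()]; compartment activities in `spec` are
#'   ignored in favour of the kinetic models.
#' @param kinetics Named list mapping compartment labels to kinetics
#'   objects (see [monoexp_kinetics()]). Compartments without an entry
#'   keep zero activity.
#' @param times_h Strictly increasing imaging times in hours; >= 2 points.
#' @param seed Integer seed; each time point uses a distinct derived seed.
#' @param lambda_phys Physical decay constant in h^-1.
#' @param noiseless If `TRUE`, return rate images without Poisson noise.
#' @return A list with one element per time:
#'   `list(anterior =, posterior =, time_h =)`.
#' @export
make_patient_series <- function(spec, kinetics, times_h, seed = 1L,
                                lambda_phys = lu177_lambda_phys(),
                                noiseless = FALSE) {
  stopifnot(inherits(spec, "phantom_spec"),
            length(times_h) >= 2L, all(diff(times_h) > 0),
            is.list(kinetics), !is.null(names(kinetics)))
  labels <- vapply(spec$compartments, `[[`, "", "label")
  unknown <- setdiff(names(kinetics), labels)
  if (length(unknown))
    stop("kinetics given for unknown compartment(s): ",
         paste(unknown, collapse = ", "))
  out <- vector("list", length(times_h))
  for (i in seq_along(times_h)) {
    t <- times_h[i]
    comps <- lapply(spec$compartments, function(comp) {
      kin <- kinetics[[comp$label]]
      comp$activity <- if (is.null(kin)) 0 else
        kinetic_activity(kin, t) * exp(-lambda_phys * t)
      comp
    })
    spec_t <- spec
    spec_t$compartments <- comps
    ant <- build_projection(spec_t, "anterior", time_h = t)
    post <- build_projection(spec_t, "posterior", time_h = t)
    if (!noiseless) {
      ant <- sample_counts(ant, seed + 2L * i)
      post <- sample_counts(post, seed + 2L * i + 1L)
    }
    out[[i]] <- list(anterior = ant, posterior = post, time_h = t)
  }
  out
}
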