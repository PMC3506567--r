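#' Dosimetric constants
#'
#' @param energy_per_decay_keV Mean energy emitted by electrons per
#'   decay; 147 keV for Lu-177.
#' @param absorbed_fraction Fraction of the emitted electron energy
#'   absorbed in the source organ; taken as 1 for Lu-177 electrons in
#'   kidney.
#' @param lambda_phys Physical decay constant, h^-1.
#' @param s_value_wb_to_kidney Whole-body-to-kidney S value in
#'   mGy/(MBq h), required only for the remainder-of-body dose; no
#'   default is shipped.
#' @return An object of class `dose_constants`.
#' @export
dose_constants <- function(energy_per_decay_keV = 147,
                           absorbed_fraction = 1,
                           lambda_phys = lu177_lambda_phys(),
                           s_value_wb_to_kidney = NULL) {
  stopifnot(energy_per_decay_keV > 0,
            absorbed_fraction > 0, absorbed_fraction <= 1,
            lambda_phys > 0)
  structure(list(energy_per_decay_keV = energy_per_decay_keV,
                 absorbed_fraction = absorbed_fraction,
                 lambda_phys = lambda_phys,
                 s_value_wb_to_kidney = s_value_wb_to_kidney),
            class = "dose_constants")
}

#' Kidney mass from an ellipsoid approximation
#'
#' The kidney volume is approximated by an ellipsoid with axes equal to
#' the measured length, width, and AP thickness; the mass assumes soft-
#' tissue density (1.05 g/cm^3 by default).
#'
#' @param length_L,width_W,thickness_x Ellipsoid axes (full lengths), cm.
#' @param density Tissue density, g/cm^3.
#' @return Mass in kg.
#' @export
ellipsoid_mass <- function(length_L, width_W, thickness_x, density = 1.05) {
  stopifnot(length_L > 0, width_W > 0, thickness_x > 0, density > 0)
  (pi / 6) * length_L * width_W * thickness_x * density / 1000
}

#' Mean absorbed dose to the kidney
#'
#' MIRD-style self-dose for a locally absorbed emitter:
#' \deqn{\bar D = \tilde A \, nE \, \phi / m,}
#' with the cumulated activity in decays, `nE` the mean electron energy
#' per decay and `phi` the absorbed fraction. An unbounded cumulated
#' activity propagates as an unbounded dose flag.
#'
#' @param a_tilde A [cumulated_activity()] result.
#' @param mass_kg Kidney mass, kg; > 0.
#' @param constants A [dose_constants()].
#' @param administered_GBq Administered activity; when supplied the dose
#'   per administered activity (Gy/GBq) is reported as well.
#' @return An object of class `dose_result` with fields `dose_Gy`,
#'   `dose_per_GBq`, `mass_kg`, `bounded`.
#' @export
mean_dose <- function(a_tilde, mass_kg, constants = dose_constants(),
                      administered_GBq = NULL) {
  stopifnot(inherits(a_tilde, "cumulated_activity"),
            inherits(constants, "dose_constants"))
  if (mass_kg <= 0) stop("kidney mass must be positive")
  if (!a_tilde$bounded) {
    return(structure(list(dose_Gy = NA_real_, dose_per_GBq = NA_real_,
                          mass_kg = mass_kg, bounded = FALSE),
                     class = "dose_result"))
  }
  nE_J <- constants$energy_per_decay_keV * kev_to_joule()
  D <- a_tilde$decays * nE_J * constants$absorbed_fraction / mass_kg
  per_admin <- if (is.null(administered_GBq)) NA_real_ else
    D / administered_GBq
  structure(list(dose_Gy = D, dose_per_GBq = per_admin,
                 mass_kg = mass_kg, bounded = TRUE),
            class = "dose_result")
}

#' Remainder-of-body contribution to kidney dose
#'
#' The activity in the rest of the body (whole-body cumulated activity
#' minus the renal cumulated activity, assumed uniformly distributed)
#' irradiates the kidneys with a whole-body-to-kidney S value.
#'
#' @param a_tilde_wb_MBqh Whole-body cumulated activity, MBq h.
#' @param a_tilde_kidneys_MBqh Renal cumulated activity, MBq h; must not
#'   exceed the whole-body value.
#' @param s_value_mGy_per_MBqh Whole-body-to-kidney S value.
#' @return Dose in Gy.
#' @export
remainder_dose <- function(a_tilde_wb_MBqh, a_tilde_kidneys_MBqh,
                           s_value_mGy_per_MBqh) {
  stopifnot(s_value_mGy_per_MBqh >= 0)
  if (a_tilde_wb_MBqh < a_tilde_kidneys_MBqh)
    stop("whole-body cumulated activity is smaller than the renal one")
  (a_tilde_wb_MBqh - a_tilde_kidneys_MBqh) * s_value_mGy_per_MBqh / 1000
}

#' Standard organ-size parameter set
#'
#' ICRP 89 reference kidney masses (310 g for men, 275 g for women, both
#' kidneys together — halved here because quantification and dose are
#' per kidney) with reference body and kidney AP thicknesses adapted
#' from the MIRD anthropomorphic phantom: 20 cm trunk / 6 cm kidney for
#' men, 18 cm / 5 cm for women.
#'
#' @param sex `"male"` or `"female"`.
#' @return A list of class `geometry_record` with `mass_kg` (per
#'   kidney), `trunk_T` (cm), `thickness_x` (cm), `sex`.
#' @export
standard_geometry <- function(sex = c("male", "female")) {
  sex <- match.arg(sex)
  if (sex == "male") {
    g <- list(mass_kg = 0.310 / 2, trunk_T = 20, thickness_x = 6)
  } else {
    g <- list(mass_kg = 0.275 / 2, trunk_T = 18, thickness_x = 5)
  }
  structure(c(g, list(sex = sex)), class = "geometry_record")
}

#' Patient-specific kidney geometry
#'
#' @param thickness_x Kidney AP thickness, cm.
#' @param trunk_T Body AP thickness at kidney level, cm.
#' @param mass_kg Kidney mass, kg.
#' @param depth_a Posterior kidney depth, cm (needed only for the
#'   posterior-only method).
#' @param sex Optional, for pairing with [standard_geometry()].
#' @return A list of class `geometry_record`.
#' @export
geometry_record <- function(thickness_x, trunk_T, mass_kg,
                            depth_a = NA_real_, sex = NA_character_) {
  stopifnot(thickness_x > 0, trunk_T > 0, mass_kg > 0,
            thickness_x <= trunk_T)
  structure(list(mass_kg = mass_kg, trunk_T = trunk_T,
                 thickness_x = thickness_x, depth_a = depth_a, sex = sex),
            class = "geometry_record")
}
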