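#' Physical constants for Lu-177 dosimetry
#'
#' Helpers returning the physical constants used throughout the package.
#' The Lu-177 physical half-life defaults to 6.647 days; all decay
#' constants are expressed per hour because imaging times are in hours
#' post-administration.
#'
#' @param half_life_days Physical half-life in days.
#' @return `lu177_lambda_phys()`: the physical decay constant in h^-1.
#' @export
lu177_lambda_phys <- function(half_life_days = 6.647) {
  stopifnot(half_life_days > 0)
  log(2) / (half_life_days * 24)
}

#' @rdname lu177_lambda_phys
#' @return `kev_to_joule()`: one kilo-electronvolt in joules.
#' @export
kev_to_joule <- function() 1.602177e-19 * 1e3

# MBq.h -> number of decays
MBQH_TO_DECAYS <- 3.6e9
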