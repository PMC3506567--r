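# Shared builders for the test suite. The default camera uses the
# constants of a medium-energy collimator system for Lu-177 imaging:
# k = 10.9 cps/MBq, mu = 0.119 cm^-1.

default_camera <- function(dwell = 20) camera_model(10.9, 0.119, dwell)

default_calib <- function() calibration_result(10.9, 0.119)

# single box kidney centred in a 24x20 slab phantom
box_phantom <- function(activity = 100, x = 6, a = 4, trunk = 20,
                        camera = default_camera(), pixel = 0.5) {
  kid <- box_region("kidney", 5, 14, 5, 10, thickness_x = x, depth_a = a,
                    activity = activity)
  phantom_spec(trunk, pixel, 24, 20, list(kid), camera)
}

kidney_roi <- function(spec) roi_from_region(spec$compartments[[1]])

# independent closed-form oracle: total detected rate from a uniform box
# source (activity A, thickness x, near-edge depth d) seen through mu
slab_rate_oracle <- function(k, A, mu, d, x) {
  if (mu == 0) return(k * A)
  k * A * exp(-mu * d) * (1 - exp(-mu * x)) / (mu * x)
}
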