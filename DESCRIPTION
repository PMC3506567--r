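Package: planardose
Title: Kidney Dosimetry from Planar Scintigraphy for Lu-177 Radionuclide Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Activity quantification and absorbed-dose estimation for the
    kidneys from anterior/posterior planar gamma-camera images, as used in
    Lu-177-octreotate peptide receptor radionuclide therapy. Implements
    gamma-camera calibration (sensitivity and effective linear attenuation
    coefficient from a depth-count series), the conjugate-view and
    posterior-only activity quantification methods with thickness-scaled
    background subtraction and partial-ROI extrapolation, mono-exponential
    time-activity fitting with cumulated activity, and MIRD-style mean
    absorbed dose with ellipsoid kidney masses or ICRP 89 standard organ
    sizes. A forward-projecting slab-body phantom with Poisson counting
    noise supports method-comparison studies: reduced imaging time points,
    standard versus patient-specific organ sizes, and conjugate-view versus
    posterior-only quantification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
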