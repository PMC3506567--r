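---
title: "Planar kidney dosimetry: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planar kidney dosimetry: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(planardose)
```

## The problem

After an administration of ¹⁷⁷Lu-octreotate, the absorbed dose to the
kidneys must be tracked because renal toxicity limits how many treatment
cycles a patient can receive. The clinical measurement is planar
scintigraphy: anterior and posterior whole-body images at roughly 1 h,
1 d, 2 d and 7 d after infusion. `planardose` implements the chain
from those images to a mean kidney dose, together with a digital phantom
that makes every step testable against exact ground truth.

## Activity quantification

A gamma camera detects a source of activity $A$ at depth $d$ in tissue
with count rate $k A e^{-\mu d}$, where $k$ (cps/MBq) is the planar
sensitivity and $\mu$ (cm⁻¹) an *effective* linear attenuation
coefficient that absorbs both photoelectric absorption and the scatter
accepted by the energy window. Both constants are measured by imaging a
known source at several depths in an attenuating phantom and fitting the
exponential (`fit_depth_series()`). Because the model is exactly
linearisable we fit unweighted least squares of log-rate on depth —
calibration counts are large, so the homoscedasticity error from the log
transform is negligible, and the intercept directly gives the
"extrapolated zero-depth" sensitivity. Whether one fits weighted,
unweighted, in log or linear domain changes the noiseless answer not at
all (the recovery is exact) and the noisy answer by far less than the 2%
recovery spread we verify.

An organ is not a point source. For a uniform slab of thickness $x$
whose near edge sits at depth $d$, integrating the exponential over the
slab gives the detected rate

$$R = k A\, e^{-\mu d}\,\frac{1 - e^{-\mu x}}{\mu x}.$$

Writing this for the posterior view (near-edge depth $a$) and the
anterior view (near-edge depth $T - a - x$, with $T$ the body thickness)
and eliminating the unknown $a$ via the geometric mean yields the
conjugate-view estimator implemented in `activity_cv()`:

$$A = \frac{\sqrt{R_A R_P}\; e^{\mu T/2}\; \mu x}
           {k \left(e^{\mu x/2} - e^{-\mu x/2}\right)}.$$

Its defining property — which the test suite asserts to $10^{-6}$
relative error and the phantom makes exact — is that the kidney's
anterior–posterior position drops out. The posterior-only estimator
(`activity_pa()`)

$$A = \frac{R_P\; e^{\mu a}\; \mu x}{k\,(1 - e^{-\mu x})}$$

is equally exact *if* $a$ is known, and biased by exactly $e^{\mu\,
\Delta a}$ when the assumed depth is wrong by $\Delta a$ — at $\mu
\approx 0.119$ cm⁻¹, about 12% per centimetre. That sensitivity, plus
the difficulty of defining one depth for a tilted kidney, is why the
conjugate view is the reference method. Exponent-sign conventions in
both estimators are fixed by requiring that each one exactly inverts the
noiseless forward projection of a box source; with any other sign choice
the round trip fails, so the resolution is forced rather than assumed.

Both formulas evaluate their thickness factor in the limit form 1 as
$\mu x \to 0$ (series cutoff at $\mu x < 10^{-12}$), so point-like
sources are handled without 0/0.

### ROI handling

Kidney ROIs are drawn on the posterior image and mirrored column-wise
for the anterior image (`mirror_roi()`, an involution). When
overlapping uptake (liver, spleen, intestine, tumour) obscures part of a
kidney, a partial ROI over the clean part is scaled to the full kidney
pixel count assuming uniform counts per pixel
(`extrapolate_partial()`); on a uniform source this is exact, and under
Poisson noise it is unbiased in expectation. Background is corrected by
subtracting the mean background-ROI rate per pixel scaled by
$(T - x)/T$ — the fraction of the body column at the kidney position
that is not kidney, assuming homogeneous background concentration
(`background_correct()`). A negative corrected rate is clamped to zero
and flagged; the alternative (propagating negative rates) would make the
geometric mean undefined. The background ROI itself is user-supplied:
no automatic placement rule is imposed, because placement is a manual,
image-specific step.

## Kinetics and cumulated activity

Measured activities are corrected for physical decay
(`decay_correct()`, ¹⁷⁷Lu half-life 6.647 d by default, configurable)
and fitted with $A(t) = A_0 e^{-\lambda_{bio} t}$ by nonlinear least
squares *on the linear scale*, initialised from a log-linear regression
(`fit_monoexp()`). Linear-scale fitting is deliberate: a log-domain fit
would over-weight the small, late activities, whereas the dose integral
is dominated by the early, large ones. With two points the log-linear
solution is already exact and is used directly; the Levenberg–Marquardt
refinement runs for three or more points and falls back to the
initialiser if it fails to converge. $R^2$ is reported on the linear
scale; for a constant series (zero total variance fitted perfectly) it
is defined as 1.

Because fitting happens on decay-corrected data but the camera sees
physical decay, the effective decay constant is
$\lambda_{eff} = \lambda_{bio} + \lambda_{phys}$, and the cumulated
activity is

$$\tilde A = \int_0^\infty A_0 e^{-\lambda_{eff} t}\,dt
           = A_0 / \lambda_{eff}$$

(`cumulated_activity()`), the only reading under which the integral is
dimensionally and physically consistent with decay-corrected fitting.
The infusion period (~30 min) is ignored: $t = 0$ is infusion onset. A
series that still rises near the end of observation can yield
$\lambda_{bio} < 0$; when $\lambda_{eff} \le 0$ the integral diverges.
Such fits are *flagged*, not errors — they propagate as unbounded
cumulated activities and doses so cohort-level code can count and
exclude them, which is how they must be handled in practice.

## Dose

The mean absorbed kidney dose is $\bar D = \tilde A\, nE\, \phi / m$
(`mean_dose()`), with $nE = 147$ keV per decay for ¹⁷⁷Lu electrons
(1 keV = 1.602177 × 10⁻¹⁹ J, fixed), absorbed fraction $\phi = 1$
(electron ranges are small against kidney dimensions), and the kidney
mass $m$ from an ellipsoid approximation of CT-measured axes at
1.05 g/cm³ (`ellipsoid_mass()`). The standard-size variant
(`standard_geometry()`) uses ICRP 89 reference kidney masses — 310 g
(men) and 275 g (women) for *both* kidneys, halved here because
quantification and dose are per kidney — with 20 cm/6 cm (men) and
18 cm/5 cm (women) trunk/kidney thicknesses from the MIRD
anthropomorphic phantom. Photon cross-fire from the rest of the body is
a small additive term computed from the extra-renal cumulated activity
and a whole-body-to-kidney S value (`remainder_dose()`); no S value is
shipped because it is system- and phantom-set-specific, so it is a
required input.

## The digital phantom

`phantom_spec()` describes a homogeneous attenuating slab of thickness
$T$ containing uptake compartments: boxes (constant AP chord) or
ellipsoids (analytic per-pixel-centre chords, no sub-pixel
integration). `build_projection()` computes the attenuated line
integral per pixel in closed form; `sample_counts()` adds Poisson noise
with a per-pixel dwell time. Whole-body scanning is modelled as a
static acquisition with an effective dwell time — a convention, chosen
so that quantification operates in count-rate units matching $k$ in
cps/MBq. Chords of non-box regions are placed flush against the
region's posterior plane at `depth_a`; box kidneys, for which this
choice is irrelevant, are the geometry used by every exactness oracle.
The phantom deliberately omits collimator blur, septal penetration and
explicit scatter (scatter lives inside the effective $\mu$, as in the
calibration measurement itself). Passing tests on this phantom
therefore demonstrate correctness of the estimators under their own
geometric assumptions — not robustness to PSF blur, heterogeneous
attenuation, or mis-drawn ROIs on real images.

## Synthetic cohorts and study conditions

The cohort-level studies run on generated data with these frozen
conditions:

* **Time–activity cohorts** (`make_kinetic_cohort()`, n = 200 at 1 h /
  1 d / 2 d / 7 d): 21/33 of series mono-exponential from the first
  time point and 12/33 with a day 1–2 observed maximum, the proportion
  seen clinically. Clearance half-times are log-normal (median 80 h,
  sdlog 0.35), giving effective half-lives around two days; the
  slow-uptake pattern uses a biphasic form with uptake half-times of
  0.7–4 h, so the 1-h activity is already a substantial fraction of the
  peak — tracer delivery to the kidneys is fast, and the observed
  day 1–2 maximum is a mild rise, not growth from zero. Amplitudes are
  log-normal around 250 MBq (a few percent of an administered 7.4 GBq).
  Within-series noise is multiplicative log-normal with CV 5%: the
  component of planar quantification error that varies between the time
  points of one series (counting statistics, background-ROI variation).
  The larger systematic errors (calibration, organ geometry, ROI
  definition) are common to all points of a series and cancel in the
  fitted shape, so they do not belong in this noise term.
* **Reduced-time-point study** (`omit_timepoint_study()`): refits each
  series four times, each with one time point removed. Removing day 7
  leaves a 47-hour observation window from which the fit must
  extrapolate to infinity: slow-uptake series frequently refit with
  $\lambda_{eff} \le 0$ (counted, excluded) and many of the rest
  extrapolate badly, which is why this omission shows both the largest
  mean |dose ratio − 1| and the only substantial unbounded count — and
  why the reported mean ratio is an *underestimate*, since the worst
  refits are the excluded infinite ones.
* **CV vs PA comparison** (`simulate_cv_pa_cohort()`, 16 kidneys,
  Poisson noise): the PA method is given a depth 1.5 cm too shallow,
  a plausible error given kidney tilt and breathing; its doses fall
  below the CV doses by ≈ $e^{-\mu \cdot 1.5}$ and a paired t-test
  detects the difference.
* **Organ-size study** (`size_sensitivity()` on `substudy_selection()`):
  ten patients of the packaged cohort table (four female, six male)
  spanning the kidney-mass range per sex, including the smallest
  (54 g, 87 g) and largest (234 g, 231 g) kidneys. Each kidney is
  simulated noiselessly from its true geometry and quantified with
  patient-specific versus standard sizes. The ratio
  $D_{std}/D_{specific}$ is dominated by the inverse assumed mass but
  modulated by $e^{\mu (T_{std} - T)/2}$: a borderline-mass kidney
  (0.15–0.21 kg) in a thick trunk (T ≥ 23 cm) can still be
  *under*estimated because the body-thickness term outweighs the mass
  term. The directional pattern — underestimation below 100 g,
  overestimation above 150 g — therefore holds for the selected
  sub-study extremes, not for every conceivable geometry, and the
  package reports per-kidney ratios rather than a single slope.

Problem sizes (200 series, 100 calibration replicates, 16-kidney
comparison cohort, 28 × 24-pixel phantoms) were chosen as the smallest
sizes at which the Monte-Carlo statements above are stable across
seeds.

## Numerical choices and degenerate inputs

* Calibration requires ≥ 3 distinct depths and strictly positive
  counts (log undefined otherwise); a non-negative $\mu$ is enforced by
  clamping at zero, which only binds for depth-independent input.
* Kinetic fitting requires ≥ 2 positive activities; a constant series
  returns $\lambda_{bio} = 0$ exactly.
* `decay_correct()` refuses a series already flagged as corrected, so
  the correction cannot be applied twice.
* Negative background-corrected rates clamp to zero with a flag;
  zero-activity phantoms produce identically zero images and zero
  estimates.
* Count images serialise as 16-bit TIFF (exact to 65 535 counts/pixel);
  rate images as 32-bit float TIFF (single precision); tables as
  delimited text with 6 significant digits. Printed-precision rounding
  is applied only when comparing against published, rounded values.
* All simulation randomness flows through explicit integer seeds; the
  same seed reproduces identical images, tables and files byte for
  byte.

## The packaged cohort table

`inst/extdata/table2_kidney_doses.tsv` is a verbatim transcription of a
published per-patient kidney dose table (33 patients, up to five
cycles, dose per administered activity in Gy/GBq with per-kidney
geometry), including its missing-value markers — `NA` (kidney not
evaluable, overlapping uptake), `ND` (cycle not given), `NP` (organ not
present) — and including one patient whose first three cycle values
duplicate the previous patient's, preserved as printed. Summary
statistics weight every numeric kidney-cycle entry equally (no
per-patient pre-averaging), use the n − 1 standard deviation, and
SEM = SD/√n; this operationalisation reproduces the published overall
and first-cycle statistics at printed precision. Per-cycle deviations
are ratios to the same patient's first-cycle value per kidney side;
sides lacking a first-cycle value are excluded and counted.

## Limitations

* The phantom's geometry is idealised (slab body, homogeneous
  background, no PSF); agreement there bounds algorithmic error only.
* Mono-exponential kinetics cannot represent a true uptake phase; the
  package exposes the consequence (unbounded refits) rather than hiding
  it, but a bi-exponential model is out of scope.
* The background-correction factor assumes the background column at the
  kidney position has thickness $T - x$; organs with non-uniform depth
  distributions violate this.
* No DICOM import, automatic segmentation, SPECT reconstruction, or
  biologically effective dose modelling.
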