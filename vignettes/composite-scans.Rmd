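---
title: "Composite beam-profile reconstruction: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite beam-profile reconstruction: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compscan)
```

## The measurement problem

Commissioning and annual QA of a medical linear accelerator require scanned
dose profiles — relative dose versus off-axis position at fixed depth — for
many field sizes and energies. Water-tank scanning systems produce these at
high resolution but are slow to set up and consume a lot of beam-on time.
Ion-chamber detector arrays are fast but coarse: a typical linear array has
a 0.5 cm detector pitch, too sparse to resolve the penumbra.

`compscan` implements the couch-shift interleaving technique that bridges
the two: the array is exposed repeatedly while the treatment couch is
stepped in sub-pitch increments, each acquisition's readings are mapped
into the fixed radiation-isocenter frame, and the union of all readings
forms a single *composite* profile whose point spacing is the shift
increment. Five exposures at 0.1 cm increments turn a 0.5 cm array into a
0.1 cm scan; at 50 MU per exposure the composite costs 250 MU, roughly a
quarter of what a continuously scanned tank profile of the same field
takes.

Because no public dataset of array readings exists, the package pairs the
reconstruction machinery with an analytic beam model and a virtual array,
so the entire chain is testable at desk scale and every comparison has a
known ground truth.

## Coordinate bookkeeping

Detector `i` of the array sits at `pitch * (i - central_index)` in the
array's own frame (the central detector of the default 65-chamber axis is
index 33; the crossline axis is missing indices 32 and 34 and therefore
carries 63 chambers). Moving the couch by `+s` moves the array — and every
detector — by `-s` relative to the beam axis, so the fixed-frame
coordinate of a detector is its array coordinate minus the couch shift;
at a 90° couch rotation a standard 2D rotation is applied to the shifted
position, exchanging the lateral and longitudinal axes. Only 0° and 90°
are supported: those are the two orientations the protocol uses, and
restricting the domain keeps the transform exactly invertible in tests.

```{r}
to_fixed_frame(c(0, 0), couch_state(x_shift = 0.1))
```

`interleave()` refuses coincident fixed-frame positions (tolerance 1e-6
cm) instead of averaging them: the shift schedule never revisits a
position, so a collision indicates a configuration error, not data to be
merged.

## The analytic beam model

`open_profile()` evaluates

    dose(x) = 100 * [F(x) * H(x) + T(x)] / [F(0) + T(0)]

where `F` is a double-error-function flat top of half-width
`project_field_size(field_width_iso, ssd, depth) / 2` with edge scale
`penumbra_sigma`, `H(x) = 1 + horn_amplitude * (min(|x|, h)/h)^2` models
in-field horns, and `T(x) = tail_fraction * exp(-tail_decay * max(0, |x| - h))`
is a constant in-field scatter floor decaying exponentially outside the
field. The model reproduces the qualitative features a profile comparison
must exercise — flat top, erf penumbra crossing 50% at the geometric edge,
low-dose tails — and every downstream stage treats it as an opaque
function, so nothing depends on this particular functional form.

Wedged fields use `open_profile * exp(-wedge_gradient * x)`, renormalized
to 100 at the central axis. This is a monotone-gradient surrogate for a
dynamic wedge, sufficient to exercise CAX-anchored normalization and the
signed/absolute dose-difference statistics; it does not model jaw-motion
physics.

Shape-parameter defaults are illustrative, not measured: no analytic
penumbra widths exist for specific energies, so 6 MV vs 23 MV are
expressed purely through user-chosen `penumbra_sigma` and tail parameters.
The package defaults (`penumbra_sigma` 0.3 cm at 5 cm depth for a 10 cm
class field, 0.15 cm for the small-field configuration, `tail_fraction`
0.03, `tail_decay` 0.5 /cm) were chosen once as values a physicist would
call plausible for a 6 MV beam and are not calibrated against any
measurement.

## The virtual array

`acquire()` turns the continuous profile into detector readings in three
steps: each reading is the average of the profile over the chamber width
(top-hat kernel, 24-point Gauss–Legendre quadrature, exact to well below
1e-8 for erf-scale profiles and exact for affine profiles); multiplicative
Gaussian noise of relative standard deviation `noise_cov`, truncated at
±5σ, is applied; the result is tagged with the couch state and MU. The
noise default 0.0003 reproduces the 0.03% in-field repeatability COV that
a well-behaved array shows over repeated 50 MU exposures; the Gaussian
family is a modeling choice, since only the COV magnitude is constrained.
The chamber width defaults to 0.4 cm and is deliberately a parameter — it
is the width of the rectangular kernel used for reference matching, and
no authoritative value is hard-coded.

## Gamma analysis

`gamma_profile()` computes the 1D gamma index per reference point: the
minimum over the evaluated profile of
`sqrt(((pos_e - pos_r)/dta)^2 + ((D_e - D_r)/dD)^2)`, with `dD` a
percentage of the reference CAX dose (global mode, the community default
for profile comparison) or of the local reference dose. The evaluated
profile is linearly interpolated onto a dense grid (`interp_step_mm`,
default `dta/50`) and the minimum is taken over grid samples within a
spatial window. The window starts at `3 * dta` and grows automatically
whenever the candidate minimum exceeds the window's own spatial bound
`win/dta` — a point farther than `gamma * dta` cannot beat a candidate
`gamma` — so the windowing is a pure optimization: the result equals the
exhaustive minimum over the whole dense grid, which is what the test
suite's brute-force oracle verifies on a thousand random profile pairs.

Two numerical caveats are documented rather than hidden. First, the
dense-grid minimum converges quadratically only where the gamma landscape
is smooth; near a steep penumbra crossing the grid-sampling error is
slope-limited, so gamma values on very sharp gradients carry an
uncertainty of order `slope * step / dD`. Second, the low-dose threshold
defaults to 0 (all points included), because published pass rates for
this technique evidently include the tail regions — excluding them is a
one-parameter change.

Reference points outside the evaluated scan's support are flagged
excluded rather than extrapolated.

## Reference matching

A high-resolution reference (a diode-measured tank scan, or here the
analytic truth) must be blurred to the array's chamber size before a fair
comparison. `convolve_rect()` treats the scan as a piecewise-linear
function and evaluates its convolution with a unit-area top-hat in closed
form (an exact antiderivative per segment, no quadrature), so constants
and interior ramps pass through exactly and a sampled step edge becomes
the analytic ramp of the kernel width. Edges are handled by clipping the
window to the scan support and renormalizing to the covered width;
zero-padding would fabricate dose falloff at the scan ends and corrupt
tail comparisons.

One geometric consequence worth knowing: a width-`w` top-hat displaces a
monotone edge laterally by at most `w/2`. With the 0.4 cm default
chamber, that is 2 mm — exactly the DTA of the 2%/2 mm criterion — so on
noiseless smooth profiles the benefit of convolution shows up at 1%/1 mm
rather than 2%/2 mm. Real measurements, with noise and setup error on top
of the volume averaging, degrade the unconvolved comparison much further;
passing the synthetic tests therefore bounds numerical correctness, not
real-world pass rates.

## QA statistics

`type_a_cov()` computes per-detector COV (sample standard deviation over
mean, percent) across repeated identical exposures, and averages it over
in-field detectors — those whose mean reading is at least 80% of the CAX
mean by default; the threshold is a parameter because "in-field" has no
universal definition. Sample (n−1) standard deviations are used
throughout. `couch_shift_qa()` differences successive measured positions
against successive nominal shifts, so any constant offset between the two
scales cancels; the summary reports mean, sample SD, and maximum absolute
deviation (published summaries of the form "0 ± 0.02 cm" do not say
which spread they quote, so both are available). `mu_budget()` counts
acquisitions as `pitch / spacing` (an integer for uniform composites),
while `sampling_factor()` reports the possibly fractional point-density
ratio used for non-divisor increments such as 0.2 cm.

## The pipeline and its study conditions

`run_pipeline()` chains beam → array → interleave → renormalize →
reference convolution → gamma → QA summary, writing every intermediate
artifact plus `summary.json` when an output directory is given. All
randomness derives from the configured seed (each acquisition gets a
deterministic derived seed), so identical configurations give
byte-identical artifact bundles.

The default configuration is the small-field study condition: a 2 × 2 cm
open field at 100 cm SSD and 5 cm depth on the inline (Y) array — the
crossline axis lacks its two near-center detectors, which matters for a
2 cm field — with 0.05 cm shift increments, 50 MU per exposure, 0.03%
noise COV, and gamma at both 1%/1 mm and 2%/2 mm. Pass rates are reported
to two decimals.

Problem sizes in the test suite were chosen to make the statistics
decisive while keeping the suite quick: the gamma oracle comparison runs
1,000 random 20-point profile pairs; the COV recovery uses 10,000
simulated repeats of the 63-chamber crossline array (standard error of
the in-field average ≈ 4e-5 percentage points, so a 3-SE band is a sharp
test of the generator's 0.03%); the resolution trend runs the five shift
schedules 0.5/0.2/0.15/0.1/0.05 cm under a fixed seed.

## What the synthetic tests do and do not show

The generator emulates penumbra shape, scatter tails, horns, wedge
gradients, chamber volume averaging, and exposure-to-exposure noise. It
does not emulate setup and alignment error, beam-output drift within a
session, detector-to-detector calibration residuals, energy response or
material-interface effects in the tail region, or couch-positioning
error. Consequently the synthetic resolution trend saturates: at the
default noise level every shift schedule reaches 100% at 2%/2 mm and the
trend is non-trivial only at 1%/1 mm, whereas published measurements show
large 2%/2 mm differences across the same schedules. Green tests
demonstrate that the bookkeeping, interleaving, normalization, gamma, and
convolution mathematics are correct — not that a physical array will
achieve any particular pass rate.

## Known limitations

One-dimensional profiles only (no 2D/3D reconstruction or diagonal-array
star merging); couch rotations restricted to 0°/90°; the wedge surrogate
is not a dynamic-wedge physics model; percent-depth-dose acquisition is
out of scope (arrays with high-Z internals are poorly suited to it); no
proprietary array file formats are parsed — the columnar text format in
`?profile_file` is the interchange surface.
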