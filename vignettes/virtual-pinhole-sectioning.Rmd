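---
title: "Virtual-pinhole optical sectioning with a field-stop SLM: model and methods"
author: "slmscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual-pinhole optical sectioning with a field-stop SLM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The imaging scheme

A widefield epifluorescence microscope cannot reject out-of-focus light. A
transmissive spatial light modulator (SLM) placed at the field stop can:
each SLM element transmits or blocks the illumination destined for one
small patch of the focal plane. slmscope models the acquisition scheme in
which a sparse dot array of transmitting elements — one per u x v *unit
cell*, by default 6 x 6 — is raster scanned through all 36 unit-cell
offsets, with one camera sub-image captured per offset. Sparse
illumination keeps the illuminated spots far apart (five dark elements
between neighbors), so light scattered or defocused from one spot barely
reaches another spot's detection region.

Three reconstructions turn the 36 sub-images into one image:

* **SLM-sum** — the per-pixel sum. Every location was illuminated once, so
  this is a widefield-equivalent image (light collected sequentially
  rather than simultaneously). The package asserts this equivalence up to
  the off-state leakage bound `36 / extinction_ratio`.
* **SLM-max** — the per-pixel maximum over the sub-images. Alignment-free,
  but bright out-of-focus structures leak into the maximum, and each pixel
  keeps its noisiest sample.
* **SLM-pick** — each pixel takes its value from the sub-image in which
  its conjugate SLM element transmitted. This is a *virtual pinhole*: only
  the camera pixels conjugate to the illuminated patch are kept, the
  digital analogue of a confocal pinhole, and the strategy with the best
  rejection of out-of-focus and scattered light. Pixelwise,
  `pick <= max <= sum` always.

## Forward model

Image formation is incoherent and layer-wise. A phantom is a nonnegative
fluorophore density on z slabs; for focal depth `f` and slab depth `z`:

1. excitation at the slab = transmission map convolved with the
   excitation defocus kernel at defocus `z - f`;
2. emission = excitation x density x slab thickness;
3. the camera sees the emission convolved with the emission defocus
   kernel, summed over slabs, area-binned from the simulation grid
   (4 sub-pixels per camera pixel, about 27 nm object-space) to camera
   pixels;
4. counts = Poisson(noiseless x `photon_scale` x exposure) + Gaussian
   read noise, rounded and clamped at zero. Identical seeds give
   bit-identical images.

The defocus kernel is an isotropic normalized Gaussian with
`sigma(dz)^2 = sigma0^2 + (m dz)^2`, `sigma0 = 0.21 lambda / NA` (matched
to the Airy core). Kernels are normalized to sum to one at every defocus:
defocus conserves power, so peak intensity falls as the illuminated area
grows (`I = P / A`). The kernel family is deliberately simple — it keeps
every characterization below analyzable and fast — and is isolated behind
`defocus_kernel()`, so a physical-optics kernel (Born-Wolf,
Gibson-Lanni) could be substituted without touching the rest of the
package.

### Calibrating the defocus slope

The geometric marginal-ray default `m = tan(asin(NA/n))/sqrt(2)` (about
1.71 /um at NA 1.4, n 1.515) describes an illumination beam that fills
the full aperture. The reference instrument's LED Koehler illumination
does not: its measured axial illumination response through a single SLM
element has a 0.61-um FWHM, far wider than the full-aperture geometry
predicts. `calibrate_defocus_slope()` therefore solves for `m` from the
closed-form on-axis intensity of the element's active rectangle blurred
by `sigma(dz)` — an erf product — so that the simulated single-element
axial illumination FWHM equals the measured value (default 0.61 um). The
calibrated slope, about 0.47 /um, is recorded in the configuration and
used by all simulation-backed characterizations.

## Geometry and the pixel-frame assignment

Elements project to camera pixels through a similarity transform: scale
(camera pixels per element, default 3.5 — the off-the-shelf geometry),
rotation about the optical axis, and a translation. The virtual pinhole
of an element is the digital disk of pixel centers within
`pinhole_diameter_px / 2` (default diameter 4 px) of the element's
projected center. Because 3.5 px/element is not an integer, some pixels
fall inside two pinholes — these *shared* pixels take the maximum over
exactly their claiming frames — and the corners of element cells fall
inside none. Uncovered pixels are a strict error by default; the
pipelines use the documented `fill = "max"` fallback (take the
maximum-projection value there, flagged in provenance) so that the
reconstructed field has no holes. The raster order of the scan is
row-major (row offset slowest) and is stored with every stack and
sidecar, so reconstruction never depends on an implicit convention.

`calibrate_alignment()` estimates the transform from an image of a
projected cross (center row + column of elements on a thin film): ridge
centroids are traced in sliding windows, fitted with weighted lines;
rotation comes from the line angles, offset from their intersection, and
scale from the half-maximum ridge length against the known element
count. On noiseless synthetic crosses the recovery is better than
0.01 px and 0.01 degrees; the test suite requires 0.1 px / 0.05 degrees,
and 0.3 px under Poisson noise at 100 peak counts.

## Characterization suite

* `thin_film_axial_response()` — per-depth field-of-view mean of a
  reconstructed thin-film z-stack, Gaussian-fitted. A peak is
  *measurable* only if the fitted amplitude exceeds 3x the fit residual
  SD; the criterion is this package's operationalization of "no
  measurable peak" for the widefield case, which is flat by power
  conservation.
* `gaussian_fwhm()` / `width_at_fraction()` — the width estimators; the
  fraction-crossing estimator subtracts the fitted constant offset and
  uses the outermost crossings, so an FWTM on a bimodal profile spans
  both lobes. They agree within 2% on clean unimodal profiles.
* `average_beads()` — threshold + 3D connected components, per-bead
  center z from the brightest plane, lateral center by 2D Gaussian fit,
  sub-pixel alignment, then averaging, with transverse/axial profiles
  through the mean center.
* `axial_illumination_profile()` — fixed-radius ROI sums per depth minus
  a matched background, the bead-based measurement of illumination
  intensity versus depth.
* `profile_sbr()` — peak pixel intensity divided by the mean intensity
  1.0-1.5 um away on both sides; a side is excluded when another peak
  lies within 1.5 um on that side (the numeric radius is this package's
  choice, configurable); both sides excluded is an error. SBR is
  invariant to multiplying a profile by a positive constant and *not* to
  additive offsets — by construction.
* `count_clear_fibers()` — strict `SBR > 1.5` count;
  `sbr_table_summary()` — column means +/- SD and per-fiber
  cross-modality ratios. The bundled `flp_fiber_sbr()` table (24 fibers
  of a C. elegans FLP neuron under widefield, SLM-pick and confocal
  imaging) reproduces counts of 24/23/12 clear fibers and a mean
  SLM/widefield ratio of 2.9.
* `theoretical_axial_fwhm()` — the closed-form pinhole-broadened axial
  sectioning FWHM
  `sqrt((0.88 lambda_em / (n - sqrt(n^2 - NA^2)))^2 + (sqrt(2) n PH / NA)^2)`;
  with lambda_em 0.525 um, n 1.515, NA 1.4 and the 4-pixel object-side
  pinhole `PH = 4 x 6.5/60 = 0.433 um` it evaluates to 0.83 um.

Report values are rounded half-away-from-zero (`round_half_up()`) only at
the reporting boundary; machine-readable outputs keep full precision.

## What the phantoms emulate — and what they do not

The generators cover the samples the characterization protocol needs: a
uniform optically thin film (diffuse-regime sectioning), solid-sphere
beads of any diameter including sub-voxel point beads of correct total
mass (localized-regime sectioning and resolution), parallel
Gaussian-profile fiber bundles at configurable positions (default 3.3,
5.0, 5.8, 6.9 um — a tightly bundled dendrite arrangement), and a
branched-neuron phantom with a ~5-um soma 20-30x brighter than its
~0.4-um fibers (defaults 20000/1000/800 density units), with ground-truth
centerlines for SBR evaluation. Soma and fiber diameters are stated
assumptions; the tree topology is seeded-random plumbing whose shape
parameters carry no physical claim. None of the phantoms model scattering
tissue, anatomically faithful animals, or photobleaching, so passing
tests demonstrate the pipeline's correctness on clean geometry, not
performance in scattering tissue.

## Numerical choices

* Convolutions run in the Fourier domain with an analytic Gaussian
  transfer function. Boundaries are periodic by default — exact for an
  extended uniform film under a dot array that tiles the field — and
  zero-padded (`boundary = "pad"`) for localized phantoms.
* For a laterally uniform slab, excitation and detection blurs commute
  and compose into a single Gaussian of width
  `sqrt(sigma_ex^2 + sigma_em^2)`; `characterize_thin_film()` uses this
  fast path, and the test suite asserts its equality with the general
  image former.
* Simulation grids are 4x finer than the camera pixel and area-binned
  4 -> 1; tiny negative FFT ripples are clamped to zero before the noise
  model.
* Problem sizes: the standard thin-film characterization uses a
  64 x 64-pixel field, a +/-3-um sweep at 50-nm steps (121 planes x 36
  frames), which the package runs in well under a minute; the
  property-level simulations use 24-48-pixel fields. These sizes are
  chosen so the full suite runs comfortably on a laptop while leaving
  all physics regimes (in-focus, near-focus, far-defocus) represented.

## Known limitations

* **The film-response FWHM falls short of the closed form.** With the
  defocus slope calibrated so the single-element axial illumination FWHM
  is 0.61 um, the simulated thin-film SLM-pick response measures about
  0.66 um FWHM — roughly 20% below the 0.83-um closed-form prediction
  for the matched pinhole (and below the 0.85-um film response measured
  on the reference instrument). The shortfall is structural to the
  Gaussian kernel family: a Gaussian matched to the measured on-axis
  illumination decay necessarily moves flux out of the pinhole faster
  near focus than a real high-NA defocused point-spread function, whose
  ring structure retains near-axis energy (and whose instrument
  measurement also includes finite film thickness, aberrations and
  scatter). No single defocus slope can reproduce both the 0.61-um
  illumination width and the 0.83-um sectioning width; we verified this
  both in closed form and with a flat-top (geometric disk) kernel
  variant, which lands narrower still. The package keeps the calibrated
  Gaussian model — analyzable, fast, and faithful to the illumination
  measurement — and reports the discrepancy rather than retuning any
  parameter toward the sectioning value; the acceptance suite asserts
  the 15% sectioning-consistency check and documents its failure.
* Coherence, polarization, vectorial diffraction, photobleaching and
  scattering media are out of scope.
* The widefield model is axially flat by construction (power
  conservation on a uniform map). A real Koehler system shows a wide but
  finite illumination envelope; which regime applies depends on the
  instrument, so the flat model is the documented default rather than a
  resolved answer.
* Counts are unbounded 16-bit-like integers; full-well saturation is not
  modeled.
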