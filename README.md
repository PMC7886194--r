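# slmscope

Confocal-style optical sectioning on a widefield fluorescence microscope,
without confocal hardware: a transmissive spatial light modulator (SLM) at
the field stop patterns the illumination into a sparse dot array that is
raster scanned across the field of view, and software assembles the
captured sub-images into an optically sectioned image through a *virtual
pinhole*. `slmscope` is a simulation and analysis toolkit for this scheme,
aimed at microscopists and methods developers who want to study, test or
extend it without hardware: it provides a physically motivated forward
simulator of patterned-illumination acquisition, the three reconstruction
strategies, and the full quantitative characterization suite (axial
sectioning responses, bead profiles, signal-to-background ratios of
neurites, fiber detection).

## The method

The SLM is a grid of elements at a plane conjugate to the sample; each
element gates the illumination of one ~0.4-um patch of the focal plane.
One element per u x v unit cell (default 6 x 6) transmits per frame, and
the dot array is raster scanned through all `u*v = 36` unit-cell offsets;
a camera sub-image `I_k` is captured at each offset k. Reconstructions:

- **SLM-sum** `S(p) = sum_k I_k(p)` — widefield-equivalent reference;
- **SLM-max** `M(p) = max_k I_k(p)` — alignment-free sectioning;
- **SLM-pick** `P(p) = I_{k(p)}(p)`, where `k(p)` is the frame whose
  transmitting element is conjugate to pixel p (pixels claimed by two
  elements take the maximum of the two) — the virtual pinhole, the
  digital analogue of a confocal pinhole.

Pixelwise `P <= M <= S`. The axial sectioning strength of a pinhole
system with object-side pinhole diameter `PH` follows the closed form

    FWHM = sqrt( (0.88 λ_em / (n − sqrt(n² − NA²)))² + (√2 · n · PH / NA)² )

implemented in `theoretical_axial_fwhm()`; the effective `PH` of the
4-camera-pixel virtual pinhole at 60x with a 6.5-um camera pixel is
`4 * 6.5 / 60 = 0.43 um` (`pinhole_object_diameter()`).

The forward model (`form_subimage()`, `acquire_scan()`) propagates any
SLM transmission pattern through a defocus-dependent Gaussian
point-spread function with power conservation (`I = P/A`: kernels sum to
one at every defocus), multiplies by a 3D fluorophore-density phantom,
blurs into the camera and applies Poisson + read noise. Phantom
generators (`make_thin_film()`, `make_beads()`, `make_fiber_bundle()`,
`make_neuron()`) cover the standard characterization samples. See the
methods vignette (`vignettes/virtual-pinhole-sectioning.Rmd`) for the
model, its calibration and its limitations.

## Worked example

```r
library(slmscope)

## closed-form sectioning theory for the reference optics
ph <- pinhole_object_diameter(4, 6.5, 60)
round_half_up(ph, 2)                                      # 0.43 (um)
round_half_up(theoretical_axial_fwhm(0.525, 1.515, 1.4, ph), 2)  # 0.83 (um)

## bundled reference SBR table: 24 neuronal fibers, three modalities
tab <- flp_fiber_sbr()
count_clear_fibers(tab$confocal)   # 24
count_clear_fibers(tab$slm)        # 23
count_clear_fibers(tab$widefield)  # 12
s <- sbr_table_summary(tab)
round_half_up(s$column_mean["widefield"], 1)        # 2.0
round_half_up(s$ratio_mean["slm/widefield"], 1)     # 2.9

## simulated thin-film sectioning: 64x64 field, 6x6 scan, +/-3 um sweep
characterize_thin_film("scan", "pick", seed = 1)
#> Thin-film characterization (pick): Axial response: FWHM 0.656 um over z [-3.00, 3.00] um
characterize_thin_film("widefield", seed = 1)
#> Thin-film characterization (widefield): Axial response: no measurable peak over z [-3.00, 3.00] um
```

The first block evaluates the sectioning theory: a 4-pixel virtual
pinhole corresponds to a 0.43-um object-side pinhole and a predicted
0.83-um axial sectioning FWHM. The SBR block shows that, along the same
neuron, SLM-pick imaging clearly resolves 23 of the 24 fibers a confocal
resolves (96%) while widefield resolves 12, with a 2.9x mean
signal-to-background gain over widefield. The last block runs the full
simulated pipeline: the scanned + pick reconstruction of a thin
fluorescent film shows a sharp axial response (0.66-um FWHM under the
calibrated Gaussian defocus model — about 20% below the closed form; the
vignette's *Known limitations* section analyses why), while the matched
widefield sweep is flat: no sectioning without the patterned scan.

## Command line

A thin CLI over the package functions is installed at
`inst/cli/slmscope`:

```sh
slmscope simulate    --config run.yaml
slmscope reconstruct --strategy pick --stack stacks/plane01 --out out.tif
slmscope calibrate   --cross cross.tif --grid grid.json --out map.json
slmscope fixtures    --out fixtures --seed 1
```
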