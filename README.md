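# grinsim

Simulation and evaluation of two-photon calcium imaging through long
GRIN-rod microendoscopes, with and without an aberration-correcting back-end
lens.

Gradient-index (GRIN) rod lenses relay a two-photon focal plane several
millimetres into tissue, but their intrinsic aberrations blow up the
excitation point-spread function (PSF) away from the optical axis: marginal
neurons are sampled with a large, astigmatic excitation volume, so their
fluorescence is dim, their signals mix with neighbours, and the usable field
of view (FOV) shrinks. An aspheric corrective lens on the back of the rod
keeps the PSF compact over a much larger radius. `grinsim` builds synthetic
calcium-imaging movies whose every photon has a known ground-truth source,
so the benefit of that correction can be quantified exactly:

* **tissue** — non-overlapping spherical neurons (soma radius ~ N(10, 3) µm)
  with non-fluorescent nuclei (~ N(5, 1) µm), placed by random sequential
  insertion up to a target density of 26.8·10⁴ cells/mm³;
* **activity** — per-neuron spiking as an independent Poisson process plus
  shared Poisson processes within randomly paired groups (pairing
  probability 0.05, total rate 0.3 Hz), converted to fluorescence with a
  difference-of-exponentials sensor kernel; the shared rate is calibrated so
  the mean all-pairs Pearson correlation of the ground-truth traces is
  0.041;
* **optics** — the asphere sag `Z(r) = c r²/(1 + √(1 − (1+k)c²r²)) + Σ αₙ r²ⁿ`,
  curved focal surfaces (a polynomial surface for corrected probes, two
  spherical shells for the astigmatic uncorrected ones), quartic
  radius-dependent PSF sizes `f(r) = a r⁴ + b r² + c`, quartic
  magnification/field-distortion calibration, and a radial
  excitation-intensity profile;
* **render** — a static pixel × neuron mixing matrix built by scanning the
  excitation ellipsoid along the focal surface(s), combined with the
  empirically fitted three-regime pixel-noise model at 30 Hz;
* **extract** — rectangular-box cell detection, per-frame 80th–95th
  percentile-band ROI traces with background subtraction, sliding
  20th-percentile baseline `ΔF/F₀`, and
  `peak SNR = max(ΔF/F₀) / SD(values below the 25th percentile)`;
* **metrics** — cross-contamination of adjacent cell pairs against an
  expected-correlation threshold (mean ground-truth pair correlation + 3 SD),
  a GLM source-purity index `max_j(a_j²)/Σ_j a_j²`, first-source
  correlations, and radial-trend regressions with permutation tests.

## Worked example

```r
library(grinsim)

# Table of effective-FOV radii (10 um axial-resolution threshold) and the
# fold change gained by the corrective lens
fov_fold_report()
#>   grin_length_mm radius_uncorrected_um radius_corrected_um radius_fold area_fold
#> 1            6.4                    46                 100        2.17       4.7
#> 2            8.8                    34                  52        1.53       2.3

# One simulated FOV through the corrected 6.4 mm probe (60 s, 256 x 256 px)
cfg <- experiment_config("corrected-6.4", n_fovs = 1, duration = 60,
                         fov_pixels = 256, seed = 42)
fv  <- run_fov(cfg, 1)
sum(fv$rois$snr_valid & fv$rois$peak_snr > 15)
#> [1] 302
```

The fold table reproduces the probe characterization: the corrective lens
enlarges the effective FOV radius 2.17-fold (6.4 mm rod) and 1.53-fold
(8.8 mm rod), i.e. 4.7 and 2.3 times the area. The FOV run detects the
ground-truth somata in focal reach and returns, for each, a calibrated
radial position and the peak SNR of its extracted `ΔF/F₀` trace; with the
same seed the paired uncorrected run detects a similar number of cells but
far fewer clear the SNR > 15 cutoff (185 vs 302 in this example), and its
source-purity index falls off with radius about four times faster — the
quantitative signature of off-axis aberrations.

The numbered scripts under `analysis/` run the full study at reduced scale:
`01_activity_model.R` (ground-truth correlation statistics),
`02_optical_characterization.R` (PSF curves, FOV folds, bead-phantom
closed-loop check), `03_imaging_experiments.R` (paired corrected vs
uncorrected experiments) and `04_demixing_metrics.R` (SNR sweeps,
adjacent-pair contamination, purity slopes, first-source correlations).
Each writes tidy CSV/JSON tables under `results/`.

## Package layout

`R/` implementation (one file per stage), `src/` compiled kernels for sphere
packing, voxel rasterization, excitation-volume scanning and trace
extraction, `tests/testthat/` the unit, property and acceptance suites,
`vignettes/grinsim-methods.Rmd` the methods notes, `analysis/` the workflow
scripts.
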