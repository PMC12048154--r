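---
title: "Simulating calcium imaging through GRIN microendoscopes: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating calcium imaging through GRIN microendoscopes: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`grinsim` renders synthetic two-photon calcium t-series through geometric
models of GRIN-rod microendoscopes — with and without an aspheric corrective
element — and evaluates, against exact ground truth, how the optics shape
signal-to-noise, cross-contamination between neighbouring cells, and the
purity of extracted sources. This vignette records the models, the tunable
parameters, and the places where the design was genuinely open, so a reader
can judge what a passing test suite does and does not establish.

## The forward model

**Tissue.** Neurons are spheres with radius drawn from N(10, 3) µm and a
concentric non-fluorescent nuclear region of half-width N(5, 1) µm; only the
shell between nucleus and soma boundary expresses the indicator. Spheres are
placed by random sequential insertion, rejecting any candidate whose center
is closer than the sum of soma radii to an accepted neuron, until the
density target (26.8·10⁴ cells/mm³) is reached or 10⁴ consecutive rejections
signal jamming. The target exceeds the jamming density of non-overlapping
spheres at this size distribution, so jamming is the usual stopping rule and
the realized density (~2.4·10⁵ mm⁻³) is recorded rather than forced. Two
consequences of the insertion rule are worth knowing: accepted somata skew
slightly small late in the fill, and nuclei are resampled (never the soma)
when a draw does not fit, so the soma marginal stays exactly Gaussian while
the nuclear mean is pulled down a little by the truncation. Membership is
evaluated at voxel centers on the 0.8 × 0.8 × 1 µm grid, without
partial-volume weighting.

**Activity.** Each neuron fires as an independent Poisson process plus the
common process of every shared-activity group it belongs to, for 5 min in
1 ms bins, at a configured 0.3 Hz total. Pairing is Bernoulli(0.05) over all
neuron pairs. "Groups of paired neurons" admits two readings, and the choice
matters:

* *pairs*: every sampled pair is its own group of two. Holding the
  per-neuron total rate at 0.3 Hz, a neuron with g ≈ 0.05·n groups can give
  each shared process at most 0.3/g Hz, so the mean all-pairs correlation is
  bounded near 1/n — about 0.005 at n = 200, an order of magnitude below the
  0.04 scale typical of cortical recordings that the model is meant to
  match.
* *components* (default): a group is a connected component of the pairing
  graph. At n·p ≈ 10 the graph has a giant component, i.e. in practice one
  common process shared by nearly all neurons, and the mean all-pairs
  correlation equals (shared rate)/(total rate) with no n-dependent ceiling.

Under the component reading the shared rate was calibrated once by
simulation (secant iteration on 100-simulation averages of the mean
all-pairs trace correlation at n = 200, 300 s) and frozen at **0.0123 Hz**,
which puts the mean all-pairs Pearson correlation of the fluorescence traces
at 0.041. `calibrate_shared_rate()` re-runs the procedure. Correlations are
computed on the fluorescence traces (not the raw spike counts) at 10 ms
resolution; for white Poisson inputs the common sensor filtering cancels in
the correlation, so this choice is a matter of convention, and both are
available.

**Sensor.** Spikes drive a difference-of-exponentials kernel (rise 2 ms,
half-decay 70 ms, unitary ΔF/F 0.4, all configurable; an optional Hill
saturation acts on the summed drive). These are plausible fast-GCaMP values,
not measurements — swap in indicator-specific constants for quantitative
amplitude work. The convolution is exact (two recursive exponential
filters), and traces are bin-averaged onto the 30 Hz frame grid, which
approximates frame integration rather than point sampling.

**Optics.** All models are rotationally symmetric in the radial distance r.
Corrected probes image along a polynomial focal surface; uncorrected probes
are astigmatic and carry two spherical focal shells (curvature radii
273/2000 µm for the 6.4 mm rod, 992/2000 µm for the 8.8 mm rod), each
contributing an equal-weight excitation pass — the equal weighting is a
choice, nothing in the characterization pins the ratio. PSF lateral and
axial FWHM follow quartics `a r⁴ + b r² + c`. The published coefficient
tables were not available, so the default quartics are *reconstructed*:
anchored at plausible on-axis values and at the known effective-FOV radii
(axial FWHM = 10 µm at r = 100/46 µm for the 6.4 mm probes and 52/34 µm for
the 8.8 mm probes), which reproduces the radius folds 2.17/1.53 and area
folds 4.7/2.3 exactly. Beyond the measured range the uncorrected quartics
explode (hundreds of µm at the FOV corner), so PSF sizes saturate at caps
(axial 60 µm, lateral 8 µm) — a bounded-aberration model, not a fit. The
magnification factor is a quartic in r; the cumulative distance calibration
g is derived from it by quadrature and refitted on the quartic-plus-linear
basis, so the two are mutually consistent by construction. The radial
excitation-intensity profile is a clamped even polynomial normalized to 1 on
axis, decaying faster for uncorrected probes.

**Rendering.** A static pixel × neuron mixing matrix is built once per FOV:
for every pixel inside the circular FOV, an excitation ellipsoid (semi-axes
= FWHM/2, binary support by default, Gaussian weighting optional) is
centered on the focal-surface point and oriented along the local surface
normal; the weight of (pixel, neuron) is the fraction of excitation voxels
in that neuron's fluorescent shell. Rendering is then a sparse
matrix-vector product per frame plus noise — exactly equal (to rounding) to
scanning voxels per frame, a property asserted on small grids against a
brute-force triple-loop oracle. Pixels whose tiny on-axis ellipsoid
contains no voxel center fall back to the voxel containing the ellipsoid
center.

**Noise.** Three regimes, with coefficients fitted to in vivo recordings:
dark noise outside the circular FOV (mixture of two Gaussians for the
temporal mean, SD linear in the mean, clamped at zero), background noise in
the empty center (lognormal means — interpreted as log-space parameters, so
the linear-space mean is e^6.54 ≈ 690 — with SD linear in √mean), and
occupied-pixel noise with SD linear in √mean. Two structural choices were
forced by consistency with the data the coefficients came from:

1. *Noise level.* The square-root laws were fitted to per-pixel temporal
   SDs. Drawing independent noise per excitation voxel and averaging (the
   literal reading of the generative recipe) makes pixel noise shrink as
   1/√V with the excitation-volume size, so a strongly aberrated probe
   would render almost noise-free pixels and every corrected-vs-uncorrected
   comparison inverts. The default therefore applies the laws at the pixel
   level, which reproduces the fitted statistics for any excitation size;
   `noise_model(level = "voxel")` restores the voxel-level reading.
2. *Intensity modulation.* The radial excitation-efficiency profile
   multiplies the excited fluorescence and background, and the noise SD is
   evaluated on the *modulated* (observed) mean; edge dark noise, a
   detector property, is never modulated. The alternative — multiplying the
   complete pixel value including noise (`intensity_mode = "full"`) — makes
   ΔF/F₀ SNR exactly invariant to the intensity profile and erases the
   radial SNR degradation the instrument comparison is about.

The movie baseline (sensor baseline 5000 intensity units in the experiment
defaults) is not a measured value; it was chosen once so that central-ROI
peak SNR lands in the 10–40 range reported for real recordings.

## Detection, extraction and metrics

The trained-network cell detector used on real data is replaced by a
pluggable detector. The default, ground-truth projection, boxes each
neuron's mixing-matrix footprint, with a visibility threshold: a neuron
must contribute at least 10% of some pixel's excitation volume
(`min_weight = 0.1`). Without it, the two large astigmatic shells give a
nonzero footprint to every neuron in a ~100 µm slab — several-fold more
"cells" than any projection-based detector could see, an artifact of the
detector replacement rather than of the optics. The threshold is applied
identically to both conditions; `min_weight = 0` restores the raw
footprint. All cross-condition comparisons therefore measure the optics
through the *same* detector, and reported counts, slopes and medians are
comparable between conditions but not numerically to a trained detector's.

Traces: per frame, the ROI is the set of box pixels between the 80th and
95th percentile of the box's intensity distribution (linear-interpolation
quantiles; a degenerate distribution keeps every pixel), minus the frame
background — the mean of pixels in no box, above the corner dark-noise mean
and below the box maximum, with carry-forward when the set is empty. F₀ is
the sliding 20th percentile in a 10 s window truncated at the trace ends;
ROIs whose baseline is not strictly positive everywhere are flagged and
excluded from SNR statistics. Peak SNR is max(ΔF/F₀) over the SD of values
below the trace's 25th percentile, undefined (flagged) when that SD is
zero. Centroids are converted to nominal µm by the nominal pixel size and
to real positions through the inverse distance calibration.

Metrics follow the ground truth: the expected pair correlation is the
per-FOV mean all-pairs correlation of source traces averaged over FOVs plus
three SDs of the pooled pair correlations (pooled-pairs SD, the other
reading of "3 SD" being across FOV means; at thousands of sources an evenly
spaced subset of 600 is used — the statistic is insensitive to subsetting
while the full correlation matrix is quadratic). Contributing sources of a
box are neurons whose footprint overlaps it by ≥ 1 pixel; the purity of a
trace is max(a²)/Σa² from an identity-link least-squares fit on the
contributing source traces (collinear sets fall back to the minimum-norm
solution). Note purity is defined on raw coefficients, so it is not
invariant to rescaling an individual source trace — only the fit is.
Radial trends use OLS with a Wald test when residuals pass the normality
gate (Shapiro–Wilk below n = 50, D'Agostino–Pearson otherwise) and a
pairings permutation test when they do not; condition contrasts use
label-permutation tests with 10⁴ permutations below n = 500 and 10⁵ above,
with an add-one correction so p > 0.

## Problem sizes and reproducibility

Experiments are deterministic given one seed, expanded into per-stage
substreams (tissue, pairing, spiking, noise maps, per-512-frame noise
blocks), so any stage can be re-run in isolation and chunked rendering is
chunking-invariant. Tissue and activity substreams do not depend on the
probe, making corrected/uncorrected runs a paired design that sharply
reduces the variance of ordering comparisons at small FOV counts.

The test suite and analysis scripts run at reduced scale: 5 (tests) or 3
(scripts) FOVs per condition, 60 s movies, 256 × 256 pixels, against the
full-scale design of 13–15 FOVs, 300 s, 512 × 512. The correlation
statistic uses 200 neurons and 80–150 independent simulations; its per-run
SD is ≈ 0.014 (dominated by the Poisson count of shared events in 5 min),
so averages of that many runs pin the mean to ±0.002 or so. The
bead-phantom closed-loop check uses the Gaussian-weighted excitation
option, whose axial profile is the excitation profile itself; the default
binary ellipsoid yields a top-hat whose Gaussian-fit FWHM is biased
relative to the configured value. The double-Gaussian model in profile
fitting is only accepted when the single-Gaussian fit leaves a real misfit
(> 0.5% of the signal variance) and the double fit improves the residual by
> 20% — near-exact profiles otherwise make the ratio rule unstable.

## What passing tests do not show

The generator emulates the stated study conditions, not the full physics:
no motion, photobleaching, raster timing within frames, shot-noise
statistics beyond the fitted Gaussian laws, non-spherical morphology or
neuropil, and the sensor kernel is a stand-in rather than a fitted
indicator model. Pixel noise is independent across pixels; real noise
shares voxels between neighbouring scan positions, so spatial averaging
inside ROIs is somewhat more effective here than in vivo. Absolute ROI
counts, purity slopes and correlation medians therefore depend on the
detector definition and the reconstructed optics coefficients; the
supported claims are the orderings and trends between corrected and
uncorrected probes under identical ground truth, and those are what the
acceptance suite asserts.
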