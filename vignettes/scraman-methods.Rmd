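---
title: "Methods: simulation, detection and classification for single-cell Raman phenotyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation, detection and classification for single-cell Raman phenotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scraman)
```

## The problem

Raman-activated cell sorting (RACS) characterizes single cells by their
intrinsic vibrational fingerprint instead of fluorescent labels. A
high-throughput run images a field of cells, extracts single-cell positions,
points the excitation laser at each cell to acquire its Raman spectrum,
quality-controls the spectra, stores them in a phenotype database, and
classifies or sorts the cells by spectral comparison. Every stage can fail in
characteristic ways: overlapping or irregular cells defeat segmentation, and
cells drift (Brownian motion) in the interval between imaging and laser
pointing, so the laser can miss the cell it was aimed at. The pipeline's
headline metric is *sensitivity*,

$$\mathrm{Sensitivity} = \frac{\#\,\text{correctly recognized cells}}
                              {\#\,\text{correct cells}},$$

computed once for image analysis and once, necessarily lower or equal, for
Raman profiling.

`scraman` implements this entire loop hardware-free: a parametric simulator
stands in for the microscope and spectrometer, so each downstream stage is
testable against known ground truth, and the whole pipeline can be
benchmarked end to end.

## The simulator

**Cell fields.** Cells are placed uniformly at random in a rectangular
window, with a margin of one radius plus 2 µm from the border so each cell
body lies inside the imaged field. A cell's `overlaps` flag is true iff its
center is closer to another center than the sum of the two radii. An optional
rejection-sampling mode produces fields with no overlaps (plus an optional
extra separation), used to construct ideal-case scenarios.

**Images.** Each cell is rendered as a radially shaded disk: intensity rises
above the background by a contrast term rolled off at the cell boundary by a
logistic edge of width `boundary_sharpness` (default 0.3 µm), plus white
Gaussian background noise. Intensities live in the nominal [0, 1] range of
8/16-bit rasters. Pixel `(row, col)` is 0-based with its center at
`((col + 0.5) px, (row + 0.5) px)` in stage coordinates (x rightward, y
downward, origin at the window's top-left corner).

**Spectra.** A strain is described generatively by a `strain_profile`: a peak
library (center, mean amplitude, amplitude CV, FWHM; Gaussian by default,
Lorentzian optional), a polynomial baseline over the rescaled wavenumber
axis, additive Gaussian noise, and a cell-radius distribution. The shipped
`yeast_profile()` carries the 1003 cm^-1 phenylalanine ring-breathing marker
plus CH2 (1450), amide I (1655) and CH-stretch (2935) bands. The default
grid is 400-3200 cm^-1 at 1 cm^-1 steps. When users have template spectra, a
supervised alternative (`knn_resample_spectrum`) averages the k nearest
same-label templates around a random anchor and perturbs the mean; the
parametric generator is the default because it needs no external data.

**Acquisition.** Between detection and laser pointing the cell diffuses for
`detect_to_acquire_lag` seconds as an isotropic 2-D Gaussian walk with
per-axis step variance `2 D dt` (mean squared displacement `4 D dt`).
Acquisition succeeds iff the drifted cell is still within one radius of the
pointed coordinate *and* the cell is not flagged overlapping; otherwise a
miss marker is returned. The two presets `brownian_presets()` emulate
suspended ("tube", D = 20 µm²/s) versus settled ("slide", D = 0.05 µm²/s)
cells; they are an emulation of those acquisition conditions, not a
hydrodynamic model.

**Determinism.** Every simulator output is a pure function of (config,
profile, seed). The master seed in `sim_config` streams child seeds per
window and per acquisition, so a benchmark replays exactly.

## Cell detection

Detection follows the classical edge route: a 3x3 Sobel (or Prewitt)
gradient magnitude with reflected borders, thresholding, one pass of 3x3
morphological closing, hole filling and connected-component labeling
(morphology via EBImage). The deliberately *conservative* acceptance rule
then keeps only regions that look like single, clearly bounded cells:

* touching the image border → `rejected_open_boundary` (the boundary cannot
  be verified closed);
* adjacent to another region, or larger than the single-cell area maximum →
  `rejected_overlap` (two touching cells merge into one oversized region);
* smaller than the minimum area or circularity
  $4\pi\,\mathrm{area}/\mathrm{perimeter}^2$ below 0.6 → `rejected_shape`.

Everything else is accepted. This trades sensitivity for specificity: a
missed cell costs one acquisition, a false or doubled detection pollutes the
database.

Two numerical choices deserve a note. First, the gradient *magnitude* of a
noisy background is Rayleigh-like — nonnegative with a positive median — so
a threshold proportional to its robust spread alone sits inside the noise
bulk; the threshold is therefore `median + k·MAD` (default k = 5), floored
at 10% of the strongest edge so noiseless images do not threshold at zero.
Second, filling a detected edge ring inflates the measured area by roughly
one pixel of radius; the default area window (5, 60) µm² accounts for that
bias at the calibrated cell size (radius 2.5 ± 0.25 µm at 0.5 µm/pixel),
placing the upper bound above the largest plausible single cell and below a
merged pair.

Matching detections to ground truth (for evaluation only) is greedy
nearest-centroid one-to-one matching within a tolerance of one mean cell
radius; ties break by smaller distance, then lower cell id. Greedy matching
is checked against an exhaustive optimal assignment on small random
configurations in the test suite.

## Spectrum quality control

The QC chain applies, in order: baseline correction, Savitzky-Golay
smoothing, Fourier low-pass filtering, and normalization; each step is
recorded in the spectrum's metadata and the concatenated record acts as a
preprocessing fingerprint that classifiers check at prediction time.

* **Baseline.** Default: iterative polynomial fitting (degree 5) — fit,
  clip the data to the fit from above, refit until convergence, leaving the
  lower envelope. Alternative: asymmetric least squares (Whittaker smoother,
  penalty `lambda = 1e5`, asymmetry `p = 0.01`). Both are field standards;
  the polynomial default was chosen for having fewer tuning constants.
  Stacks of spectra on a shared grid are processed column-wise.
* **Smoothing/derivatives.** Savitzky-Golay (default window 11 points,
  quadratic), with first and second derivatives with respect to wavenumber
  available; edges are handled by reflection. The implementation wraps the
  `signal` package's filter coefficients and is tested against a pointwise
  local least-squares fit.
* **Fourier filter.** FFT, zero all coefficients above
  `cutoff_fraction x Nyquist` (default 0.4), with a cosine taper
  (apodization) over the top 10% of the passband to suppress ringing;
  `cutoff = 1` with no taper is the identity. Checked against a naive
  O(N²) DFT.
* **Normalization.** Vector (unit Euclidean norm, the default — standard
  before distance and kernel computations), unit trapezoidal area, or unit
  maximum.

**SNR.** The peak signal-to-noise ratio is
`(max intensity in the peak window − median of a noise window) / (MAD-based
sd of the noise window)`, with the noise window defaulting to the
biologically silent 1750-1850 cm^-1 region. The MAD-based estimator keeps
stray peaks in the noise window from inflating the noise estimate. Note the
max over a multi-point peak window is biased upward by order one noise sd;
at the default 5 cm^-1 half-width a true amplitude-to-noise ratio of 3
measures as roughly 4. The estimator is unbiased when the peak window is a
single grid point (`peak_halfwidth = 0`), which the calibration tests use.

## The phenotype database

The store is a plain directory: a tab-delimited `manifest.tsv` with a
four-block schema — (A) project (cell id, project id, ISO-8601 date), (B)
sample preparation (name, temperature, shaking, OD, plus free key-value
extras), (C) instrument (laser, filter, objective, grating), (D) phenotype
(image reference, spectrum reference, stage coordinates) — with spectra and
images as files referenced by relative path. A directory store is
inspectable, language-neutral and diff-friendly.

Two tiers: *raw* keeps every record; *refined* holds records promoted by a
rule. The default rule promotes a record when its marker peak (1003 cm^-1 by
default) has SNR **strictly over** 3; alternatives promote on a raw
intensity threshold or on a curator flag ingested from a table. Promotion is
idempotent, records its reason, and the refined tier is a subset of raw
after every operation (asserted by `db_check_invariants`).

## Classification and search

Spectra are QC'd (vector-normalized) before any comparison.

* **Euclidean search** ranks the reference library by distance to the query;
  the label is the majority of the top k (default 1), ties broken by smaller
  mean distance then lexical label order.
* **SVM** uses the RBF kernel $K(x_i, x_j) = \exp(-\gamma\|x_i - x_j\|^2)$,
  $\gamma > 0$, with nu-SVC (via e1071/libsvm). $\gamma$ is grid-searched
  over $2^{-15}, \dots, 2^{3}$ and nu over 0.1-0.5 by stratified 5-fold
  cross-validation with a seed-deterministic fold assignment; the model is
  refit on all data at the best setting, ties resolved toward smaller
  $\gamma$ then smaller nu.
* **PCA separation** projects a two-strain set onto the top two principal
  components and assigns each cell to the nearer label centroid in PC
  space; the separation error rate is the fraction of wrongly assigned
  cells. Nearest-centroid assignment is this package's operationalization
  of "wrongly assigned"; other choices (e.g. a classifier in PC space) are
  possible.

Models save to plain-text archives; SVM archives store support vectors,
dual coefficients and intercepts, and prediction from a loaded archive is
recomputed from the one-vs-one decision functions (verified against the
in-memory model in the tests). Search wall-clock timing is deliberately not
benchmarked — it is hardware-dependent.

## The end-to-end benchmark

`run_benchmark` replays the whole loop per window — place, render, detect,
match, then acquire at each matched detection's centroid after the lag —
and pools counts across windows (pooled counts, not averaged per-window
rates). A cell is image-correct if matched within tolerance, Raman-correct
if additionally its acquisition did not miss, so
`sensitivity_raman <= sensitivity_image` structurally. The report carries
per-window counts, the config echo and the seed list, and serializes to
JSON.

### Shipped calibration

The default configuration is 5 windows of 100 cells in an 800 x 800 µm
window at 0.5 µm/pixel — a sparse plating of roughly 150 cells/mm², chosen
so that the expected overlapping-cell fraction (the dominant, deliberate
loss of the conservative detector) is a few percent — with the yeast-like
profile (radius 2.5 ± 0.25 µm), background 0.15, cell contrast 0.5, image
noise sd 0.02, slide-like D = 0.05 µm²/s and a 0.5 s lag. Under these
conditions pooled image-analysis sensitivity is ≈ 96-98% and Raman-profiling
sensitivity sits just below it, consistent with the regime reported for
simulated fields of this design (95% image / 91% Raman as lower bounds). At
100 cells per 100 x 100 µm — 20% area coverage — more than half of all
cells overlap a neighbour, so no conservative detector can reach those
sensitivities; the shipped window size represents the sparse fields such
numbers imply.

### What the simulator does and does not show

The generator emulates strain-specific peak structure, amplitude
variability, baseline drift, shot-like noise, cell overlap, border clipping
and Brownian drift between detection and pointing. It does not model
diffraction or the λ⁻⁴ scattering efficiency, CCD response, non-circular or
3-D cell shapes, illumination gradients, fluorescence photobleaching,
cosmic-ray spikes, or fluid dynamics in microfluidic channels. Passing
tests therefore demonstrate the correctness and calibration of the
pipeline's logic under this generative model, not performance on real
acquisitions; on real data every stated loss mechanism is harsher (the
tube/slide presets, for instance, only mimic the direction of the
suspension effect).

### Problem sizes used by the test suite

Monte-Carlo tests run at sizes chosen to keep the whole suite in the
low-minutes range while leaving comfortable statistical margin: the full
5 x 100-cell calibration runs once; invariant sweeps (specificity bias,
density monotonicity, drift effect, Raman <= image) use 150-250 µm windows
with 8-24 cells over 20 seeds; spectral Monte-Carlo calibrations use 200-500
draws; classification comparisons use 20 training / 40 test spectra per
seed over 20 seeds on a 600-1800 cm^-1 grid at 2 cm^-1.

## Known limitations

* The detector never splits touching cells (no watershed) — by design, the
  conservative rule rejects them.
* Circularity from pixel-counted perimeters is biased for small regions
  (values above 1 occur); the 0.6 floor is calibrated to the 0.5 µm/pixel
  default, and detection of cells below ~8 pixels of diameter degrades.
* `knn_resample_spectrum` requires all templates on one grid; no
  interpolation/resampling between grids is provided.
* The database store is single-writer; there is no locking for concurrent
  mutation.
* nu-SVC feasibility bounds nu by class balance; infeasible grid points are
  skipped (recorded as NA in the CV table).
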