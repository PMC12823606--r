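---
title: "Spectral staging of secondary lymphedema: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral staging of secondary lymphedema: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Secondary lymphedema of the arm — a frequent sequela of breast-cancer
treatment — is conventionally staged by palpation, circumference tapes,
two-point discrimination, joint mobility and patient questionnaires, all of
which are operator-dependent and only moderately reproducible. Near-infrared
hyperspectral imaging (HSI) offers a contactless alternative: each
acquisition is a reflectance hypercube (two spatial axes × one wavelength
axis) in which water and lipid absorption leave characteristic spectral
signatures. Edema replaces subcutaneous lipid with interstitial fluid, so
the affected arm shows a deeper water absorption band (~970 nm) and a
shallower lipid band (~930 nm) than the contralateral, unaffected arm.

`lymphspec` implements the full analysis path from raw hypercubes to a
spectral disease stage, together with a synthetic-cohort generator that
emulates the acquisition, so every stage of the pipeline is testable without
patient data.

## Data model

The instrument records 640 × 480 pixel frames over 100 spectral bands.
The nominal range is quoted loosely as "500 to 1000 nm in 5 nm steps",
which would give 101 bands; with 100 stored planes the consistent reading,
adopted here, is band centers 500, 505, …, 995 nm (`make_default_grid()`).
Cubes move through ENVI rasters (text header + band-sequential float
payload), the de facto HSI interchange format.

## Spectral indices

All indices are built from two primitives:

* `band_mean(s, c(lo, hi))` — the arithmetic mean of the reflectance at all
  grid points with `lo ≤ λ ≤ hi`, **inclusive** at both ends (so 925–935
  covers {925, 930, 935}).
* `second_derivative_mean(s, band)` — the mean over band grid points of the
  central-difference second derivative with `h = 5` nm. An optional 1-D
  Gaussian pre-smoothing along the spectral axis is exposed (`sigma`, in
  band units); it is **off by default**, so the estimator is exactly the
  central difference; `sigma = 1` is the recommended value when it is
  enabled for noisy single-pixel spectra. Note that an absorption *dip*
  has positive curvature at its minimum, so a deeper dip centered in a band
  *raises* the band's curvature mean.

The indices:

| Index | Definition | Responds to |
|---|---|---|
| LWR | `band_mean(925–935) / band_mean(965–985)` | ratio of lipid to water band reflectance |
| TWI (raw) | `band_mean(875–895) / band_mean(950–975)` | tissue water (water absorption depresses the denominator) |
| TLI (raw) | `second_derivative_mean(925–935)` | lipid band curvature |
| StO2 (raw) | `second_derivative_mean(575–590) / second_derivative_mean(740–780)` | hemoglobin band curvature against a reference band |

A direction note on LWR: because absorption lowers reflectance, deepening
the water dip *raises* LWR (it lowers the denominator) and deepening the
lipid dip lowers it. On the affected limb — more water, less lipid — LWR is
therefore *higher* than on the unaffected limb, and the interlimb difference
ΔLWR = LWR(affected) − LWR(unaffected) grows with severity. This is exactly
the behaviour visible in the affected/unaffected spectral ratio (a relative
peak near 920 nm and a dip near 970 nm), and it fixes the staging sign:
`run_cohort()` stages `staging_direction * d_lwr` with
`staging_direction = +1` by default (the flag exists for instruments or
band conventions where the direction reverses).

The instrument vendor's affine constants that map raw index values onto the
familiar 0–100 display scale are proprietary. `index_scaling()` therefore
supplies documented defaults chosen so that a featureless (water- and
hemoglobin-free) spectrum scores near 0, and they are overridable. The
scaled values exist only for display and for background segmentation; every
scientific output (interlimb deltas, staging, statistics) uses raw,
unscaled values, so no conclusion depends on these constants. For the same
reason the deltas are computed on raw values: a difference of an affine map
would only rescale them.

The lipid band is 925–935 nm, the band-definition table's value; an
alternative statement of 920–935 nm appears in figure text, and the band is
an argument (`index_bands()`) for users who prefer it.

## Background segmentation

Body parts are imaged on a matte black surface. The segmentation feature
map is the sum of the (5 × 5 Gaussian-filtered, each-divided-by-its-own-
maximum) scaled TWI and StO2 images, giving values in [0, 2]: inert
background scores near 0, perfused water-bearing tissue near 2. The "(5, 5)
kernel" is interpreted as a 5 × 5 pixel support; the standard deviation is
not fixed by that phrase, so it is exposed (`kernel_sigma`, default 1 px,
which resolves the kernel well inside its support).

When the histogram of fused values is bimodal — one mode per class, the
usual case — the threshold comes from Otsu's method on a fixed 256-bin
histogram over [0, 2] (fixed binning keeps the threshold deterministic).
When the between-class variance is maximized on a plateau of cuts (the
empty gap between two well-separated classes) the plateau midpoint is
returned, which centers the threshold in the gap. Otherwise — no body in
the frame, or body filling the frame — a fixed fallback threshold of 1.0
(the midpoint of the fused range) is used and recorded as such.

Bimodality itself is not defined by the source description, so the package
commits to a simple deterministic rule (`is_bimodal()`): a 64-bin
histogram, smoothed with a 5-bin moving average, is bimodal when two local
maxima — each at least 5 % of the highest mode, so stray counts in a tail
do not qualify — are separated by a valley dipping at least 20 % below the
smaller of the two. The bin count, smoothing window, prominence and
minimum-peak fraction are all arguments.

Each site is acquired three times; `select_best_repeat()` keeps the repeat
whose body mask covers the largest fraction of the central region (the same
disk used for ROI analysis, aligning selection with what is analyzed), with
ties resolved to the earliest repeat.

## ROI spectra and interlimb deltas

Analysis happens in a central circular region of interest, 100 px across on
the full frame (about 4.6 cm of tissue at the 50 cm capture distance). With
0-based pixel centers the image center is `((H−1)/2, (W−1)/2)`; a pixel
belongs to the disk when its center lies strictly within `diameter/2` of
that point. This convention is reflection-symmetric and unambiguous; on
even-dimensioned frames it implies a diameter-1 disk is empty (the center
falls between pixels), which the tests pin down.

Every pixel spectrum in the body ∩ ROI intersection is L1-normalized
(divided by its summed intensity) *first*, then the normalized spectra are
averaged. The order matters — it removes pixel-level illumination
differences before averaging — and indices are computed from this one
average spectrum, not averaged over per-pixel indices (the two differ on
heterogeneous tissue; a test asserts the pipeline uses the former). An
empty intersection yields a measurement flagged missing, never a silent
zero spectrum.

## Staging and statistics

The spectral stage is obtained by agglomerative clustering of the scalar
severity values (ΔLWR, affected sites only) with Ward linkage
(`ward.D2` on 1-D Euclidean distances), cut at `k = 3` and relabeled
low/mid/high by ascending cluster mean. Ward linkage is the default because
its merge criterion minimizes within-cluster variance, the natural notion
of grouping for scalar severity values; on well-separated data it recovers
the optimal contiguous partition, which a dynamic-programming oracle
verifies on 200 random fixtures in the test suite. `complete` and
`average` linkage are available as alternatives.

The statistics layer provides:

* `spearman()` — rank correlation (mid-ranks), fronting `stats::cor`;
* `mann_whitney_u()` — two-sided; exact null distribution of U for
  tie-free samples with `min(n1, n2) ≤ 8` (the stage groups of a cohort
  this size live near that boundary), normal approximation with tie and
  continuity corrections otherwise;
* `normality_omnibus()` — the D'Agostino–Pearson K² omnibus (transformed
  skewness + kurtosis against χ² with 2 df), flagged unreliable below
  n = 20;
* `min_detectable_r(n, alpha, power)` — the Fisher-z minimum detectable
  correlation `tanh((z[1−α/2] + z[power]) / sqrt(n − 3))`; for n = 58,
  α = 0.05, power = 0.80 this gives 0.36.

## The synthetic cohort

The generator is the package's stand-in for patient data and defines the
study conditions:

* **Spectral model** — a low-order polynomial reflectance baseline times
  Gaussian absorption dips (hemoglobin at 542/576 nm, lipid at 930 nm,
  width 15 nm; water at 970 nm, width 30 nm) plus per-band Gaussian noise,
  clipped positive. This is the minimal structure that reproduces the
  affected/unaffected ratio signature and monotone index responses.
* **Scene model** — an elliptical body region on a low-reflectance
  background, with the ground-truth mask recorded; triplicate repeats share
  the tissue model and differ in framing jitter and noise.
* **Cohort model** — 58 patients with ISL stage counts 11/13/28/6
  (stages 0–III), three sites per arm, both sides, in triplicate.
  Physician-flagged ("affected") sites per patient default to 1/1/2/2 by
  stage, roughly matching the published per-stage measurement counts; the
  site-level breakdown is not published, so this is a configuration knob.
  Affected-side water-depth increments and lipid decrements are drawn from
  stage-conditional distributions, with the stage-II spread deliberately
  overdispersed so that stage-II measurements span the full spectral-stage
  range (the heterogeneity the staging is meant to expose). Stage-correlated
  clinical covariates (circumference, cutis/subcutis thickness, two-point
  discrimination, mobility, questionnaire items) are emitted in the CSV
  schema the statistics layer consumes.

Effect-size defaults are *calibrated, not predicted*: they were tuned once
so that the default cohort yields stage correlations of realistic strength
(mean over seeds ≈ 0.64 for the spectral stage, ≈ 0.56 for cutis %, the
committed values in `cohort_config()$target_spearman_hsi/_cutis`), and are
committed as configuration. Regression tests assert recovery within ±0.1 of
the calibrated target; the test suite also checks the zero-effect null
(association below the detectable-correlation bound in ≥ 80 % of seeds).

What the generator does **not** emulate: melanin/skin-tone variation,
specular highlights and shadowing, curvature-dependent illumination,
radiative-transfer realism, instrument calibration drift. Passing tests on
synthetic cohorts therefore demonstrate the correctness and internal
consistency of the algorithms under the stated generative assumptions, not
clinical performance.

## Problem sizes and runtime choices

The generator supports the instrument's full 640 × 480 frame (used to pin
down the acquisition format) and a 64 × 48 small-frame mode with a
proportionally scaled ROI disk (10 px), which is the default in
`cohort_config()` and is used for the cohort-level and segmentation test
runs. A full 58-patient cohort — 1044 small-frame cubes through
segmentation, repeat selection, ROI extraction and staging — completes in
about a minute. The cohort object stores per-measurement seeds instead of
materialized cubes; `realize_measurement()` regenerates any triplicate
bit-exactly on demand. A spectra-level fast path
(`measurement_roi_spectrum()`) draws the ROI pixel spectra directly —
identical to the image path from the representative spectrum onward — and
is used where many whole cohorts are needed (e.g. the 50–100-seed null
calibration), where image formation would add nothing to what is measured.

## Known limitations

* The 0–100 display scalings are documented stand-ins for proprietary
  constants; only raw values should be compared across instruments.
* The bimodality rule is a pragmatic commitment; pathological histograms
  (three modes, heavy tails) may take the fallback path.
* `hsi_stage()` labels are only guaranteed monotone in the value for
  well-separated data; the DP oracle comparison in the tests documents the
  regime in which Ward agrees with the optimal contiguous partition.
* Reproducing the published patient-level correlation figures requires the
  study's released source tables, which are not redistributable here;
  `published_table_correlations()` accepts such a table directly.
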