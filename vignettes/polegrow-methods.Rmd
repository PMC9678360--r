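---
title: "Quantifying asymmetric polar growth: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying asymmetric polar growth: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polegrow)
library(dplyr)
```

## The biological problem

Mycobacteria elongate by inserting new cell wall at their poles rather than
along their side walls, and they do so unequally: the established growth
pole inherited from an earlier generation (the *old pole*) extends faster
than the pole created at the most recent division (the *new pole*). This
asymmetry makes every division produce two physiologically distinct
daughters, and it is actively regulated — deleting regulators such as LamA
redistributes growth toward the new pole, while polar factors such as PgfA
concentrate at the old pole, partially relocalize to the septum late in the
cell cycle, and vanish from the division site before the next generation
begins.

Measuring this from time-lapse microscopy requires a chain of small,
well-defined computations: pole identity must be assigned from lineage
(which end of a daughter was the mother's septum), axial fluorescence
profiles must be extracted and oriented new pole → old pole, per-cell
kymographs must be normalized onto a common (cell-cycle time × relative
length) grid before averaging, single-timepoint populations are displayed
as brightest-pole demographs, pulse-chase images yield per-pole growth
lengths, and replicate-level statistics ("super plots") decide whether
strains differ. `polegrow` implements this chain as composable
tidyverse-style functions, together with a lineage simulator whose recorded
ground truth lets every stage be validated by parameter recovery — no
external images are required to test the code.

## The growth model behind the simulator

The simulator (`sim_config()`, `simulate_lineage()`) uses the simplest
model that makes pole-resolved ground truth exact:

* A cell of length $L$ elongates by a constant $r_{old} + r_{new}$ µm per
  frame, split between the poles in fixed proportion. The old-pole share of
  total elongation is therefore exactly
  $f_{old} = r_{old} / (r_{old} + r_{new})$ for every cell — a closed form
  the tests exploit.
* Division is triggered by length, not by a timer: the cell divides at the
  first frame where $L \ge L_{div}$. With a length trigger, interdivision
  times and per-pole growth are integer-frame quantities that can be
  hand-computed.
* The septum is placed at a relative position drawn from a normal
  distribution truncated to $(0.2, 0.8)$ (mean 0.5, sd 0.05 by default).
  Truncation avoids degenerate near-zero-length daughters while preserving
  the mildly asymmetric division the organism shows.
* Each daughter inherits one pre-existing pole (its `old_pole_age` is the
  mother's incremented, or 2 if it inherits the mother's new pole) and one
  pole born at the septum (age 1). Founder cells have no recorded division,
  so their new/old identity is *unknowable from the data*; they carry
  `founder = TRUE`, are assigned `old_pole_age = 1` by convention, and are
  excluded from all pole-resolved statistics.

Cells also live on a one-dimensional "lab" axis: the left end moves with
whatever pole is on the left, daughters inherit the mother's spatial
orientation, and the recorded interval endpoints are what
`orient_track_new_to_old()` uses to recover pole identity the way a human
tracker would — the daughter end that coincides with the mother's septum
position (within half the mother's length) is the new pole.

Default parameters emulate *M. smegmatis* in a microfluidic device imaged
every 15 minutes at 0.11 µm/pixel: birth at 2.5 µm, division at 5 µm,
elongation 0.19 µm/frame (≈ 3.5 h interdivision time), old-pole share 0.68
for wild-type-like configurations and 0.5 for ΔlamA-like ones. Total
elongation rate is deliberately a free parameter, not constrained to be
conserved between such configurations: strains that redistribute growth
between poles without changing overall rate are modeled by keeping
$r_{old} + r_{new}$ fixed, but nothing enforces this.

### What the renderer emulates — and what it does not

`render_localization_track()` draws one axial profile per frame, new pole →
old pole, at one sample per pixel. Polar programs are terminal Gaussian
spots (sigma 2 px); `midcell_late` adds a septal spot at the cell's future
division site once the cell-cycle fraction passes `septal_onset_fraction`;
polar modes with `septal_transfer_fraction > 0` move that fraction of polar
amplitude to the septum after onset — the old-pole-then-septum program of a
PgfA-like protein. `render_pulse_chase_pair()` draws the birth profile
fully labeled and the pre-division profile with unlabeled margins equal to
the recorded per-pole growth. `render_frame_image()` renders spherocylinder
footprints with an isotropic Gaussian PSF.

Real data differ in ways the simulator does not attempt to capture:
photobleaching, focus and stage drift, segmentation errors in crowded
fields, diffraction-limited spot shapes, autofluorescence gradients, and
biological correlations between growth rate and cell size. Passing the
recovery tests therefore demonstrates that the *analysis chain* is correct
and unbiased under its stated assumptions, not that it is robust to every
artifact of real microscopy. The segmentation provided
(`segment_frame()`: Otsu threshold + connected components, border and
minimum-area filters) is intentionally minimal and aimed at the synthetic
frames; for real crowded micrographs a dedicated tool should produce the
masks, which the rest of the chain consumes unchanged.

## Profile extraction and orientation

`extract_axial_profile()` mirrors a hand-drawn segmented-line measurement:
the medial axis is computed by morphological thinning, pruned to its
longest geodesic path, extended tangentially to the object boundary, and
resampled at 1-pixel arc-length steps; intensity is averaged across an odd
`width_px` (5 for localization, 7 for pulse-chase profiles) perpendicular
to the local axis direction, with out-of-image samples excluded. No
installed package provides 2-D skeletonization, so the thinning pass is
implemented in the package and applied only to small single-cell masks.

Two orientation rules exist because two kinds of experiment exist:

* **Lineage orientation** (`orient_track_new_to_old()`): time-lapse tracks
  with a recorded mother get their new pole at index 0 from division
  geometry. This is exact on simulated data (the tests require 100%
  correctness on non-founders, and ≥ 99% with noise at 10% of signal).
* **Brightest-pole orientation** (`orient_by_brightest_pole()`): fixed
  single-timepoint populations have no lineage, so profiles are aligned by
  the brighter terminal region — the demograph convention. The comparison
  window is `ceiling(terminal_fraction × length)` samples with
  `terminal_fraction = 0.1` by default (the window is an implementation
  choice; results are insensitive to it for terminal spots). An exact tie
  keeps the original order, which makes the operation an involution.

Background subtraction (median of non-mask pixels, clipped at 0) is exposed
as an option rather than hard-wired, since hand-drawn-profile workflows
differ on whether it is applied before kymograph construction.

## Kymographs as localization-probability maps

`grid_normalize_track()` resamples each frame's profile to `L_bins`
positions on [0, 1] (new pole → old pole) and then resamples along time to
`T_bins` rows, with the $i$-th of $F$ frames at relative time $i/(F-1)$ —
piecewise-linear in both axes, no extrapolation, endpoints mapping exactly
to birth/last-frame and the pole tips. Relative (not absolute) time is
essential: it lets cells with different interdivision times contribute to
one average. The implementation is checked against a brute-force
pointwise bilinear oracle to $10^{-9}$ on random tracks.

`average_kymographs()` first normalizes each cell (default: every time-row
scaled to sum 1) and then takes the pointwise mean. Row-sum normalization
makes the average read as the probability of finding the protein at a given
relative position at a given cycle stage; `"none"` and `"global_max"` are
retained because cross-strain *intensity* comparisons (e.g. old-pole
accumulation with and without a regulator) must not be re-scaled per cell.
Whether the original hand analyses normalized per cell before averaging is
not knowable from a figure; the default here is declared, not inferred.
The default grid (T = 50, L = 100) gives 1% positional bins and oversamples
a multi-hour cycle imaged every 15 min.

`pole_intensity_snapshot()` reduces each cell's kymograph to its new- and
old-pole mean intensity (first/last `ceiling(pole_window × L)` bins) at the
time-row nearest a chosen cycle fraction — the single-timepoint contrast
used to show reduced old-pole accumulation in a deletion strain.

## Demographs

`build_demograph()` stacks brightest-pole-aligned profiles, left-aligned
and right-padded with `NA` (the padding is excluded from every statistic),
sorted ascending by length so length serves as a cell-cycle proxy. Profiles
keep absolute length — normalizing length would erase the very signal the
ordering displays. The sort is stable, so equal-length cells keep input
order, making the construction permutation-invariant up to ties.

## Pulse-chase growth measurement

`measure_polar_growth()` turns a birth/pre-division profile pair into
per-pole growth. The labeled region is the maximal contiguous run of
samples at or above
$\theta = b + t \,(\hat{p} - b)$, where $b$ is background, $t$ the
`threshold_fraction` (default 0.5), and $\hat{p}$ the labeled-plateau level
estimated as the median of the top quartile of samples — an estimator that
ignores both the dim margins and isolated bright noise. The unlabeled
margin at each pole is the distance from the cell end to the nearest run
boundary, and growth is the margin increase from birth to pre-division.

Design choices worth stating:

* The half-plateau rule was chosen over derivative-based edge detection
  because it is bias-stable: on noise-free data the measurement is
  *identical* for any `threshold_fraction` in [0.3, 0.7] (a tested
  invariant), so the default cannot tune the result.
* Growth is floored at 0; negative margins only arise from noise or
  segmentation jitter, and a floor that clips more than 1 px raises the
  `floored_negative` QC flag rather than passing silently.
* Multiple above-threshold runs separated by more than `gap_px` (default
  2) flag the cell `ambiguous_label`; the longest run is still measured so
  cohort counts stay interpretable.
* A profile whose plateau does not exceed background has no detectable
  label boundary and raises an error naming the cell.

The per-cell summaries are the old-pole share
$f_{old} = g_{old}/(g_{old}+g_{new})$ and the asymmetry index
$a = (g_{old}-g_{new})/(g_{old}+g_{new}) \in [-1, 1]$; cells with zero
total polar growth are flagged and excluded rather than dividing by zero.
Growth is exported both in µm and as % of birth length, since either
convention is common.

## Super-plot statistics

Cells from one culture are not independent replicates. `replicate_medians()`
reduces per-cell values to one median per (strain, biological replicate),
and `paired_oneway_anova()` runs a balanced repeated-measures one-way ANOVA
with replicate as the block:

$$SS_{strain} = n\sum_k (\bar{y}_{k\cdot} - \bar{y})^2,\quad
  SS_{block} = k\sum_n (\bar{y}_{\cdot n} - \bar{y})^2,\quad
  F = \frac{SS_{strain}/(k-1)}{SS_{error}/((k-1)(n-1))}.$$

This is the standard reading of a "paired one-way ANOVA" on replicate
medians. For $k = 2$ it reduces exactly to the squared paired $t$
statistic (tested to $10^{-9}$), and the implementation is cross-checked
against `aov()`'s within-block decomposition. Pairwise contrasts against a
reference strain are each $k = 2$ blocks-retained ANOVAs, Holm-adjusted by
default (Bonferroni and none are available); the correction is this
package's documented choice, since starred figure contrasts rarely name
one. With very small $n$ a perfectly consistent table can make
$SS_{error} = 0$; that fit is reported as degenerate ($F = \infty$,
flagged) instead of crashing, and sphericity corrections are out of scope
at such sizes.

```{r anova-example}
tb <- tibble::tibble(strain = rep(c("A", "B"), each = 3),
                     replicate = rep(1:3, 2),
                     median_value = c(1, 2, 3, 2, 4, 3))
glance(paired_oneway_anova(tb))
```

## Numerical and degenerate-input policy

* Profiles are sampled at pixel centers, 0-based, index 0 = new pole;
  distances are kept in pixels internally and converted to µm only in
  reports.
* All interpolation is linear with no extrapolation; exact ties in the
  brightest-pole rule keep input order; the snapshot picks the *nearest*
  time row (first on a tie).
* Empty masks, single-frame tracks, unbalanced designs, unknown
  localization modes, unknown config keys, and unplaceable cells all raise
  typed errors (`polegrow_*` condition classes) naming the offending
  object.
* One seed determines everything: `simulate_lineage()` seeds R's RNG from
  `config$seed`, per-strain/replicate sub-seeds are derived arithmetically
  from the pipeline seed, and `run_pipeline()` writes per-file MD5 digests
  into its manifest so any nondeterminism is detectable. Re-running with
  the same config is byte-identical.

## Problem sizes used in the validation suite

The shipped tests validate at the cohort scales typical of the underlying
experiments, chosen once as realistic for this kind of study: 25-cell
cohorts for average kymographs, 50 cells per condition for pulse-chase
recovery at old-pole shares 0.5–0.8 (recovered medians within ±0.05 with
noise at 5% of signal), 3 replicates × 30 cells for super-plot power (0.7
vs 0.5 contrast detected in ≥ 90% of 50 seeded runs, ≤ 10% false positives
under the null), and 194–335-cell demographs are represented by 30-cell
noise-free cohorts for the structural contract. One caveat found during
validation: at these noise levels the within-replicate medians of the
old-pole share are extremely stable, so the null distribution of the
super-plot F statistic is strongly discrete (often exactly 0); the
false-positive bound holds, but its estimate is conservative rather than a
calibration check of the F approximation.

## Limitations

* The growth model is deterministic given division events; it has no
  per-cell rate variability, lag phases, or new-end take-off dynamics, so
  it cannot be used to study growth-rate *distributions*.
* Orientation recovery consumes recorded division geometry; it does not
  re-track cells from raw images.
* The simulator's images are a rendering of the model, not a physics
  simulation of the microscope; segmentation robustness on real data is
  explicitly out of scope.
* The repeated-measures ANOVA requires a balanced design — every strain
  present in every replicate — by construction, matching the paired
  experimental design it serves.
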