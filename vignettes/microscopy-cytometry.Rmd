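---
title: "Microscopy-based cytometry: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microscopy-based cytometry: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microcyto)
library(dplyr)
```

## The problem

Flow cytometry is the standard for per-cell fluorescence statistics, but it
requires dedicated hardware and destroys the spatial context of adherent
cultures. An ordinary widefield microscope can substitute for it if each
adherent cell can be segmented reliably from a brightfield image: apply the
segmentation mask to the fluorescence channels, average the pixels inside
each segment, and every cell becomes one "event" in a flow-like table.
`microcyto` implements that pipeline end to end:

1. **Segment** a brightfield (or nuclear-stain) image into a label mask.
2. **Filter** the mask: remove border-touching segments, then size-gate the
   rest against a normal fit of the segment-area distribution.
3. **Quantify** per-cell mean intensities in every channel.
4. **Gate** cells positive/negative against a high percentile of a
   non-fluorescent control population.
5. **Summarize**: SNR/CV of a fluorescent population, doublet rates from
   two-color mixes, and per-condition efficiency/survival tables for plate
   screens.

Every stage is verifiable against the synthetic generators in the package,
which produce ground-truth masks and intensities, so nothing here requires a
microscope, a trained model, or a download.

## Segmentation and its two parameters

Modern cell segmenters expose two dominant parameters: an expected **object
diameter** in pixels (models are trained at a fixed scale) and a **flow
threshold** bounding the mismatch between predicted flows and candidate
segments. The package treats the segmenter as pluggable: `segment()`
dispatches `model = "cyto"` or `"nuclei"` to a user-registered Cellpose
adapter (an optional extra, `options(microcyto.cellpose_adapter = ...)`),
and `model = "fallback"` to a built-in classical pipeline that needs no
trained weights:

smooth (Gaussian, σ = diameter/8) → Otsu threshold (minority class as
foreground, which handles both bright objects and dark cell rims) → hole
filling → Euclidean distance transform → seeds at local maxima separated by
at least diameter/2 → seeded watershed, labels in raster order of seeds.

The fallback consumes only the diameter; it is fully deterministic and is
what all tests run against. The smoothing σ and the seed-separation radius
are clamped to the image size so that diameters comparable to the field of
view remain well-defined. Automatic diameter estimation is deliberately not
a default anywhere: on brightfield data it can underestimate the true
diameter severely, and the diameter is the single most influential setting —
users should always set it from their own images.

Two caveats of the fallback worth knowing:

* It relies on edge contrast. Brightfield images of fully adherent cells
  often lack it; a brief trypsinization markedly increases rim contrast
  without detaching the cells, and the synthetic generator emulates exactly
  that regime (a dark rim on a flat background).
* Hole filling can flood background regions that are *completely enclosed*
  by cell rims. Regular lattice arrangements of synthetic cells can create
  such enclosures; randomly placed cells essentially never do. Real fields
  are not lattices, so this matters for constructing fixtures, not for use.

## The edge and size filters

Border-touching segments (any pixel in the first/last row or column,
including single corner pixels) are removed first: partially imaged cells
bias both areas and intensities, and removing them before the size fit keeps
clipped cells from perturbing the Gaussian.

The size filter is two-stage: a hard prefilter discards very small segments
(default 2000 px, tied to 60× sampling; `scale_min_area()` scales it by
(magnification/60)² for other objectives, our convention since no reference
values exist for 10×/20×), then a normal distribution is fitted to the
remaining areas and segments outside `n_sd` (default 2) standard deviations
of the mean are dropped. The "fit" is moment matching — sample mean and
sample SD with ddof = 1 — which coincides with the Gaussian MLE up to the
variance denominator and is fully deterministic. With fewer than 3 segments
after the prefilter the band is skipped with a warning (σ is undefined or
degenerate) and the prefiltered segments are kept.

Two properties of this filter deserve explicit statement because they are
easy to get wrong:

* **Small-sample impotence.** No point of an n-sample can lie more than
  (n−1)/√n sample SDs from the sample mean, so for n ≤ 5 a 2-SD band can
  never reject anything — a single gross outlier among four normal segments
  passes. The filter is designed for images with dozens-to-hundreds of
  segments, where it does reject outliers; tests cover both regimes.
* **Fixed-threshold idempotence, refit non-idempotence.** Applying the
  *fitted* band twice is the identity. *Refitting* on the surviving
  segments is not idempotent in general: trimming a normal at ±2σ shrinks
  the refitted SD to ≈ 0.88σ, so borderline segments can drop on a second
  pass. The pipeline therefore fits thresholds once per image and applies
  them once.

## Scoring segmentation against nuclei

Nuclear-stain masks serve as the per-cell reference: nuclei of adjacent
cells are usually separated even when cytoplasms touch, and nuclei-model
segmentation is far more robust than brightfield. `quality_metrics()`
reports three numbers for a candidate mask against a reference mask:

* segments/nucleus — candidate count over reference count (1 = count-accurate);
* FN ratio — fraction of reference nuclei with no candidate segment falling
  within them (missed cells), normalized by the reference count;
* FP ratio — fraction of candidate segments containing no nucleus (spurious
  segments), normalized by the candidate count.

"Falls within" defaults to **any-pixel overlap**, which is robust to the
nucleus occupying only ~80–90% of the cell area; centroid containment is
available as `criterion = "centroid"` and the choice is recorded in the
output. Each ratio is normalized by the population it describes so both stay
in [0, 1]; the denominators are our convention, stated here because they are
not standardized. These are deliberately not IoU/AP instance metrics — they
are designed to catch exactly two failure modes: several segments per cell,
and no segment per cell.

`parameter_screen()` sweeps a diameter × flow-threshold grid (default 25
evenly spaced diameters on [25, 505] px × 21 flow thresholds on
[0.05, 2.05], i.e. 525 combinations), applies the full filter chain at each
grid cell, scores against precomputed reference masks, and averages metrics
across images with equal weight per image. Segmentations are cached per
unique parameter set the active model actually consumes — the fallback
ignores the flow threshold, so each diameter is segmented once and reused
across the 21 flow columns, a pure speed optimization with identical
results.

## From masks to events

`extract_cell_records()` applies the mask to every channel and computes, per
segment, the sum of in-segment pixel values divided by the pixel count. No
background subtraction is performed by default (an optional out-of-segment
median subtraction exists but is off); no rescaling happens anywhere in
I/O, so values remain camera counts per pixel. Coordinates in all outputs
are 0-based (row, col) pixels, and areas are pixel counts — physical units
are carried only as metadata.

**Gating.** The positivity threshold per channel is the 99.9th percentile
(configurable) of the per-cell mean intensities of a non-fluorescent control
population, computed with linear interpolation between order statistics
(`quantile(type = 7)`; the method choice moves the threshold by less than
one order statistic). Positivity is strict `>`, so ties are negative. By
construction ~0.1% of true negatives gate positive; the package warns below
1000 control cells because the tail percentile is poorly resolved there —
with, say, 6 control cells, the threshold interpolates just below the
control maximum and the top control cell itself flags positive.

**SNR and CV.** `signal_stats()` implements
snr = (mean⁺ − mean⁻)/sd⁻ and cv = sd⁺/(mean⁺ − mean⁻), sample SDs
throughout (ddof = 1, which matters at small n). Both are invariant under
any positive affine intensity map applied to both populations, which is
exactly why `normalize_to_reference()` — the unique order-preserving affine
map sending the observed group means onto reference means — can place
different instruments on one scale without distorting either statistic.

**Doublet rate.** In a two-color mix with mix fraction p, only heterotypic
doublets are double-positive, and a doublet is heterotypic with probability
2p(1−p). `doublet_rate(frac_double, p)` therefore returns
frac_double/(2p(1−p)); at p = 0.5 this is exactly twice the double-positive
fraction, since half of the doublets arise from two cells of the same color.
A cell positive in both channels counts toward frac_double regardless of
intensity magnitudes (no unmixing), and the fraction is computed over all
gated cells. The estimator generalizes the 50/50 argument to any p and is
minimized at p = 0.5 for fixed frac_double.

**Plate screens.** `screen_summary()` reports per condition: cell count,
positive fraction (the editing-efficiency readout), total positives (which
integrates efficiency and proliferation and is the practical metric for
tagging throughput), and cell count relative to a no-plasmid control
(survival). Cells from all images of a well are pooled unweighted.

## The synthetic generators: what they emulate, and what not

`make_field()` renders elliptical cells (area-preserving random axis ratio
and orientation, jittered diameter) with concentric elliptical nuclei
scaled to a nucleus/cell area fraction of 0.85 by default — the middle of
the 80–90% range typical of HEK-like cells. The brightfield-like channel is
a flat background with a dark rim at every label boundary, including
cell–cell interfaces, mimicking the edge contrast of briefly trypsinized
cells. Fluorescence channels carry one log-normal per-cell true mean
(positive, right-skewed, like real expression distributions) constant
across the cell, plus Gaussian read noise clipped at zero; Poisson shot
noise, point-spread blur, depth of field, texture and out-of-focus light
from stacked cells are deliberately **not** modeled. Consequently, passing
tests demonstrate the correctness of the measurement and statistics chain,
not segmentation performance on realistic optics — that is what the
Cellpose adapter and real images are for. Placement is integer-coordinate
rejection sampling under a minimum center distance (10⁴ attempts, then a
placement error naming the density); `min_center_distance` switches between
well-separated and partially overlapping regimes, and a doublet fraction
merges pairs of ellipses under one label with summed fluorescence.

`make_mixing_experiment()` is record-level: each cell is a doublet with
probability r; each parent is population A with probability p; doublet
channel values are sums of two independent parents. Intensities are
log-normal: positives at meanlog = log 500, sdlog = 0.5; autofluorescence at
meanlog = log 10, sdlog = 0.8. The background width is a deliberate choice:
the gate sits at the 99.9th percentile of *single-cell* background, while a
homotypic doublet's background channel is the *sum of two* background draws.
A broad log-scale tail (sdlog 0.8) puts that percentile far above twice the
median, keeping P(background sum > gate) at ~0.3%, so double-positives are
dominated by heterotypic doublets — the assumption behind the ×2 rule. A
narrow background (e.g. sdlog 0.1) would invert this and the estimator would
be badly biased; that regime is physically implausible for fluorescence
backgrounds, which spread multiplicatively.

`make_screen_plate()` draws per-well cell counts as Poisson around a
control count times a proliferation surface (decreasing in MLH1dn dose,
emulating its dose-dependent suppression of proliferation) and positives as
binomial with an efficiency surface peaking at a low editor dose and an
intermediate MLH1dn dose. The default 8 × 11 = 88-condition grid spans PE
doses 5–85 ng and MLH1dn doses 0–77 ng per well. Tests compare recovered
quantities against the returned truth surfaces rather than against
hard-coded optima.

## Worked example

```{r example}
field <- make_field(field_spec(shape = c(300, 300), n_cells = 10,
                               diameter_px = 40, margin = 25,
                               min_center_distance = 55, noise_sd = 1,
                               seed = 42))
mask <- segment(field$stack$channels$brightfield,
                segmenter_params(diameter_px = 40, model = "fallback"))
filt <- apply_segment_filters(mask, min_area_px = 500, n_sd = 2)
quality_metrics(filt$mask, field$cell_mask)

records <- extract_cell_records(filt$mask, field$stack,
                                well = "A1", condition = "demo")
head(dplyr::select(records, cell_id, area_px, mean_mNG), 3)
```

```{r doublet}
# the two-color mixing arithmetic: 0.90% double-positive, 50/50 mix
doublet_rate(frac_double = 0.0090, mix_fraction_a = 0.5)
```

## Numerical choices and degenerate inputs

* Percentiles: linear interpolation (`type = 7`); SDs: ddof = 1 everywhere.
* Ties at the gate are negative (strict `>`).
* Watershed seed ties are resolved by raster-order seed labeling, making the
  fallback segmenter bit-deterministic.
* Constant images segment to an empty mask rather than erroring; empty masks
  produce empty (not missing) statistics tables.
* Label masks round-trip exactly through TIFF: 16-bit integer pages up to
  65535 labels, 32-bit pages (scaled by 2⁻²⁴, exact for all labels < 2²⁴)
  beyond that; filters delete labels without relabeling so cell identity is
  traceable across stages.
* `normalize_to_reference()` refuses equal group means (degenerate map) and
  oppositely ordered references (the order-preserving map would need a < 0).
* All generator randomness is funneled through a single integer seed; the
  same spec yields bit-identical output.

## Problem sizes used in the test suite

The suite exercises the full 525-combination screen on one 256×256
synthetic pair (caching makes this 25 segmentations), mixing experiments of
20,000–50,000 cells with 20,000-cell controls, 88-condition plates at
400–2000 cells per control well, 200 randomized 64×64 oracle-equivalence
fixtures, and density series up to 22 cells per 560×560 field. These sizes
were chosen to give every statistical assertion a 3–4σ margin under its
stated tolerance while keeping the whole suite near a minute of runtime.

## Known limitations

* The FCS reader is minimal by design: FCS 3.0/3.1, list mode, float or
  uniform-width integer data, no compensation, no transformation, no
  writing. Files using `$DATATYPE D/A`, correlated mode, or mixed integer
  widths raise explicit unsupported-feature errors.
* The fallback segmenter is an edge-based classical method; it will not
  match a trained model on low-contrast adherent cells and is not meant to.
* FN/FP scoring against nuclei cannot detect a wrong cytoplasmic boundary
  that still contains the nucleus; it is a counting metric.
* The doublet estimator assumes doublets pair cells independently of color
  and that double-positivity is driven by heterotypic doublets; strongly
  correlated seeding or heavy background violates it.
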