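# microcyto

Flow-cytometry-like single-cell fluorescence analysis from ordinary
microscope images of **adherent cells**.

Flow cytometry gives per-cell fluorescence statistics but needs dedicated
hardware and a cell suspension. For adherent cultures, a widefield
microscope can do the same job if each cell can be segmented from a
brightfield image: apply the segmentation mask to the fluorescence
channels, average the pixels inside each segment, and every cell becomes
one event in a flow-like table. `microcyto` is for cell biologists and
screening labs who want that pipeline — segmentation, filtering, per-cell
quantification, gating, and screen summaries — as composable, tested R
functions with tibble inputs and outputs.

## What it computes

* **Segmentation** (`segment()`): pluggable segmenter — a Cellpose adapter
  for the `cyto`/`nuclei` models (optional extra), or a built-in
  deterministic watershed pipeline (`model = "fallback"`): Gaussian smooth
  (σ = d/8) → Otsu → hole filling → distance transform → seeds ≥ d/2 apart →
  seeded watershed.
* **Filters**: border-touching segments removed
  (`remove_edge_segments()`); then a hard minimum-area prefilter (default
  2000 px at 60×) and a Gaussian size band — fit N(μ, σ) to the remaining
  segment areas by sample moments and keep areas in μ ± 2σ
  (`size_filter()`, `apply_segment_filters()`).
* **Segmentation quality vs a nuclei reference** (`quality_metrics()`):
  segments/nucleus = n_cand / n_ref, FN ratio = #{nuclei with no
  overlapping segment}/n_ref, FP ratio = #{segments overlapping no
  nucleus}/n_cand; plus the full diameter × flow-threshold screen
  (`parameter_screen()`, default 25 × 21 = 525 combinations on
  [25, 505] px × [0.05, 2.05]).
* **Per-cell quantification** (`extract_cell_records()`): mean intensity =
  in-segment pixel sum / pixel count, no background subtraction by default.
* **Gating** (`compute_gates()`, `apply_gates()`): threshold per channel =
  99.9th percentile of a non-fluorescent control population; positive iff
  mean intensity > threshold.
* **Signal statistics** (`signal_stats()`):
  `snr = (mean⁺ − mean⁻)/sd⁻`, `cv = sd⁺/(mean⁺ − mean⁻)` (sample SDs),
  and the affine cross-instrument normalization
  (`normalize_to_reference()`) under which both are invariant.
* **Doublet rate** (`doublet_rate()`): in a two-color mix with mix fraction
  p, doublet rate = double-positive fraction / (2p(1−p)) — twice the
  double-positive fraction for a 50/50 mix.
* **Plate screens** (`screen_summary()`): per condition, the positive-cell
  fraction (editing efficiency), total positives, and cell counts relative
  to a no-plasmid control (survival).
* **Synthetic ground truth** (`make_field()`, `make_mixing_experiment()`,
  `make_screen_plate()`): elliptical cells with concentric nuclei, dark-rim
  brightfield, log-normal per-cell fluorescence, controllable density and
  doublet fraction — every stage is testable offline.
* **I/O**: multi-page TIFF stacks and label masks (exact integer
  round-trips), CSV event tables, YAML plate configs, and a minimal
  FCS 3.0/3.1 reader (`read_fcs()`) for flow comparisons.

## Worked example

```r
library(microcyto)

# a ground-truthed synthetic field: 10 cells, diameter 40 px, mild noise
field <- make_field(field_spec(shape = c(300, 300), n_cells = 10,
                               diameter_px = 40, margin = 25,
                               min_center_distance = 55, noise_sd = 1,
                               seed = 42))

mask <- segment(field$stack$channels$brightfield,
                segmenter_params(diameter_px = 40, model = "fallback"))
filt <- apply_segment_filters(mask, min_area_px = 500, n_sd = 2)
quality_metrics(filt$mask, field$cell_mask)
#> # A tibble: 1 × 6
#>   n_candidate n_reference segments_per_nucleus fn_ratio fp_ratio criterion
#>         <int>       <int>                <dbl>    <dbl>    <dbl> <chr>
#> 1           9          10                  0.9      0.1        0 overlap
```

All ten cells were segmented, but the smallest (1471 px against a fitted
size distribution of 2114 ± 301 px) fell below the μ − 2σ band and was
removed by the size filter, leaving segments/nucleus 0.9 and FN 0.1; no
spurious segments were called (FP 0). Quantify and inspect events:

```r
records <- extract_cell_records(filt$mask, field$stack,
                                well = "A1", condition = "demo")
head(dplyr::select(records, cell_id, area_px, mean_mNG), 3)
#> # A tibble: 3 × 3
#>   cell_id area_px mean_mNG
#>     <int>   <int>    <dbl>
#> 1       1    2352     56.2
#> 2       2    2224     36.4
#> 3       3    2029     41.0
```

The doublet-rate arithmetic for a two-color 50/50 mix, and a full simulated
recovery: 20,000 cells with a 5% injected doublet rate, gated at the 99.9th
percentile of 20,000 non-fluorescent controls:

```r
doublet_rate(frac_double = 0.0090, mix_fraction_a = 0.5)
#> [1] 0.018

spec <- mix_spec(n_cells = 20000, mix_fraction = 0.5, doublet_rate = 0.05,
                 control_n = 20000, seed = 1)
mx <- make_mixing_experiment(spec)
gates <- compute_gates(mx$controls, percentile = 99.9)
mixing_summary(mx$records, gates, spec$channels, spec$mix_fraction)
#> # A tibble: 1 × 6
#>   n_cells frac_pos_a frac_pos_b frac_double mix_fraction_a doublet_rate
#>     <int>      <dbl>      <dbl>       <dbl>          <dbl>        <dbl>
#> 1   20000      0.514      0.510       0.026            0.5        0.052
```

2.6% of cells gated double-positive, giving a doublet-rate estimate of
5.2% against the injected 5%. Throughput planning: at ~3,300 analyzable
cells per 10× field, matching a 50,000-cell flow run takes

```r
fields_per_well(cells_per_image = 3300, target_cells = 50000)
#> [1] 16
```

images per well. A thin command-line front end over the same functions
lives at `inst/cli/microcyto.R`
(`Rscript microcyto.R <simulate|segment|quantify|screen-params|pipeline> ...`),
and `run_pipeline()` executes a whole configured plate (segment → filter →
quantify → gate) writing `events.csv`, `metrics.csv` and a reproducibility
manifest.

See the vignette (`vignettes/microscopy-cytometry.Rmd`) for the models,
parameter conventions, numerical choices and known limitations.

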