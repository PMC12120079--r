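# Per-cell fluorescence quantification and all downstream cytometry
# statistics: percentile gating, SNR/CV, cross-instrument normalization,
# doublet-rate estimation, and plate-screen summaries.

#' Extract per-cell event records from a mask and a channel stack
#'
#' The segmentation mask is applied to every channel to exclude all data
#' outside segments; for each segment and channel the mean intensity is the
#' sum of in-segment pixel values divided by the segment's pixel count. No
#' background subtraction is performed by default (set
#' `background_subtract = TRUE` to subtract the per-channel median of
#' out-of-segment pixels).
#'
#' @param mask Integer label matrix.
#' @param stack A [channel_stack()] with the same dimensions as `mask`.
#' @param well Well identifier recorded in each row.
#' @param condition Condition label recorded in each row.
#' @param background_subtract Subtract the median out-of-segment pixel value
#'   per channel. Off by default.
#' @return Tibble ordered by label: `cell_id`, `well`, `condition`,
#'   `area_px`, `centroid_row`, `centroid_col` (0-based), and one
#'   `mean_<channel>` column per channel (counts/pixel).
#' @export
extract_cell_records <- function(mask, stack, well = "well1", condition = NA_character_,
                                 background_subtract = FALSE) {
  mask <- assert_label_mask(mask)
  stopifnot(inherits(stack, "channel_stack"))
  if (!identical(dim(mask), dim(stack)))
    stop_value("mask and channel stack must share the same shape")
  stats <- compute_segment_stats(mask)
  base <- tibble(cell_id = stats$label, well = well, condition = condition,
                 area_px = stats$area_px,
                 centroid_row = stats$centroid_row,
                 centroid_col = stats$centroid_col)
  if (nrow(stats) == 0) {
    for (ch in names(stack$channels)) base[[paste0("mean_", ch)]] <- double()
    return(base)
  }
  inside <- mask > 0
  lab <- mask[inside]
  idx <- match(lab, stats$label)
  for (ch in names(stack$channels)) {
    v <- stack$channels[[ch]][inside]
    sums <- unname(rowsum(v, idx)[, 1])
    m <- sums / stats$area_px
    if (background_subtract) {
      bg <- stats::median(stack$channels[[ch]][!inside])
      if (is.na(bg)) bg <- 0
      m <- m - bg
    }
    base[[paste0("mean_", ch)]] <- m
  }
  base
}

#' Compute percentile gating thresholds from a control population
#'
#' The positivity threshold for each channel is a high percentile (default
#' 99.9) of the per-cell mean intensities of a non-fluorescent control
#' population (e.g. the parental cell line), so that by construction about
#' `100 - percentile` percent of true negatives are flagged positive.
#' Percentiles use linear interpolation between order statistics
#' (`quantile(type = 7)`).
#'
#' @param control_records Tibble of control-cell records with
#'   `mean_<channel>` columns.
#' @param channels Channels to gate; default all `mean_*` columns present.
#' @param percentile Percentile in `(0, 100)`; default 99.9. A warning is
#'   issued when fewer than 1000 control cells are available, because the
#'   99.9th percentile is poorly resolved below that.
#' @return Object of class `cyto_gates`: tibble (`channel`, `threshold`) with
#'   attributes `control_n` and `percentile`. [tidy()] returns the thresholds,
#'   [glance()] the attributes.
#' @export
compute_gates <- function(control_records, channels = NULL, percentile = 99.9) {
  control_records <- as_tibble(control_records)
  if (nrow(control_records) == 0)
    stop_value("control population is empty")
  if (percentile <= 0 || percentile >= 100)
    stop_value("`percentile` must be in (0, 100)")
  if (is.null(channels))
    channels <- sub("^mean_", "", grep("^mean_", names(control_records), value = TRUE))
  if (length(channels) == 0) stop_value("no channels to gate")
  if (nrow(control_records) < 1000)
    warn(sprintf("compute_gates: only %d control cells; the %.6g-th percentile is poorly resolved below 1000",
                 nrow(control_records), percentile))
  thresholds <- map_dbl(channels, function(ch) {
    col <- paste0("mean_", ch)
    if (!col %in% names(control_records))
      stop_key(paste0("control records lack column ", col))
    unname(quantile(control_records[[col]], percentile / 100, type = 7, names = FALSE))
  })
  out <- tibble(channel = channels, threshold = thresholds)
  attr(out, "control_n") <- nrow(control_records)
  attr(out, "percentile") <- percentile
  class(out) <- c("cyto_gates", class(out))
  out
}

#' @export
tidy.cyto_gates <- function(x, ...) {
  tibble(channel = x$channel, threshold = x$threshold)
}

#' @export
glance.cyto_gates <- function(x, ...) {
  tibble(control_n = attr(x, "control_n"), percentile = attr(x, "percentile"),
         n_channels = nrow(x))
}

#' Apply gating thresholds to cell records
#'
#' A cell is positive in a channel iff its mean intensity is strictly greater
#' than the channel threshold; ties are negative.
#'
#' @param records Tibble with `mean_<channel>` columns.
#' @param gates A `cyto_gates` object from [compute_gates()].
#' @return `records` with one logical `positive_<channel>` column per gated
#'   channel.
#' @export
apply_gates <- function(records, gates) {
  stopifnot(inherits(gates, "cyto_gates"))
  records <- as_tibble(records)
  for (i in seq_len(nrow(gates))) {
    ch <- gates$channel[i]
    col <- paste0("mean_", ch)
    if (!col %in% names(records))
      stop_key(paste0("records lack column ", col, " for gated channel ", ch))
    records[[paste0("positive_", ch)]] <- records[[col]] > gates$threshold[i]
  }
  records
}

#' Signal-to-noise ratio and coefficient of variation
#'
#' `snr = (mean(pos) - mean(neg)) / sd(neg)` and
#' `cv = sd(pos) / (mean(pos) - mean(neg))`: the background-corrected CV.
#' Standard deviations are sample SDs (ddof = 1), which matters at small n.
#' Both statistics are invariant under any positive affine intensity
#' transform applied jointly to both populations, so they are comparable
#' across instruments after [normalize_to_reference()].
#'
#' @param pos_values Numeric vector of positive-population intensities
#'   (>= 2 values).
#' @param neg_values Numeric vector of negative-population intensities
#'   (>= 2 values).
#' @return Object of class `signal_stats` with fields `snr`, `cv`,
#'   `mean_pos`, `mean_neg`, `sd_pos`, `sd_neg`, `n_pos`, `n_neg`.
#'   [tidy()] returns them as a one-row tibble.
#' @export
signal_stats <- function(pos_values, neg_values) {
  if (length(pos_values) < 2 || length(neg_values) < 2)
    stop_value("both populations need at least 2 values")
  mp <- mean(pos_values); mn <- mean(neg_values)
  sp <- sd(pos_values);   sn <- sd(neg_values)
  if (sn == 0)
    stop_undefined("snr undefined: negative population has zero standard deviation")
  if (mp == mn)
    stop_undefined("cv undefined: positive and negative means are equal")
  structure(list(snr = (mp - mn) / sn, cv = sp / (mp - mn),
                 mean_pos = mp, mean_neg = mn, sd_pos = sp, sd_neg = sn,
                 n_pos = length(pos_values), n_neg = length(neg_values)),
            class = "signal_stats")
}

#' @export
print.signal_stats <- function(x, ...) {
  cat(sprintf("<signal_stats> snr %.3f, cv %.3f (n_pos %d, n_neg %d)\n",
              x$snr, x$cv, x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
tidy.signal_stats <- function(x, ...) {
  tibble(snr = x$snr, cv = x$cv, mean_pos = x$mean_pos, mean_neg = x$mean_neg,
         sd_pos = x$sd_pos, sd_neg = x$sd_neg)
}

#' @export
glance.signal_stats <- function(x, ...) {
  tibble(n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Affine normalization to reference population means
#'
#' Computes the unique order-preserving affine map `a * x + b` (a > 0) that
#' sends the observed negative- and positive-group means to the given
#' reference means, and applies it to all values. Used to place intensity
#' distributions from different instruments on a common scale so their
#' negative and positive population means coincide; SNR and CV are invariant
#' under the map.
#'
#' @param values Numeric intensity vector.
#' @param positive Logical vector (same length) marking the positive group.
#' @param ref_means Length-2 numeric `c(neg_ref, pos_ref)`.
#' @return Transformed numeric vector with attributes `a` and `b`.
#' @export
normalize_to_reference <- function(values, positive, ref_means) {
  if (length(values) != length(positive))
    stop_value("`values` and `positive` must have the same length")
  if (length(ref_means) != 2 || any(!is.finite(ref_means)))
    stop_value("`ref_means` must be finite c(neg_ref, pos_ref)")
  if (!any(positive) || !all(positive %in% c(TRUE, FALSE)) || all(positive))
    stop_value("both groups must be present")
  mn <- mean(values[!positive]); mp <- mean(values[positive])
  if (mp == mn)
    stop_degenerate("group means are equal: affine normalization is degenerate")
  a <- (ref_means[2] - ref_means[1]) / (mp - mn)
  if (a <= 0)
    stop_degenerate("reference means are ordered oppositely to the observed group means")
  b <- ref_means[1] - a * mn
  out <- a * values + b
  attr(out, "a") <- a
  attr(out, "b") <- b
  out
}

#' Doublet rate from the double-positive fraction of a two-color mix
#'
#' In a mix of two populations carrying spectrally distinct fluorophores,
#' only heterotypic doublets (one cell of each color) show both signals; a
#' doublet is heterotypic with probability `2 p (1 - p)` where `p` is the
#' mix fraction. The total doublet rate is therefore
#' `frac_double / (2 p (1 - p))`; for a 50/50 mix this is exactly twice the
#' observed double-positive fraction, since half of the doublets arise from
#' two cells with the same fluorescent protein.
#'
#' @param frac_double Observed fraction of gated cells positive in both
#'   channels.
#' @param mix_fraction_a Design mix proportion `p` of population A, in (0, 1).
#' @return Estimated doublet rate (fraction).
#' @export
doublet_rate <- function(frac_double, mix_fraction_a = 0.5) {
  p <- mix_fraction_a
  if (!is.numeric(p) || length(p) != 1 || p <= 0 || p >= 1)
    stop_value("`mix_fraction_a` must lie strictly between 0 and 1")
  het <- 2 * p * (1 - p)
  if (frac_double < 0 || frac_double > het)
    stop_value(sprintf(
      "`frac_double` must lie in [0, 2p(1-p)] = [0, %.4g] for p = %.3g", het, p))
  frac_double / het
}

#' Images required per well for a target cell count
#'
#' Throughput helper: with `cells_per_image` cells per field of view, the
#' number of fields needed to reach `target_cells` analyzed cells per well
#' (e.g. 3,300 cells/image at 10x on a typical sCMOS sensor and a 50,000-cell
#' flow-equivalent target gives 16 fields).
#'
#' @param cells_per_image Expected analyzable cells per field of view (> 0).
#' @param target_cells Desired number of cells per well (> 0).
#' @return Integer number of fields.
#' @export
fields_per_well <- function(cells_per_image, target_cells) {
  if (cells_per_image <= 0 || target_cells <= 0)
    stop_value("cell counts must be positive")
  as.integer(ceiling(target_cells / cells_per_image))
}

#' Plate-screen summary: editing efficiency, survival and total positives
#'
#' Per condition: `n_cells` (event count), `frac_positive` (positives /
#' total, the editing-efficiency readout), `total_positive` (integrates
#' efficiency and proliferation), and `rel_proliferation` (cell count
#' relative to the no-plasmid control condition). Cells of all images of a
#' well/condition are pooled unweighted.
#'
#' @param records Tibble of cell records; must contain a `condition` column
#'   and either a `positive_<channel>` column or gates to apply.
#' @param channel Channel whose positivity defines the readout.
#' @param control_condition Condition label of the no-plasmid control.
#' @param gates Optional `cyto_gates`; when given, [apply_gates()] runs
#'   first.
#' @param condition_cols Extra condition-factor columns (e.g. `PE_ng`,
#'   `MLH1_ng`) carried into the summary, one value per condition.
#' @param all_conditions Optional character vector of expected conditions;
#'   conditions with zero cells are emitted with `n_cells = 0`,
#'   `frac_positive = NA` and `empty = TRUE`.
#' @return Tibble of class `screen_summary`: `condition`, any
#'   `condition_cols`, `n_cells`, `frac_positive`, `total_positive`,
#'   `rel_proliferation`, `empty`.
#' @export
screen_summary <- function(records, channel, control_condition,
                           gates = NULL, condition_cols = character(),
                           all_conditions = NULL) {
  records <- as_tibble(records)
  if (!"condition" %in% names(records))
    stop_value("records need a `condition` column")
  if (!is.null(gates)) records <- apply_gates(records, gates)
  pos_col <- paste0("positive_", channel)
  if (!pos_col %in% names(records))
    stop_key(paste0("records lack column ", pos_col,
                    "; gate them first or pass `gates`"))
  if (!control_condition %in% records$condition)
    stop_value(paste0("control condition '", control_condition,
                      "' has no records"))
  summ <- records %>%
    group_by(.data$condition) %>%
    summarise(dplyr::across(dplyr::all_of(condition_cols), ~ .x[1]),
              n_cells = dplyr::n(),
              total_positive = sum(.data[[pos_col]]),
              .groups = "drop") %>%
    mutate(frac_positive = .data$total_positive / .data$n_cells,
           empty = FALSE)
  if (!is.null(all_conditions)) {
    missing <- setdiff(all_conditions, summ$condition)
    if (length(missing)) {
      pad <- tibble(condition = missing, n_cells = 0L, total_positive = 0L,
                    frac_positive = NA_real_, empty = TRUE)
      summ <- bind_rows(summ, pad)
    }
  }
  n_control <- summ$n_cells[summ$condition == control_condition]
  summ <- summ %>%
    mutate(rel_proliferation = .data$n_cells / n_control) %>%
    select(dplyr::all_of(c("condition", condition_cols)),
           "n_cells", "frac_positive", "total_positive",
           "rel_proliferation", "empty") %>%
    arrange(.data$condition)
  class(summ) <- c("screen_summary", class(summ))
  attr(summ, "control_condition") <- control_condition
  attr(summ, "channel") <- channel
  summ
}

#' @export
glance.screen_summary <- function(x, ...) {
  best_frac <- x[which.max(ifelse(x$empty, -Inf, x$frac_positive)), ]
  best_tot <- x[which.max(ifelse(x$empty, -Inf, x$total_positive)), ]
  tibble(n_conditions = nrow(x),
         n_cells_total = sum(x$n_cells),
         control_condition = attr(x, "control_condition"),
         best_frac_condition = best_frac$condition[1],
         best_frac_positive = best_frac$frac_positive[1],
         best_total_condition = best_tot$condition[1],
         best_total_positive = best_tot$total_positive[1])
}
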