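# Cell segmentation: pluggable segmenter (Cellpose adapter or the built-in
# watershed fallback) followed by the edge and Gaussian size filters.

#' Segmenter parameters
#'
#' Two parameters govern boundary determination: the expected object diameter
#' in pixels (the segmentation models are trained at a fixed scale, so a wrong
#' diameter badly degrades boundary calls) and the flow threshold, the maximum
#' allowed error between predicted flows and candidate segments. The built-in
#' fallback segmenter consumes only the diameter.
#'
#' @param diameter_px Expected cell diameter in pixels (> 0). Automatic
#'   diameter estimation is deliberately not a default anywhere in this
#'   package: on brightfield data it can underestimate badly, and the
#'   diameter is the single most influential setting.
#' @param flow_threshold Maximum allowed flow error (> 0); only used by the
#'   Cellpose models.
#' @param model One of `"fallback"` (built-in watershed segmenter),
#'   `"cyto"` or `"nuclei"` (dispatched to a registered Cellpose adapter).
#' @return A list of class `segmenter_params`.
#' @export
segmenter_params <- function(diameter_px, flow_threshold = 0.95,
                             model = c("fallback", "cyto", "nuclei")) {
  model <- match.arg(model)
  if (!is.numeric(diameter_px) || length(diameter_px) != 1 || diameter_px <= 0)
    stop_value("`diameter_px` must be a positive scalar")
  if (!is.numeric(flow_threshold) || length(flow_threshold) != 1 || flow_threshold <= 0)
    stop_value("`flow_threshold` must be a positive scalar")
  structure(list(diameter_px = diameter_px, flow_threshold = flow_threshold,
                 model = model),
            class = "segmenter_params")
}

#' Segment a single-channel image into a cell label mask
#'
#' Dispatches to the Cellpose adapter for `model = "cyto"` (cytoplasmic model,
#' for brightfield images) or `"nuclei"` (for nuclear-stain images), or to
#' [fallback_segment()] for `model = "fallback"`. The Cellpose adapter is an
#' optional extra: register a function
#' `function(image, diameter_px, flow_threshold, model) -> label matrix` via
#' `options(microcyto.cellpose_adapter = ...)`. Deterministic for fixed
#' inputs and parameters.
#'
#' @param image Numeric matrix of finite intensities.
#' @param params A [segmenter_params()] object.
#' @return Integer label matrix of the same shape (0 = background).
#' @export
segment <- function(image, params) {
  stopifnot(inherits(params, "segmenter_params"))
  if (!is.matrix(image) || length(image) == 0)
    stop_value("`image` must be a non-empty matrix")
  if (any(!is.finite(image)))
    stop_value("`image` must be finite")
  if (params$model == "fallback")
    return(fallback_segment(image, params$diameter_px))
  adapter <- getOption("microcyto.cellpose_adapter")
  if (is.null(adapter))
    stop_dependency(paste0(
      "model '", params$model, "' requires the Cellpose adapter: install the ",
      "'cellpose' optional extra and register it via ",
      "options(microcyto.cellpose_adapter = ...), or use model = 'fallback'"))
  mask <- adapter(image, params$diameter_px, params$flow_threshold, params$model)
  assert_label_mask(mask)
}

#' Built-in watershed segmenter
#'
#' A fixed, fully deterministic classical pipeline used wherever a trained
#' model is unnecessary or unavailable: Gaussian smoothing
#' (sigma = `diameter_px / 8`), Otsu threshold (the minority class is taken
#' as foreground, which handles both bright objects on dark background and
#' dark cell rims on a bright brightfield background), hole filling,
#' Euclidean distance transform, seeding at local maxima separated by at
#' least `diameter_px / 2`, and seeded watershed. Labels are assigned in
#' raster order (row-major) of the seed positions.
#'
#' @param image Numeric matrix of finite intensities.
#' @param diameter_px Expected object diameter in pixels.
#' @return Integer label matrix (0 = background).
#' @export
fallback_segment <- function(image, diameter_px) {
  if (!is.matrix(image) || length(image) == 0)
    stop_value("`image` must be a non-empty matrix")
  if (any(!is.finite(image))) stop_value("`image` must be finite")
  if (diameter_px <= 0) stop_value("`diameter_px` must be positive")
  zero <- matrix(0L, nrow(image), ncol(image))
  rng <- range(image)
  if (rng[2] - rng[1] <= 0) return(zero)         # constant image: nothing to segment

  # smoothing and seed-separation scales are clamped to the image size so
  # diameters comparable to the field of view remain well-defined
  sigma_max <- (min(dim(image)) - 1) / 7
  sm <- EBImage::gblur(image, sigma = min(max(diameter_px / 8, 0.5), sigma_max))
  rng <- range(sm)
  if (rng[2] - rng[1] <= 0) return(zero)
  smn <- (sm - rng[1]) / (rng[2] - rng[1])
  thr <- EBImage::otsu(EBImage::Image(smn), range = c(0, 1))
  fg_dark <- smn < thr
  fg <- if (mean(fg_dark) <= 0.5) fg_dark else !fg_dark
  if (!any(fg)) return(zero)
  fgf <- EBImage::fillHull(EBImage::Image(fg))

  dm <- EBImage::distmap(fgf)
  radius <- max(1L, as.integer(floor(min(diameter_px / 4, (min(dim(image)) - 1) / 2))))
  brush <- EBImage::makeBrush(2L * radius + 1L, shape = "disc")
  dil <- EBImage::dilate(dm, brush)
  maxima <- (EBImage::imageData(dm) == EBImage::imageData(dil)) &
    (EBImage::imageData(dm) > 0)
  if (!any(maxima)) return(zero)
  seeds <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(maxima)))
  seeds <- relabel_raster_order(seeds)
  ws <- EBImage::propagate(dm, EBImage::Image(seeds), mask = fgf)
  mask <- EBImage::imageData(ws)
  storage.mode(mask) <- "integer"
  mask
}

# Relabel a label matrix so labels follow row-major raster order of each
# label's first pixel; keeps seed numbering deterministic.
relabel_raster_order <- function(labels) {
  pos <- which(labels > 0, arr.ind = TRUE)
  if (nrow(pos) == 0) return(matrix(0L, nrow(labels), ncol(labels)))
  lab <- labels[labels > 0]
  raster <- (pos[, 1] - 1) * ncol(labels) + pos[, 2]   # row-major index
  first <- tapply(raster, lab, min)
  order_map <- setNames(rank(first, ties.method = "first"), names(first))
  out <- matrix(0L, nrow(labels), ncol(labels))
  out[labels > 0] <- as.integer(order_map[as.character(lab)])
  out
}

#' Remove segments touching the image border
#'
#' Any label with at least one pixel in the first or last row or column —
#' including single corner pixels — is deleted (set to background). Partially
#' imaged cells would otherwise bias sizes and intensities. Remaining labels
#' are untouched (no relabeling).
#'
#' @param mask Integer label matrix.
#' @return Filtered label matrix.
#' @export
remove_edge_segments <- function(mask) {
  mask <- assert_label_mask(mask)
  border <- unique(c(mask[1, ], mask[nrow(mask), ], mask[, 1], mask[, ncol(mask)]))
  border <- border[border > 0]
  if (length(border)) mask[mask %in% border] <- 0L
  mask
}

#' Per-segment statistics
#'
#' One row per unique positive label, sorted by label: pixel area, centroid,
#' bounding box and an edge-contact flag. Coordinates are 0-based `(row, col)`
#' pixel indices, the convention used throughout the package's outputs; the
#' bounding box is inclusive.
#'
#' @param mask Integer label matrix.
#' @return A tibble with columns `label`, `area_px`, `centroid_row`,
#'   `centroid_col`, `bbox_min_row`, `bbox_min_col`, `bbox_max_row`,
#'   `bbox_max_col`, `touches_edge`.
#' @export
compute_segment_stats <- function(mask) {
  mask <- assert_label_mask(mask)
  pos <- which(mask > 0, arr.ind = TRUE)
  empty <- tibble(label = integer(), area_px = integer(),
                  centroid_row = double(), centroid_col = double(),
                  bbox_min_row = integer(), bbox_min_col = integer(),
                  bbox_max_row = integer(), bbox_max_col = integer(),
                  touches_edge = logical())
  if (nrow(pos) == 0) return(empty)
  lab <- mask[mask > 0]
  r0 <- pos[, 1] - 1L   # 0-based
  c0 <- pos[, 2] - 1L
  labs <- sort(unique(lab))
  idx <- match(lab, labs)
  area <- tabulate(idx, nbins = length(labs))
  sum_r <- unname(rowsum(as.double(r0), idx)[, 1])
  sum_c <- unname(rowsum(as.double(c0), idx)[, 1])
  min_r <- tapply(r0, idx, min); max_r <- tapply(r0, idx, max)
  min_c <- tapply(c0, idx, min); max_c <- tapply(c0, idx, max)
  tibble(
    label = as.integer(labs),
    area_px = as.integer(area),
    centroid_row = sum_r / area,
    centroid_col = sum_c / area,
    bbox_min_row = as.integer(min_r), bbox_min_col = as.integer(min_c),
    bbox_max_row = as.integer(max_r), bbox_max_col = as.integer(max_c),
    touches_edge = min_r == 0L | min_c == 0L |
      max_r == nrow(mask) - 1L | max_c == ncol(mask) - 1L
  )
}

#' Gaussian size filter on segment areas
#'
#' Mirrors the two-stage size thresholding used for brightfield cell masks:
#' first discard very small segments (hard prefilter, default 2000 px for 60x
#' images), then fit a normal distribution to the remaining areas — by moment
#' matching, i.e. sample mean and sample SD (ddof = 1), which is the Gaussian
#' MLE-equivalent and fully deterministic — and keep segments within
#' `n_sd` standard deviations of the mean on both sides.
#'
#' If fewer than 3 segments survive the prefilter the Gaussian fit is
#' ill-posed: the band filter is skipped with a warning and all prefiltered
#' segments are kept.
#'
#' @param stats Tibble with `label` and `area_px` columns
#'   (from [compute_segment_stats()]).
#' @param min_area_px Hard minimum area prefilter in pixels.
#' @param n_sd Half-width of the kept band in standard deviations.
#' @return A list of class `size_filter_fit`: `kept_labels` (integer vector),
#'   `mean` and `sd` of the fitted normal (NA when skipped), `n_prefiltered`
#'   (segments surviving the hard prefilter), `skipped` (logical).
#' @export
size_filter <- function(stats, min_area_px = 2000, n_sd = 2) {
  if (min_area_px < 0) stop_value("`min_area_px` must be >= 0")
  if (n_sd <= 0) stop_value("`n_sd` must be > 0")
  stats <- as_tibble(stats)
  keep0 <- stats[stats$area_px >= min_area_px, , drop = FALSE]
  if (nrow(keep0) < 3) {
    warn(sprintf(
      "size_filter: only %d segment(s) survive the %g px prefilter; Gaussian band filter skipped",
      nrow(keep0), min_area_px))
    return(structure(list(kept_labels = as.integer(keep0$label),
                          mean = NA_real_, sd = NA_real_,
                          n_prefiltered = nrow(keep0), skipped = TRUE),
                     class = "size_filter_fit"))
  }
  mu <- mean(keep0$area_px)
  sigma <- sd(keep0$area_px)
  in_band <- keep0$area_px >= mu - n_sd * sigma & keep0$area_px <= mu + n_sd * sigma
  structure(list(kept_labels = as.integer(keep0$label[in_band]),
                 mean = mu, sd = sigma,
                 n_prefiltered = nrow(keep0), skipped = FALSE),
            class = "size_filter_fit")
}

#' @export
print.size_filter_fit <- function(x, ...) {
  cat(sprintf("<size_filter_fit> kept %d/%d prefiltered segments; mean %.1f px, sd %.1f px%s\n",
              length(x$kept_labels), x$n_prefiltered, x$mean, x$sd,
              if (x$skipped) " (band filter skipped)" else ""))
  invisible(x)
}

#' Keep only the given labels in a mask
#'
#' Deletes all other labels without relabeling, so label identity is
#' preserved across pipeline stages.
#'
#' @param mask Integer label matrix.
#' @param keep_labels Integer vector of labels to retain.
#' @return Filtered label matrix.
#' @export
filter_mask <- function(mask, keep_labels) {
  mask <- assert_label_mask(mask)
  mask[!(mask %in% c(0L, keep_labels))] <- 0L
  mask
}

#' Apply edge removal and the Gaussian size filter to a mask
#'
#' Edge removal runs first so that clipped border cells cannot perturb the
#' Gaussian fit of the size distribution.
#'
#' @inheritParams size_filter
#' @param mask Integer label matrix.
#' @return A list: `mask` (filtered), `fit` (the `size_filter_fit`),
#'   `n_edge_removed`, `n_size_removed`.
#' @export
apply_segment_filters <- function(mask, min_area_px = 2000, n_sd = 2) {
  mask <- assert_label_mask(mask)
  n0 <- n_labels(mask)
  mask <- remove_edge_segments(mask)
  n1 <- n_labels(mask)
  stats <- compute_segment_stats(mask)
  fit <- size_filter(stats, min_area_px = min_area_px, n_sd = n_sd)
  mask <- filter_mask(mask, fit$kept_labels)
  list(mask = mask, fit = fit,
       n_edge_removed = n0 - n1,
       n_size_removed = n1 - n_labels(mask))
}

#' Number of distinct positive labels in a mask
#' @param mask Integer label matrix.
#' @return Integer count.
#' @export
n_labels <- function(mask) {
  length(unique(mask[mask > 0]))
}

#' Scale the minimum-area prefilter to a different magnification
#'
#' The 2000 px default is tied to 60x sampling; segment areas scale with the
#' square of magnification, so at magnification `m` the equivalent prefilter
#' is `min_area_px * (m / 60)^2`.
#'
#' @param min_area_px Reference prefilter at `ref_magnification`.
#' @param magnification Target objective magnification.
#' @param ref_magnification Magnification at which `min_area_px` was chosen.
#' @return Scaled pixel area.
#' @export
scale_min_area <- function(min_area_px, magnification, ref_magnification = 60) {
  if (magnification <= 0 || ref_magnification <= 0)
    stop_value("magnifications must be positive")
  min_area_px * (magnification / ref_magnification)^2
}
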