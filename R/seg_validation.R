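# Segmentation-quality scoring against a reference (nuclei) mask, and the
# diameter x flow-threshold parameter screen.

#' Parameter grid for the segmentation screen
#'
#' @param diameters Strictly increasing vector of diameters (pixels).
#' @param flow_thresholds Strictly increasing vector of flow thresholds.
#' @return A list of class `param_grid`.
#' @export
param_grid <- function(diameters, flow_thresholds) {
  for (v in list(diameters, flow_thresholds)) {
    if (length(v) == 0) stop_value("grid axes must be non-empty")
    if (any(diff(v) <= 0)) stop_value("grid axes must be strictly increasing")
  }
  structure(list(diameters = diameters, flow_thresholds = flow_thresholds),
            class = "param_grid")
}

#' Evenly spaced parameter grid
#'
#' The default grid — 25 diameters on `[25, 505]` px and 21 flow thresholds
#' on `[0.05, 2.05]`, inclusive endpoints (steps of 20 px and 0.1) — spans
#' the full 525-combination screen used to locate optimal segmentation
#' parameters.
#'
#' @param diameter_range Length-2 inclusive range of diameters (pixels).
#' @param n_diameters Number of evenly spaced diameters.
#' @param flow_range Length-2 inclusive range of flow thresholds.
#' @param n_flows Number of evenly spaced flow thresholds.
#' @return A [param_grid()].
#' @export
param_grid_even <- function(diameter_range = c(25, 505), n_diameters = 25,
                            flow_range = c(0.05, 2.05), n_flows = 21) {
  param_grid(seq(diameter_range[1], diameter_range[2], length.out = n_diameters),
             seq(flow_range[1], flow_range[2], length.out = n_flows))
}

# distinct (candidate, reference) label pairs under the chosen criterion
match_pairs <- function(candidate, reference, criterion) {
  if (criterion == "overlap") {
    both <- candidate > 0 & reference > 0
    if (!any(both)) return(list(cand_ref = tibble(cand = integer(), ref = integer()),
                                ref_cand = tibble(cand = integer(), ref = integer())))
    pairs <- distinct(tibble(cand = candidate[both], ref = reference[both]))
    # overlap is symmetric: the same pair set serves both directions
    list(cand_ref = pairs, ref_cand = pairs)
  } else {
    centroid_hits <- function(src, dst) {
      st <- compute_segment_stats(src)
      if (nrow(st) == 0) return(tibble(src = integer(), dst = integer()))
      # centroid pixel: nearest pixel to the (0-based) centroid
      r <- pmin(pmax(round(st$centroid_row) + 1, 1), nrow(src))
      c <- pmin(pmax(round(st$centroid_col) + 1, 1), ncol(src))
      hit <- dst[cbind(r, c)]
      tibble(src = st$label, dst = hit)[hit > 0, ]
    }
    cr <- centroid_hits(candidate, reference)   # candidate centroid inside reference
    rc <- centroid_hits(reference, candidate)   # reference centroid inside candidate
    list(cand_ref = tibble(cand = cr$src, ref = cr$dst),
         ref_cand = tibble(cand = rc$dst, ref = rc$src))
  }
}

#' Match candidate segments to reference segments
#'
#' Counts, for every reference label, how many candidate segments "fall
#' within" it, and vice versa. Under the default `overlap` criterion a
#' candidate falls within a reference iff their pixel sets share at least one
#' pixel (robust to nuclei occupying only ~80-90% of the cell area); under
#' `centroid` the candidate's centroid pixel must lie inside the reference
#' (and symmetrically for the reverse direction).
#'
#' @param candidate,reference Integer label matrices of identical shape.
#' @param criterion `"overlap"` (default) or `"centroid"`.
#' @return A list with tibbles `reference_hits` (`label`, `n_hits`: candidate
#'   segments falling within each reference label) and `candidate_hits`
#'   (`label`, `n_hits`: reference segments falling within each candidate
#'   label). Every label of each mask appears, including zero-hit ones.
#' @export
match_segments <- function(candidate, reference,
                           criterion = c("overlap", "centroid")) {
  criterion <- match.arg(criterion)
  candidate <- assert_label_mask(candidate, "candidate")
  reference <- assert_label_mask(reference, "reference")
  if (!identical(dim(candidate), dim(reference)))
    stop_value("candidate and reference masks must share the same shape")
  pairs <- match_pairs(candidate, reference, criterion)
  all_ref <- sort(unique(reference[reference > 0]))
  all_cand <- sort(unique(candidate[candidate > 0]))
  ref_hits <- count(pairs$ref_cand, .data$ref, name = "n_hits")
  cand_hits <- count(pairs$cand_ref, .data$cand, name = "n_hits")
  list(
    reference_hits = tibble(label = as.integer(all_ref)) %>%
      left_join(rename(ref_hits, label = "ref"), by = "label") %>%
      mutate(n_hits = as.integer(ifelse(is.na(.data$n_hits), 0L, .data$n_hits))),
    candidate_hits = tibble(label = as.integer(all_cand)) %>%
      left_join(rename(cand_hits, label = "cand"), by = "label") %>%
      mutate(n_hits = as.integer(ifelse(is.na(.data$n_hits), 0L, .data$n_hits)))
  )
}

#' Segmentation quality metrics against a reference mask
#'
#' Scores a candidate (typically brightfield-derived) mask against a
#' reference (typically nuclei) mask, both expected post-filtering:
#' * `segments_per_nucleus` — candidate count / reference count; 1 indicates
#'   count-accurate segmentation.
#' * `fn_ratio` — fraction of reference labels with no candidate falling
#'   within them (a cell whose nucleus attracted no segment was missed).
#' * `fp_ratio` — fraction of candidate labels containing no reference
#'   (a segment with no nucleus is spurious); 0 when there are no candidates.
#'
#' Each ratio is normalized by the population it describes, so both stay in
#' `[0, 1]`.
#'
#' @inheritParams match_segments
#' @return One-row tibble: `n_candidate`, `n_reference`,
#'   `segments_per_nucleus`, `fn_ratio`, `fp_ratio`, `criterion`.
#' @export
quality_metrics <- function(candidate, reference,
                            criterion = c("overlap", "centroid")) {
  criterion <- match.arg(criterion)
  hits <- match_segments(candidate, reference, criterion)
  n_ref <- nrow(hits$reference_hits)
  if (n_ref == 0) stop_value("reference mask has no segments")
  n_cand <- nrow(hits$candidate_hits)
  tibble(
    n_candidate = n_cand,
    n_reference = n_ref,
    segments_per_nucleus = n_cand / n_ref,
    fn_ratio = sum(hits$reference_hits$n_hits == 0) / n_ref,
    fp_ratio = if (n_cand == 0) 0 else sum(hits$candidate_hits$n_hits == 0) / n_cand,
    criterion = criterion
  )
}

#' Diameter x flow-threshold parameter screen
#'
#' Segments every brightfield image at every grid combination, applies the
#' edge and Gaussian size filters, scores the result against the paired
#' reference nuclei mask, and averages the metrics across images
#' (unweighted per-image mean). Reference masks are supplied precomputed and
#' reused across the whole grid.
#'
#' Segmentations are cached per unique set of parameters the active model
#' actually consumes (the fallback segmenter ignores the flow threshold, so
#' each diameter is segmented once).
#'
#' @param pairs List of image pairs; each element is a list with
#'   `brightfield` (numeric matrix) and `reference` (integer label mask).
#' @param grid A [param_grid()].
#' @param model Segmenter model, see [segmenter_params()].
#' @param min_area_px,n_sd Size-filter settings applied to each candidate
#'   mask (see [size_filter()]).
#' @param criterion Matching criterion, see [match_segments()].
#' @return A tibble of class `param_screen` with one row per grid
#'   combination: `diameter_px`, `flow_threshold`, `segments_per_nucleus`,
#'   `fn_ratio`, `fp_ratio`, `n_images`.
#' @export
parameter_screen <- function(pairs, grid, model = "fallback",
                             min_area_px = 2000, n_sd = 2,
                             criterion = c("overlap", "centroid")) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(grid, "param_grid"))
  if (!is.list(pairs) || length(pairs) == 0)
    stop_value("`pairs` must be a non-empty list of (brightfield, reference) pairs")
  combos <- expand.grid(flow_threshold = grid$flow_thresholds,
                        diameter_px = grid$diameters)[, 2:1]
  if (nrow(combos) == 0) stop_value("parameter grid is empty")

  cache <- new.env(parent = emptyenv())
  segment_cached <- function(img, i, d, f) {
    key <- if (model == "fallback") sprintf("%d_%g", i, d) else sprintf("%d_%g_%g", i, d, f)
    if (!is.null(cache[[key]])) return(cache[[key]])
    params <- segmenter_params(d, flow_threshold = f, model = model)
    filtered <- suppressWarnings(
      apply_segment_filters(segment(img, params),
                            min_area_px = min_area_px, n_sd = n_sd))
    cache[[key]] <- filtered$mask
    filtered$mask
  }

  rows <- map(seq_len(nrow(combos)), function(k) {
    d <- combos$diameter_px[k]; f <- combos$flow_threshold[k]
    per_image <- map(seq_along(pairs), function(i) {
      mask <- segment_cached(pairs[[i]]$brightfield, i, d, f)
      quality_metrics(mask, pairs[[i]]$reference, criterion)
    })
    per_image <- bind_rows(per_image)
    tibble(diameter_px = d, flow_threshold = f,
           segments_per_nucleus = mean(per_image$segments_per_nucleus),
           fn_ratio = mean(per_image$fn_ratio),
           fp_ratio = mean(per_image$fp_ratio),
           n_images = length(pairs))
  })
  out <- bind_rows(rows)
  class(out) <- c("param_screen", class(out))
  attr(out, "criterion") <- criterion
  out
}

#' @export
glance.param_screen <- function(x, ...) {
  best <- x[which.min(abs(x$segments_per_nucleus - 1)), ]
  tibble(n_combinations = nrow(x),
         n_diameters = length(unique(x$diameter_px)),
         n_flow_thresholds = length(unique(x$flow_threshold)),
         best_diameter_px = best$diameter_px[1],
         best_flow_threshold = best$flow_threshold[1],
         best_segments_per_nucleus = best$segments_per_nucleus[1],
         criterion = attr(x, "criterion") %||% NA_character_)
}
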