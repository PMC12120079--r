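# Event tables (CSV) and plate configuration (YAML).

event_fixed_cols <- c("cell_id", "well", "condition", "area_px",
                      "centroid_row", "centroid_col")

#' Write a per-cell event table to CSV
#'
#' The event table is the flow-cytometry-like output of the pipeline: one row
#' per cell with its mean intensity per channel and, if gated, a positivity
#' flag per channel. The column order is deterministic: `cell_id, well,
#' condition, area_px, centroid_row, centroid_col`, then `mean_<channel>`
#' columns, then `positive_<channel>` columns.
#'
#' @param records Tibble of cell records as produced by
#'   [extract_cell_records()] (optionally after [apply_gates()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(records, path) {
  records <- as_tibble(records)
  missing <- setdiff(event_fixed_cols, names(records))
  if (length(missing))
    stop_schema(paste0("event table lacks required column(s): ",
                       paste(missing, collapse = ", ")))
  mean_cols <- grep("^mean_", names(records), value = TRUE)
  pos_cols  <- grep("^positive_", names(records), value = TRUE)
  if (nrow(records) > 0 && length(mean_cols) > 0 &&
      anyNA(records[mean_cols]))
    stop_schema("records carry heterogeneous channel sets (NA mean intensities)")
  out <- records[, c(event_fixed_cols, mean_cols, pos_cols), drop = FALSE]
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a per-cell event table written by [write_event_table()]
#'
#' @param path CSV path.
#' @return A tibble; `positive_<channel>` columns are logical.
#' @export
read_event_table <- function(path) {
  if (!file.exists(path)) stop_io(paste0("cannot read event table: ", path))
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  for (cl in grep("^positive_", names(out), value = TRUE))
    out[[cl]] <- as.logical(out[[cl]])
  out
}

# plate configuration ---------------------------------------------------------

plate_known_keys <- c("wells", "channels", "default_params")
well_known_keys  <- c("condition", "role", "image", "channels")
well_roles <- c("sample", "control_nonfluorescent", "control_no_plasmid")

#' Read and validate a plate configuration
#'
#' A plate config is a single YAML document mapping wells to conditions,
#' control roles and image files, plus the channel-role map and default
#' segmentation parameters, e.g.:
#'
#' ```yaml
#' channels:
#'   brightfield: bf
#'   nuclei: dapi
#'   fluor: [mNG]
#' default_params: {diameter_px: 145, flow_threshold: 0.95,
#'                  min_area_px: 2000, n_sd: 2, percentile: 99.9}
#' wells:
#'   A1: {condition: WT, role: control_nonfluorescent, image: A1.tif}
#'   A2: {condition: PE5_MLH15, role: sample, image: A2.tif}
#' ```
#'
#' Unknown keys are ignored with a warning. Well ids must match the 96/384
#' plate convention `[A-P][1-24]`; exactly one channel must carry the
#' brightfield role.
#'
#' @param path YAML file path.
#' @return A validated list of class `plate_config`.
#' @export
read_plate_config <- function(path) {
  if (!file.exists(path)) stop_io(paste0("cannot read plate config: ", path))
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), plate_known_keys)
  if (length(unknown))
    warn(paste0("plate config: ignoring unknown key(s): ",
                paste(unknown, collapse = ", ")))
  if (is.null(cfg$wells) || length(cfg$wells) == 0)
    stop_schema("plate config: `wells` is missing or empty")
  if (is.null(cfg$channels$brightfield) || length(cfg$channels$brightfield) != 1)
    stop_schema("plate config: `channels` must assign exactly one brightfield channel")
  ids <- names(cfg$wells)
  bad <- ids[!grepl("^[A-P][0-9]{1,2}$", ids)]
  if (length(bad))
    stop_schema(paste0("plate config: invalid well id(s): ", paste(bad, collapse = ", ")))
  for (id in ids) {
    w <- cfg$wells[[id]]
    unknown <- setdiff(names(w), well_known_keys)
    if (length(unknown))
      warn(paste0("plate config: well ", id, ": ignoring unknown key(s): ",
                  paste(unknown, collapse = ", ")))
    if (is.null(w$condition))
      stop_schema(paste0("plate config: wells.", id, ".condition is required"))
    role <- w$role %||% "sample"
    if (!role %in% well_roles)
      stop_schema(paste0("plate config: wells.", id, ".role must be one of ",
                         paste(well_roles, collapse = ", ")))
    cfg$wells[[id]]$role <- role
  }
  defaults <- list(diameter_px = 145, flow_threshold = 0.95,
                   min_area_px = 2000, n_sd = 2, percentile = 99.9)
  cfg$default_params <- utils::modifyList(defaults, cfg$default_params %||% list())
  structure(cfg[plate_known_keys], class = "plate_config")
}

#' All channel names a plate config expects in each image
#' @param config A `plate_config`.
#' @return Character vector in page order: brightfield, nuclei (if any), fluor.
#' @export
config_channel_names <- function(config) {
  stopifnot(inherits(config, "plate_config"))
  ch <- config$channels
  c(ch$brightfield, ch$nuclei, unlist(ch$fluor))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
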