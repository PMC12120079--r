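# Minimal FCS 3.0/3.1 reader: list-mode, float ($DATATYPE F) or integer
# ($DATATYPE I) data, little- or big-endian. Enough to ingest files exported
# from a cell sorter for flow-vs-microscopy comparisons; no compensation,
# no transformation, no writing.

fcs_text_segment <- function(raw, begin, end) {
  delim <- rawToChar(raw[begin])
  txt <- rawToChar(raw[(begin + 1):end])
  # FCS escapes the delimiter by doubling; plain split is fine for the simple
  # instrument files targeted here, but guard against trailing delimiter
  parts <- strsplit(txt, delim, fixed = TRUE)[[1]]
  parts <- parts[nzchar(trimws(parts)) | seq_along(parts) %% 2 == 0]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  keys <- trimws(parts[seq(1, length(parts), by = 2)])
  vals <- trimws(parts[seq(2, length(parts), by = 2)])
  setNames(as.list(vals), toupper(keys))
}

#' Read an FCS 3.0/3.1 file
#'
#' Reads list-mode flow cytometry standard files with float (`$DATATYPE F`)
#' or integer (`$DATATYPE I`) data. All events for all parameters are
#' returned as raw instrument values; no compensation or transformation is
#' applied. Unsupported data types or modes raise an explicit error rather
#' than a silent misread.
#'
#' @param path Path to an `.fcs` file.
#' @return An object of class `fcs_data`: a list with `parameter_names`
#'   (ordered character vector), `events` (numeric matrix, one row per event,
#'   one column per parameter) and `header_metadata` (named list of all TEXT
#'   keywords).
#' @export
read_fcs <- function(path) {
  if (!file.exists(path)) stop_io(paste0("cannot read FCS file: ", path))
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 58) stop_format("file too short to be an FCS file")
  version <- rawToChar(raw[1:6])
  if (!version %in% c("FCS3.0", "FCS3.1"))
    stop_unsupported(paste0("unsupported FCS version: '", version,
                            "' (FCS 3.0/3.1 only)"))
  off <- function(i) {
    s <- trimws(rawToChar(raw[(10 + 8 * (i - 1) + 1):(10 + 8 * i)]))
    if (!nzchar(s)) 0 else as.numeric(s)
  }
  text_begin <- off(1); text_end <- off(2)
  data_begin <- off(3); data_end <- off(4)
  if (text_begin <= 0 || text_end <= text_begin)
    stop_format("invalid TEXT segment offsets in FCS header")
  kw <- fcs_text_segment(raw, text_begin + 1, text_end + 1)  # offsets are 0-based

  datatype <- toupper(kw[["$DATATYPE"]] %||% "")
  if (!datatype %in% c("F", "I"))
    stop_unsupported(paste0("unsupported $DATATYPE '", datatype,
                            "': only F (float) and I (integer) list data are read"))
  mode <- toupper(kw[["$MODE"]] %||% "")
  if (mode != "L")
    stop_unsupported(paste0("unsupported $MODE '", mode, "': only list mode (L) is read"))

  n_par <- as.integer(kw[["$PAR"]])
  n_tot <- as.integer(kw[["$TOT"]])
  if (is.na(n_par) || is.na(n_tot))
    stop_format("FCS TEXT segment lacks $PAR or $TOT")
  byteord <- kw[["$BYTEORD"]] %||% "1,2,3,4"
  endian <- switch(byteord,
                   "1,2,3,4" = "little", "2,1" = "little",
                   "4,3,2,1" = "big",    "1,2" = "big",
                   stop_unsupported(paste0("unsupported $BYTEORD: ", byteord)))

  bits <- map_int(seq_len(n_par), function(i) {
    b <- kw[[paste0("$P", i, "B")]]
    if (is.null(b)) stop_format(paste0("missing $P", i, "B keyword"))
    as.integer(b)
  })
  if (datatype == "F" && any(bits != 32))
    stop_unsupported("float data must be 32 bits per parameter ($PnB = 32)")
  if (datatype == "I" && any(!bits %in% c(16L, 32L)))
    stop_unsupported("integer data must be 16 or 32 bits per parameter")
  if (datatype == "I" && length(unique(bits)) > 1)
    stop_unsupported("mixed integer widths across parameters are not supported")

  names_par <- map(seq_len(n_par), function(i)
    kw[[paste0("$P", i, "N")]] %||% paste0("P", i))
  names_par <- unlist(names_par)

  if (data_begin <= 0) data_begin <- as.numeric(kw[["$BEGINDATA"]] %||% 0)
  if (data_end <= 0) data_end <- as.numeric(kw[["$ENDDATA"]] %||% 0)
  if (data_begin <= 0 || data_end < data_begin)
    stop_format("invalid DATA segment offsets")
  payload <- raw[(data_begin + 1):(data_end + 1)]
  n_values <- n_par * n_tot
  size <- bits[1] / 8
  if (length(payload) < n_values * size)
    stop_format(sprintf("DATA segment too short: %d bytes for %d values of %d bytes",
                        length(payload), n_values, size))
  values <- if (datatype == "F") {
    readBin(payload, "numeric", n = n_values, size = 4, endian = endian)
  } else {
    readBin(payload, "integer", n = n_values, size = size, endian = endian,
            signed = size > 2)
  }
  if (any(!is.finite(values)))
    stop_format("FCS data contain non-finite values")
  events <- matrix(as.double(values), nrow = n_tot, ncol = n_par, byrow = TRUE)
  colnames(events) <- names_par
  structure(list(parameter_names = names_par, events = events,
                 header_metadata = kw),
            class = "fcs_data")
}

#' @export
print.fcs_data <- function(x, ...) {
  cat(sprintf("<fcs_data> %d events x %d parameters: %s\n",
              nrow(x$events), length(x$parameter_names),
              paste(x$parameter_names, collapse = ", ")))
  invisible(x)
}

#' Convert FCS events to a tibble
#' @param x An `fcs_data` object.
#' @param ... Unused.
#' @return A tibble with one column per parameter.
#' @export
as_tibble.fcs_data <- function(x, ...) {
  as_tibble(as.data.frame(x$events))
}
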