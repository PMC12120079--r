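# TIFF I/O for channel stacks and integer label masks.
#
# Counts are stored as 16-bit integer TIFF pages. Label masks with a maximum
# label below 2^16 are also 16-bit integer; larger masks fall back to 32-bit
# float pages with labels scaled by 2^-24, which represents every integer
# below 2^24 exactly, so round-trips stay bit-exact on the label values.

#' Create a multi-channel image stack
#'
#' A channel stack holds one 2-D intensity matrix per named channel, for
#' example a brightfield channel, a nuclear-stain channel and any number of
#' fluorescence channels acquired from the same field of view.
#'
#' @param channels Named list of numeric matrices, all with identical
#'   dimensions. Intensities are arbitrary-unit counts and must be finite and
#'   non-negative.
#' @param pixel_size_um Optional physical pixel size in micrometres. All
#'   geometry in the package is computed in pixels; this is carried as
#'   metadata only.
#' @param metadata Named character vector of free-form metadata.
#' @return An object of class `channel_stack`.
#' @export
channel_stack <- function(channels, pixel_size_um = NULL, metadata = character()) {
  if (!is.list(channels) || length(channels) == 0)
    stop_value("`channels` must be a non-empty named list of matrices")
  nms <- names(channels)
  if (is.null(nms) || any(!nzchar(nms)) || anyDuplicated(nms))
    stop_value("channel names must be unique and non-empty")
  dims <- map(channels, dim)
  if (any(map_lgl(channels, function(m) !is.matrix(m) || !is.numeric(m))))
    stop_value("every channel must be a numeric matrix")
  ref <- dims[[1]]
  if (any(map_lgl(dims, function(d) !identical(d, ref))))
    stop_value("all channels must share identical height x width")
  bad <- map_lgl(channels, function(m) any(!is.finite(m)) || any(m < 0))
  if (any(bad))
    stop_value(paste0("channel intensities must be finite and >= 0 (offending: ",
                      paste(nms[bad], collapse = ", "), ")"))
  channels <- map(channels, function(m) { storage.mode(m) <- "double"; m })
  structure(
    list(channels = channels, pixel_size_um = pixel_size_um, metadata = metadata),
    class = "channel_stack"
  )
}

#' @export
print.channel_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<channel_stack> %d x %d px, %d channel(s): %s\n",
              d[1], d[2], length(x$channels),
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' @export
dim.channel_stack <- function(x) dim(x$channels[[1]])

#' Read a multi-page TIFF as a channel stack
#'
#' Each TIFF page becomes one channel, in the order of `channel_names`.
#' Integer pixel types are converted to floating-point intensities without
#' rescaling, so counts written by a camera (or by
#' [write_channel_stack()]) read back unchanged.
#'
#' @param path Path to a single- or multi-page TIFF file.
#' @param channel_names Character vector naming the pages in order; its
#'   length must equal the page count.
#' @return A [channel_stack()].
#' @export
read_channel_stack <- function(path, channel_names) {
  if (!file.exists(path)) stop_io(paste0("cannot read TIFF: ", path))
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) stop_io(paste0("unreadable TIFF ", path, ": ",
                                                       conditionMessage(e))))
  if (!is.list(pages)) pages <- list(pages)
  # a single page with a 3rd dimension is treated as a plane-per-channel stack
  if (length(pages) == 1 && length(dim(pages[[1]])) == 3) {
    arr <- pages[[1]]
    pages <- map(seq_len(dim(arr)[3]), function(k) arr[, , k])
  }
  if (length(pages) != length(channel_names))
    stop_format(sprintf(
      "channel count mismatch: file '%s' has %d page(s) but %d name(s) given",
      path, length(pages), length(channel_names)))
  channels <- setNames(map(pages, function(p) {
    storage.mode(p) <- "double"
    p
  }), channel_names)
  channel_stack(channels)
}

#' Write a channel stack to a multi-page 16-bit TIFF
#'
#' @param stack A [channel_stack()]. Intensities must be integer-valued counts
#'   in `[0, 65535]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_channel_stack <- function(stack, path) {
  stopifnot(inherits(stack, "channel_stack"))
  mx <- max(map_dbl(stack$channels, max), 0)
  if (mx > 65535)
    stop_format("channel intensities exceed the 16-bit range (max 65535)")
  pages <- map(stack$channels, function(m) round(m) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

# label masks -----------------------------------------------------------------

assert_label_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask) || !is.numeric(mask))
    stop_value(paste0("`", arg, "` must be a numeric matrix"))
  if (any(!is.finite(mask)) || any(mask < 0))
    stop_format(paste0("`", arg, "` must be finite and non-negative"))
  if (any(mask != round(mask)))
    stop_format(paste0("`", arg, "` must be integer-valued (labels)"))
  storage.mode(mask) <- "integer"
  mask
}

#' Read an integer label mask
#'
#' Labels are read back exactly as written; 0 is background and labels need
#' not be contiguous (filters delete labels without relabeling, preserving
#' traceability across pipeline stages).
#'
#' @param path Path to a single-page TIFF written by [write_label_mask()] or
#'   any integer-valued single-page TIFF.
#' @return An integer matrix.
#' @export
read_label_mask <- function(path) {
  if (!file.exists(path)) stop_io(paste0("cannot read mask: ", path))
  info <- tryCatch(tiff::readTIFF(path, payload = FALSE),
                   error = function(e) stop_io(paste0("unreadable TIFF ", path, ": ",
                                                      conditionMessage(e))))
  if (is.data.frame(info) && nrow(info) > 1)
    stop_format("label masks must be single-page images")
  bits <- if (is.data.frame(info)) info$bits.per.sample[1] else info$bits.per.sample
  if (!is.null(bits) && bits == 32) {
    m <- tiff::readTIFF(path) * 2^24
    tol <- 0.01   # 32-bit samples are quantized at 2^24 / (2^32 - 1) ~ 0.004
  } else {
    m <- tiff::readTIFF(path, as.is = TRUE)
    tol <- 1e-6
  }
  if (length(dim(m)) == 3) stop_format("label masks must be single-plane images")
  if (max(abs(m - round(m))) > tol)
    stop_format("mask contains non-integer pixel values")
  m <- round(m)
  if (any(m < 0)) stop_format("mask contains negative values")
  storage.mode(m) <- "integer"
  m
}

#' Write an integer label mask
#'
#' @param mask Integer matrix of non-negative labels (0 = background).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_label_mask <- function(mask, path) {
  mask <- assert_label_mask(mask)
  mx <- max(mask, 0L)
  if (mx < 2^16) {
    tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L)
  } else if (mx < 2^24) {
    tiff::writeTIFF(mask / 2^24, path, bits.per.sample = 32L)
  } else {
    stop_format("labels above 2^24 are not supported by the TIFF writer")
  }
  invisible(path)
}
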