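# Minimal FCS 3.1 writer used only to create round-trip fixtures for the
# reader; the package itself does not write FCS.

write_fcs_fixture <- function(path, events, parameter_names,
                              datatype = c("F", "I"), endian = "little",
                              mode = "L", version = "FCS3.1") {
  datatype <- match.arg(datatype)
  stopifnot(ncol(events) == length(parameter_names))
  n_par <- ncol(events); n_tot <- nrow(events)
  bits <- if (datatype == "F") 32L else 32L

  kw <- c("$DATATYPE", datatype, "$MODE", mode,
          "$BYTEORD", if (endian == "little") "1,2,3,4" else "4,3,2,1",
          "$PAR", as.character(n_par), "$TOT", as.character(n_tot),
          "$NEXTDATA", "0")
  for (i in seq_len(n_par)) {
    kw <- c(kw, paste0("$P", i, "B"), as.character(bits),
            paste0("$P", i, "N"), parameter_names[i],
            paste0("$P", i, "R"), "262144",
            paste0("$P", i, "E"), "0,0")
  }
  text <- paste0("/", paste(kw, collapse = "/"), "/")

  header_len <- 58L
  # pad the header to a fixed width, then place TEXT right after it
  text_begin <- header_len
  text_end <- text_begin + nchar(text) - 1L
  data_begin <- text_end + 1L
  data_end <- data_begin + n_par * n_tot * (bits / 8) - 1L
  fmt8 <- function(x) formatC(as.integer(x), width = 8, format = "d", flag = " ")
  header <- paste0(version, "    ",
                   fmt8(text_begin), fmt8(text_end),
                   fmt8(data_begin), fmt8(data_end),
                   fmt8(0), fmt8(0))
  stopifnot(nchar(header) == header_len)

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  values <- as.vector(t(events))   # event-major (row by row)
  if (datatype == "F") {
    writeBin(as.double(values), con, size = 4, endian = endian)
  } else {
    writeBin(as.integer(values), con, size = 4, endian = endian)
  }
  invisible(path)
}
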