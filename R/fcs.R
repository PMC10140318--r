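# Minimal FCS 3.1 writer/reader.
#
# Supports the subset used by this pipeline: a single dataset in list mode
# ($MODE L), 32-bit float data ($DATATYPE F), linear amplification, little-
# or big-endian byte order. This is deliberately not a general FCS
# implementation: analysis segments, multiple datasets, and integer or
# log-amplified data are out of scope.

#' Write events to an FCS 3.1 file
#'
#' @param events data frame of numeric channel columns; column names are
#'   mapped to `$PnN` short names (`fl1_h` -> `FL1-H`, `fl3_h` -> `FL3-H`,
#'   `fsc_h` -> `FSC-H`, anything else upper-cased).
#' @param path output file.
#' @param extra_keywords named character vector merged into the TEXT
#'   segment (e.g. acquisition metadata).
#' @return `path`, invisibly.
#' @seealso [read_fcs()]
#' @export
write_fcs <- function(events, path, extra_keywords = NULL) {
  stopifnot(is.data.frame(events), nrow(events) > 0)
  num <- vapply(events, is.numeric, logical(1))
  events <- events[num]
  if (ncol(events) == 0L) abort("no numeric channel columns to write")
  chan_names <- vapply(names(events), fcs_channel_name, "")
  n <- nrow(events)
  p <- ncol(events)

  kw <- c(
    "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
    "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
    "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
    "$NEXTDATA" = "0", "$PAR" = as.character(p), "$TOT" = as.character(n)
  )
  for (j in seq_len(p)) {
    kw[sprintf("$P%dN", j)] <- chan_names[j]
    kw[sprintf("$P%dB", j)] <- "32"
    kw[sprintf("$P%dE", j)] <- "0,0"
    kw[sprintf("$P%dR", j)] <- format(ceiling(max(events[[j]], 1)),
                                      scientific = FALSE)
  }
  if (!is.null(extra_keywords)) kw[names(extra_keywords)] <- extra_keywords

  delim <- "/"
  build_text <- function(begin_data, end_data) {
    kw2 <- c(kw, "$BEGINDATA" = sprintf("%010d", begin_data),
             "$ENDDATA" = sprintf("%010d", end_data))
    paste0(delim, paste0(names(kw2), delim, unname(kw2), delim,
                         collapse = ""))
  }
  text_len <- nchar(build_text(0, 0), type = "bytes")
  text_start <- 58L
  text_end <- text_start + text_len - 1L
  data_start <- text_end + 1L
  data_end <- data_start + 4L * n * p - 1L
  text <- build_text(data_start, data_end)

  header <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d",
                    text_start, text_end,
                    if (data_end <= 99999999) data_start else 0,
                    if (data_end <= 99999999) data_end else 0, 0, 0)

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  # list mode: event-major (row-wise) order
  writeBin(as.numeric(t(as.matrix(events))), con, size = 4,
           endian = "little")
  invisible(path)
}

#' Read a list-mode float FCS file
#'
#' Parses the subset of FCS 3.0/3.1 written by [write_fcs()]: single
#' dataset, `$MODE L`, `$DATATYPE F`, 32-bit parameters.
#'
#' @param path FCS file.
#' @return List with `events` (data frame, columns named from `$PnN`,
#'   lower-cased with `-` -> `_`) and `keywords` (named character vector).
#' @export
read_fcs <- function(path) {
  if (!file.exists(path)) abort("FCS file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readChar(con, 58, useBytes = TRUE)
  if (!grepl("^FCS3", header)) {
    abort("not an FCS 3.x file (header '%s')", substr(header, 1, 6))
  }
  offs <- suppressWarnings(as.integer(substring(
    header, 10 + 8 * (0:3) + 1, 10 + 8 * (1:4))))
  if (any(is.na(offs[1:2]))) abort("unparseable FCS header offsets")
  text_start <- offs[1]; text_end <- offs[2]

  seek(con, text_start)
  text <- readChar(con, text_end - text_start + 1L, useBytes = TRUE)
  delim <- substr(text, 1, 1)
  parts <- strsplit(substring(text, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  keys <- parts[seq(1, length(parts), by = 2)]
  vals <- parts[seq(2, length(parts), by = 2)]
  kw <- stats::setNames(vals, toupper(trimws(keys)))

  if (!identical(kw[["$DATATYPE"]], "F") || !identical(kw[["$MODE"]], "L")) {
    abort("unsupported FCS layout: only list-mode float data is supported ($DATATYPE=%s, $MODE=%s)",
          kw[["$DATATYPE"]] %||% "?", kw[["$MODE"]] %||% "?")
  }
  p <- as.integer(kw[["$PAR"]])
  n <- as.integer(kw[["$TOT"]])
  data_start <- offs[3]
  if (is.na(data_start) || data_start == 0L) {
    data_start <- as.integer(kw[["$BEGINDATA"]])
  }
  endian <- if (identical(kw[["$BYTEORD"]], "4,3,2,1")) "big" else "little"

  seek(con, data_start)
  raw_vals <- readBin(con, numeric(), n = n * p, size = 4, endian = endian)
  m <- matrix(raw_vals, nrow = n, ncol = p, byrow = TRUE)
  nm <- vapply(seq_len(p), function(j) kw[[sprintf("$P%dN", j)]], "")
  colnames(m) <- gsub("-", "_", tolower(nm), fixed = TRUE)
  list(events = as.data.frame(m), keywords = kw)
}

fcs_channel_name <- function(x) {
  switch(x,
         fl1_h = "FL1-H", fl3_h = "FL3-H", fsc_h = "FSC-H",
         ssc_h = "SSC-H",
         gsub("_", "-", toupper(x), fixed = TRUE))
}
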