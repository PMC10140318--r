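#' Read flow-cytometry events from disk
#'
#' Accepts either the tidy CSV interchange format (columns `time_h`,
#' `fl1_h`, `fl3_h`, optionally `fsc_h` and `true_label`; one event per
#' row) or a list-mode float FCS 3.0/3.1 file. FL1-H and FL3-H are
#' required; a missing FSC-H is tolerated with a warning (size summaries
#' are then unavailable).
#'
#' @param path file to read.
#' @param format `"auto"` (by extension), `"csv"` or `"fcs"`.
#' @param acquired_volume_ul,dilution_factor,instrument_threshold_fl1
#'   acquisition metadata; when `NULL` they are taken from the metadata
#'   sidecar (`<path>.meta.yaml`) or FCS keywords, falling back to the
#'   instrument defaults (20 uL, 1000x, threshold 500).
#' @return A single `fcm_sample`, or a list of them when a CSV holds
#'   multiple sampling times.
#' @seealso [write_fcm_events()], [read_fcs()]
#' @export
read_fcm_events <- function(path, format = c("auto", "csv", "fcs"),
                            acquired_volume_ul = NULL,
                            dilution_factor = NULL,
                            instrument_threshold_fl1 = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.fcs$", path, ignore.case = TRUE)) "fcs" else "csv"
  }
  if (!file.exists(path)) abort("event file not found: %s", path)

  meta <- list(acquired_volume_ul = acquired_volume_ul,
               dilution_factor = dilution_factor,
               instrument_threshold_fl1 = instrument_threshold_fl1)

  if (format == "csv") {
    events <- utils::read.csv(path)
    sidecar <- paste0(path, ".meta.yaml")
    if (file.exists(sidecar)) {
      sc <- yaml::read_yaml(sidecar)
      for (nm in names(meta)) meta[[nm]] <- meta[[nm]] %||% sc[[nm]]
    }
    check_channels(names(events))
    time_col <- if ("time_h" %in% names(events)) events$time_h else 0
    build <- function(ev, t) {
      fcm_sample(time_h = t,
                 events = ev[setdiff(names(ev), "time_h")],
                 acquired_volume_ul = meta$acquired_volume_ul %||% 20,
                 dilution_factor = meta$dilution_factor %||% 1000,
                 instrument_threshold_fl1 =
                   meta$instrument_threshold_fl1 %||% 500)
    }
    times <- unique(time_col)
    if (length(times) <= 1L) {
      return(build(events, times[1] %||% 0))
    }
    return(lapply(sort(times),
                  function(t) build(events[time_col == t, , drop = FALSE], t)))
  }

  fcs <- read_fcs(path)
  check_channels(names(fcs$events))
  kw <- fcs$keywords
  num_kw <- function(key) {
    if (!is.null(kw[[key]]) && !is.na(kw[[key]])) as.numeric(kw[[key]]) else NULL
  }
  fcm_sample(
    time_h = num_kw("TIME_H") %||% 0,
    events = fcs$events,
    acquired_volume_ul = meta$acquired_volume_ul %||%
      num_kw("VOLUME_UL") %||% 20,
    dilution_factor = meta$dilution_factor %||% num_kw("DILUTION") %||% 1000,
    instrument_threshold_fl1 = meta$instrument_threshold_fl1 %||%
      num_kw("THRESHOLD_FL1") %||% 500
  )
}

check_channels <- function(nms) {
  miss <- setdiff(c("fl1_h", "fl3_h"), nms)
  if (length(miss)) {
    abort("missing required channel(s) %s; available channels: %s",
          paste(toupper(gsub("_", "-", miss)), collapse = ", "),
          paste(nms, collapse = ", "))
  }
  if (!"fsc_h" %in% nms) {
    warn("FSC-H channel absent; forward-scatter summaries will be unavailable")
  }
  invisible(TRUE)
}

#' Write flow-cytometry samples to disk
#'
#' CSV output is the tidy interchange format (one event per row, `time_h`
#' column, metadata in a YAML sidecar); FCS output writes one FCS 3.1 file
#' per sample with acquisition metadata as custom keywords.
#'
#' @param samples an `fcm_sample` or list of them.
#' @param path CSV file path, or (for `format = "fcs"`) a directory that
#'   will receive `sample_###.fcs` files.
#' @param format `"csv"` or `"fcs"`.
#' @return The path(s) written, invisibly.
#' @export
write_fcm_events <- function(samples, path, format = c("csv", "fcs")) {
  format <- match.arg(format)
  if (inherits(samples, "fcm_sample")) samples <- list(samples)
  stopifnot(all(vapply(samples, inherits, logical(1), "fcm_sample")))

  if (format == "csv") {
    tidy <- do.call(rbind, lapply(samples, function(s) {
      cbind(data.frame(time_h = s$time_h), s$events)
    }))
    utils::write.csv(tidy, path, row.names = FALSE)
    s1 <- samples[[1]]
    yaml::write_yaml(
      list(acquired_volume_ul = s1$acquired_volume_ul,
           dilution_factor = s1$dilution_factor,
           instrument_threshold_fl1 = s1$instrument_threshold_fl1),
      paste0(path, ".meta.yaml"))
    return(invisible(path))
  }

  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  out <- vapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    f <- file.path(path, sprintf("sample_%03d.fcs", i))
    write_fcs(s$events, f, extra_keywords = c(
      TIME_H = format(s$time_h),
      VOLUME_UL = format(s$acquired_volume_ul),
      DILUTION = format(s$dilution_factor),
      THRESHOLD_FL1 = format(s$instrument_threshold_fl1)))
    f
  }, "")
  invisible(out)
}
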