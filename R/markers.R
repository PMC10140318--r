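#' Freeze-drying survivability
#'
#' Percentage of viable cells (plate counts) retained through
#' freeze-drying: `100 * cfu_after / cfu_before`. Values above 100% are
#' reported as-is with a warning flag (they indicate counting error, not
#' growth). The measure is deliberately CFU-based; an FCM-intact-based
#' variant would answer a different question and is not conflated here.
#'
#' @param cfu_before,cfu_after viable counts (CFU/mL) before and after
#'   freeze-drying; `cfu_before` must be positive.
#' @return Numeric percentage with attributes `above_100` and `extinct`
#'   (logical flags).
#' @examples
#' fd_survivability(2.0e9, 1.236e9) # 61.8
#' @export
fd_survivability <- function(cfu_before, cfu_after) {
  stopifnot_scalar(cfu_before, "cfu_before", 0, strict = TRUE)
  stopifnot_scalar(cfu_after, "cfu_after", 0)
  pct <- 100 * cfu_after / cfu_before
  if (pct > 100) warn("survivability %.1f%% exceeds 100%%; check counts", pct)
  if (cfu_after == 0) warn("no viable cells after freeze-drying (extinction)")
  structure(pct, above_100 = pct > 100, extinct = cfu_after == 0)
}

#' Summarise an acid-challenge survival assay
#'
#' Per-timepoint log10 reduction relative to the uncensored time-zero
#' count, and the death rate as the negative slope of the least-squares
#' fit of log10 CFU on time over the uncensored points (at least 2
#' required; otherwise the rate is reported as undefined). Censored
#' points are excluded from the fit and counted. A per-assay
#' `survived_at_end` flag records uncensored detection at the final
#' timepoint, supporting statements of the form "survived at 90 min in
#' k out of n experiments".
#'
#' @param assay a `survival_assay` (see [simulate_acid_challenge()]), or
#'   a data frame with columns `minute`, `cfu`, `censored`.
#' @return List of class `acid_summary`: `log10_reduction` data frame,
#'   `death_rate` (log10 CFU per minute, `NA` if undefined),
#'   `n_censored`, `survived_at_end`, `fit_points`.
#' @examples
#' a <- list(data = data.frame(minute = c(0, 20, 40),
#'                             cfu = c(1e8, 1e7, 1e6),
#'                             censored = FALSE), lod = 1e3)
#' acid_survival_summary(a)$death_rate # 0.05
#' @export
acid_survival_summary <- function(assay) {
  d <- if (is.data.frame(assay)) assay else assay$data
  stopifnot(all(c("minute", "cfu", "censored") %in% names(d)))
  if (is.unsorted(d$minute, strictly = TRUE)) {
    abort("timepoints must be strictly increasing")
  }
  if (d$minute[1] != 0 || d$censored[1]) {
    abort("an uncensored timepoint-0 count is required as the reference")
  }
  log_red <- log10(d$cfu / d$cfu[1])
  log_red[d$censored] <- NA_real_

  unc <- !d$censored
  death_rate <- NA_real_
  if (sum(unc) >= 2) {
    fit <- stats::lm.fit(cbind(1, d$minute[unc]), log10(d$cfu[unc]))
    death_rate <- -unname(fit$coefficients[2])
  } else {
    warn("fewer than 2 uncensored points; death rate undefined")
  }
  structure(
    list(log10_reduction = data.frame(minute = d$minute,
                                      log10_reduction = log_red,
                                      censored = d$censored),
         death_rate = death_rate,
         n_censored = sum(d$censored),
         survived_at_end = !d$censored[nrow(d)],
         fit_points = sum(unc)),
    class = "acid_summary"
  )
}

#' Bile-tolerance lag time
#'
#' Time of the first upward crossing of the OD cutoff (default 0.5, the
#' conventional marker for the start of exponential growth in bile),
#' linearly interpolated between the bracketing samples of the 15-min
#' grid. Curves that never reach the cutoff report "not reached". No
#' smoothing is applied in the primary mode, so a transient single-point
#' spike above the cutoff is honoured; `smooth = TRUE` applies a 3-point
#' running median first.
#'
#' @param curve a `bile_curve` (see [simulate_bile_curve()]) or a data
#'   frame with columns `time_h`, `od`.
#' @param cutoff OD threshold (default taken from the curve, else 0.5).
#' @param smooth apply 3-point median smoothing before crossing detection.
#' @return List of class `bile_lag`: `lag_h` (numeric, `NA` when not
#'   reached), `reached` (logical), `started_above` (logical; the curve
#'   began at or above the cutoff, lag 0 with a warning).
#' @export
bile_lag_time <- function(curve, cutoff = NULL, smooth = FALSE) {
  d <- if (is.data.frame(curve)) curve else curve$data
  stopifnot(all(c("time_h", "od") %in% names(d)), nrow(d) >= 2)
  if (is.null(cutoff)) {
    cutoff <- if (!is.data.frame(curve) && !is.null(curve$cutoff)) {
      curve$cutoff
    } else {
      0.5
    }
  }
  od <- d$od
  if (smooth && length(od) >= 3) od <- stats::runmed(od, 3)

  if (od[1] >= cutoff) {
    warn("curve starts at OD %.3f, already at/above the cutoff %.2f", od[1],
         cutoff)
    return(structure(list(lag_h = 0, reached = TRUE, started_above = TRUE),
                     class = "bile_lag"))
  }
  above <- which(od >= cutoff)
  if (!length(above)) {
    return(structure(list(lag_h = NA_real_, reached = FALSE,
                          started_above = FALSE), class = "bile_lag"))
  }
  j <- above[1]
  i <- j - 1L
  lag <- if (od[j] == cutoff) {
    d$time_h[j]
  } else {
    d$time_h[i] + (cutoff - od[i]) * (d$time_h[j] - d$time_h[i]) /
      (od[j] - od[i])
  }
  structure(list(lag_h = unname(lag), reached = TRUE, started_above = FALSE),
            class = "bile_lag")
}

#' @export
print.bile_lag <- function(x, ...) {
  cat(if (x$reached) sprintf("OD cutoff reached at %.2f h\n", x$lag_h)
      else "OD cutoff not reached\n")
  invisible(x)
}

#' Summarise 5'-nucleotidase activity measurements
#'
#' Mean and SD of enzyme activity (U/L) per condition. With nested
#' technical replicates inside biological replicates, the primary mode
#' averages technical replicates within each biological replicate first
#' and summarises across biological means, so pseudo-replication does not
#' shrink the SD. `mode = "pooled"` summarises all measurements flat.
#'
#' @param measurements data frame with columns `condition`,
#'   `biological_rep`, `u_per_l`, and optionally `technical_rep`.
#' @param mode `"nested"` (primary) or `"pooled"`.
#' @return Data frame with columns `condition`, `mean_u_per_l`,
#'   `sd_u_per_l`, `n`.
#' @export
nt_activity_summary <- function(measurements, mode = c("nested", "pooled")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(measurements),
            all(c("condition", "u_per_l") %in% names(measurements)))
  if (nrow(measurements) == 0) abort("no measurements supplied")
  if (mode == "nested" && !"biological_rep" %in% names(measurements)) {
    abort("nested mode requires a 'biological_rep' column")
  }
  out <- lapply(split(measurements, measurements$condition), function(m) {
    vals <- if (mode == "nested") {
      tapply(m$u_per_l, m$biological_rep, mean)
    } else {
      m$u_per_l
    }
    data.frame(condition = m$condition[1], mean_u_per_l = mean(vals),
               sd_u_per_l = if (length(vals) > 1) stats::sd(vals) else 0,
               n = length(vals))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
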