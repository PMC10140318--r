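#' Construct a flow-cytometry sample
#'
#' One timestamped batch of events as acquired by an online flow cytometer
#' (e.g. a BD Accuri drawing from the reactor through an automated
#' dilution/staining module).
#'
#' @param time_h sampling time (h since inoculation).
#' @param events data frame with numeric columns `fl1_h`, `fl3_h` and
#'   optionally `fsc_h` (channel intensities, >= 0) plus any extra columns
#'   (e.g. `true_label` for synthetic data).
#' @param acquired_volume_ul sample volume acquired by the instrument (uL).
#' @param dilution_factor fold-dilution applied upstream of acquisition.
#' @param instrument_threshold_fl1 acquisition threshold on FL1-H (channel
#'   number); events below it are discarded during preprocessing.
#' @return An object of class `fcm_sample`.
#' @export
fcm_sample <- function(time_h, events, acquired_volume_ul = 20,
                       dilution_factor = 1000,
                       instrument_threshold_fl1 = 500) {
  stopifnot_scalar(time_h, "time_h", 0)
  stopifnot_scalar(acquired_volume_ul, "acquired_volume_ul", 0, strict = TRUE)
  stopifnot_scalar(dilution_factor, "dilution_factor", 1)
  stopifnot(is.data.frame(events))
  need <- c("fl1_h", "fl3_h")
  miss <- setdiff(need, names(events))
  if (length(miss)) {
    abort("events lack required channel column(s) %s; available: %s",
          paste(miss, collapse = ", "), paste(names(events), collapse = ", "))
  }
  chan <- intersect(c("fl1_h", "fl3_h", "fsc_h"), names(events))
  for (ch in chan) {
    if (any(!is.finite(events[[ch]])) || any(events[[ch]] < 0)) {
      abort("channel '%s' contains negative or non-finite values", ch)
    }
  }
  structure(
    list(time_h = time_h, events = events,
         acquired_volume_ul = acquired_volume_ul,
         dilution_factor = dilution_factor,
         instrument_threshold_fl1 = instrument_threshold_fl1),
    class = "fcm_sample"
  )
}

#' @export
print.fcm_sample <- function(x, ...) {
  cat(sprintf("<fcm_sample> t = %.2f h, %d events, %g uL at %gx dilution, FL1 threshold %g\n",
              x$time_h, nrow(x$events), x$acquired_volume_ul,
              x$dilution_factor, x$instrument_threshold_fl1))
  invisible(x)
}

#' Simulate an online flow-cytometry time course
#'
#' Draws seeded event batches along a cultivation: at each sampling time
#' the four viability subpopulations contribute events according to their
#' `fraction_trajectory`, each subpopulation being a log-normal cloud in
#' (FL1-H, FL3-H) channel space per its [population_spec()]. The number of
#' events per sample tracks culture biomass, and the effective dilution
#' factor is chosen so that [count_populations()] recovers the profile's
#' true cell concentration. Forward scatter is drawn log-normally with a
#' mid-cultivation maximum (cells are smallest at the start and end of the
#' batch). The generating subpopulation of every event is retained in the
#' `true_label` column for downstream validation.
#'
#' @param profile a `culture_profile` from [simulate_batch_culture()].
#' @param specs named list of four [population_spec()] objects (default
#'   [default_population_specs()]).
#' @param events_per_sample expected event count at harvest biomass
#'   (>= 100); earlier samples contain proportionally fewer events.
#' @param interval_h sampling interval (h); the default 0.5 matches about
#'   two samples per hour.
#' @param seed integer seed; expands deterministically into per-sample
#'   seeds.
#' @param afu_per_gram_cdw calibration from biomass (g/L) to total events
#'   per mL of undiluted culture; must match the value used for the
#'   profile.
#' @return List of `fcm_sample` objects.
#' @examples
#' prof <- simulate_batch_culture(culture_scenario(noise_cv = 0))
#' fcm <- simulate_fcm_timeseries(prof, events_per_sample = 500, seed = 7)
#' table(fcm[[1]]$events$true_label)
#' @export
simulate_fcm_timeseries <- function(profile,
                                    specs = default_population_specs(),
                                    events_per_sample = 10000,
                                    interval_h = 0.5,
                                    seed = 1L,
                                    afu_per_gram_cdw = 1.25e9) {
  stopifnot(inherits(profile, "culture_profile"))
  if (events_per_sample < 100) {
    abort("events_per_sample must be >= 100 (got %g)", events_per_sample)
  }
  if (length(specs) != 4L ||
      !setequal(vapply(specs, `[[`, "", "name"),
                c("intact", "damaged_A", "damaged_B", "debris"))) {
    abort("specs must cover exactly the four populations intact, damaged_A, damaged_B, debris")
  }
  specs <- specs[order(match(vapply(specs, `[[`, "", "name"),
                             c("intact", "damaged_A", "damaged_B", "debris")))]

  horizon <- max(profile$series$time_h)
  times <- seq(0, horizon, by = interval_h)
  check_fraction_sum(specs, times)

  # Biomass (hence concentration) at FCM sampling times, interpolated from
  # the noiseless series when available.
  src <- if (!is.null(profile$truth)) profile$truth$series else profile$series
  conc <- stats::approx(src$time_h, src$fcm_total_afu_ml, xout = times,
                        rule = 2)$y
  conc_max <- max(conc)
  vol_ml <- 20 / 1000
  dilution <- conc_max * vol_ml / events_per_sample

  lapply(seq_along(times), function(i) {
    t <- times[i]
    n <- max(100L, as.integer(round(conc[i] * vol_ml / dilution)))
    w <- vapply(specs, function(p) p$fraction_trajectory(t), numeric(1))
    with_seed(derive_seed(seed, i), {
      counts <- as.vector(stats::rmultinom(1, n, w))
      lab <- rep(names(specs), counts)
      fl1 <- numeric(n)
      fl3 <- numeric(n)
      idx0 <- cumsum(c(0, counts))
      for (j in seq_along(specs)) {
        if (counts[j] == 0) next
        sel <- (idx0[j] + 1):idx0[j + 1]
        p <- specs[[j]]
        fl1[sel] <- 10^stats::rnorm(counts[j], p$log10_fl1_mean, p$log10_sd)
        fl3[sel] <- 10^stats::rnorm(counts[j], p$log10_fl3_mean, p$log10_sd)
      }
      fsc_mu <- 3.9 + 0.2 * sin(pi * t / max(horizon, 1e-9))
      fsc <- 10^stats::rnorm(n, fsc_mu, 0.15)
      fcm_sample(
        time_h = t,
        events = data.frame(fl1_h = fl1, fl3_h = fl3, fsc_h = fsc,
                            true_label = lab),
        acquired_volume_ul = 20,
        dilution_factor = dilution
      )
    })
  })
}
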