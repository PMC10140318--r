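#' Simulate a low-pH (synthetic gastric juice) survival assay
#'
#' Viable counts decline log-linearly at `death_rate` (log10 CFU per
#' minute); plate counts carry Poisson noise: each timepoint is plated at
#' the serial dilution that targets `colonies_target` colonies, the
#' colony count is a Poisson draw, and the count is scaled back to
#' CFU/mL. Observations falling below the limit of detection are
#' reported at the LOD and flagged censored, never as zero — a zero-colony
#' plate bounds the concentration, it does not measure it.
#'
#' @param cfu_0 starting concentration (CFU/mL), above `lod`.
#' @param death_rate decline rate (log10 CFU per minute, >= 0).
#' @param timepoints sampling times in minutes (default the standard
#'   0/20/50/90 grid).
#' @param lod limit of detection (CFU/mL).
#' @param seed integer seed.
#' @param colonies_target expected colony count on the counted plate
#'   (sets the Poisson noise scale).
#' @param condition,replicate labels carried into the result.
#' @return An object of class `survival_assay`: data frame `data` with
#'   columns `minute`, `cfu`, `censored`, plus `lod`, `condition`,
#'   `replicate`.
#' @export
simulate_acid_challenge <- function(cfu_0, death_rate,
                                    timepoints = c(0, 20, 50, 90),
                                    lod = 1e3, seed = 1L,
                                    colonies_target = 100,
                                    condition = "synthetic",
                                    replicate = 1L) {
  stopifnot_scalar(cfu_0, "cfu_0", 0, strict = TRUE)
  stopifnot_scalar(death_rate, "death_rate", 0)
  stopifnot_scalar(lod, "lod", 0, strict = TRUE)
  if (cfu_0 <= lod) abort("cfu_0 (%g) must exceed the LOD (%g)", cfu_0, lod)
  expected <- cfu_0 * 10^(-death_rate * timepoints)
  obs <- with_seed(seed, {
    vapply(expected, function(e) {
      if (e <= 0) return(0)
      # serial dilution targeting ~colonies_target colonies on the plate
      scale <- e / colonies_target
      stats::rpois(1, colonies_target) * scale
    }, numeric(1))
  })
  censored <- obs < lod
  obs[censored] <- lod
  structure(
    list(data = data.frame(minute = timepoints, cfu = obs,
                           censored = censored),
         lod = lod, condition = condition, replicate = replicate),
    class = "survival_assay"
  )
}

#' Simulate a bile-tolerance growth curve
#'
#' Microplate OD readings on a 15-min grid: a flat baseline during the
#' bile-adaptation lag, then a logistic rise from the baseline towards
#' `od_max` at specific growth rate `mu`. Optional multiplicative noise
#' emulates reader scatter.
#'
#' @param lag_h lag-phase duration (h), shorter than `horizon_h`.
#' @param mu specific growth rate once growth resumes (1/h).
#' @param od_max carrying-capacity OD.
#' @param od_0 baseline OD of the inoculated well.
#' @param interval_min sampling interval (minutes, default 15).
#' @param horizon_h total incubation (h, default 24).
#' @param noise_cv multiplicative noise CV (0 = noiseless).
#' @param seed integer seed.
#' @param condition,well labels carried into the result.
#' @return An object of class `bile_curve`: data frame `data` with
#'   columns `time_h`, `od`, plus `cutoff` (0.5) and the labels.
#' @export
simulate_bile_curve <- function(lag_h, mu, od_max = 1.2, od_0 = 0.05,
                                interval_min = 15, horizon_h = 24,
                                noise_cv = 0, seed = 1L,
                                condition = "synthetic", well = "A1") {
  stopifnot_scalar(lag_h, "lag_h", 0)
  stopifnot_scalar(mu, "mu", 0, strict = TRUE)
  if (lag_h >= horizon_h) {
    abort("lag_h (%.2f h) must be shorter than horizon_h (%.2f h)",
          lag_h, horizon_h)
  }
  time_h <- seq(0, horizon_h, by = interval_min / 60)
  od <- logistic_od(time_h, lag_h, mu, od_0, od_max)
  if (noise_cv > 0) {
    od <- with_seed(seed, pmax(od * (1 + stats::rnorm(length(od),
                                                      sd = noise_cv)), 0))
  }
  structure(
    list(data = data.frame(time_h = time_h, od = od),
         cutoff = 0.5, condition = condition, well = well),
    class = "bile_curve"
  )
}

# Flat baseline until lag, then logistic growth from od_0 towards od_max.
logistic_od <- function(time_h, lag_h, mu, od_0, od_max) {
  g <- pmax(time_h - lag_h, 0)
  od_max * od_0 * exp(mu * g) / (od_max - od_0 + od_0 * exp(mu * g))
}

# Time at which the noiseless logistic curve crosses `od`; used to
# construct curves with a known crossing for validation.
logistic_crossing_time <- function(lag_h, mu, od_0, od_max, od = 0.5) {
  if (od_max <= od) return(NA_real_)
  lag_h + log(od * (od_max - od_0) / (od_0 * (od_max - od))) / mu
}
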