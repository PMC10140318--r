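#' Simulate a batch cultivation time series
#'
#' Generates hourly OD620, dissolved-oxygen tension (DOT), cumulative base
#' addition, and HPLC metabolite concentrations for one batch culture
#' following a [culture_scenario()]: biomass grows exponentially at
#' `mu_max` after the lag until glucose is exhausted, each product is
#' formed proportionally to the glucose consumed at its fixed yield,
#' citrate is either depleted linearly by `citrate_depletion_h` or left
#' constant, and DOT decays linearly to zero by `dot_depletion_h` (rising
#' again after glucose depletion when the vessel is actively aerated).
#' Additive Gaussian noise with coefficient of variation `noise_cv` is
#' applied to every measured series; the noiseless series are retained in
#' `$truth` so estimators can be validated against the generating values.
#'
#' @param scenario a [culture_scenario()].
#' @param afu_per_gram_cdw flow-cytometry total-count calibration
#'   (events/mL per g/L biomass); sets the scale of the `fcm_total_afu_ml`
#'   column.
#' @return An object of class `culture_profile`: a list with elements
#'   `series` (data frame with columns `time_h`, `od620`, `dot_pct`,
#'   `base_ml`, `glucose_g_l`, `citrate_g_l`, `lactate_g_l`,
#'   `acetate_g_l`, `ethanol_g_l`, `succinate_g_l`, `fcm_total_afu_ml`),
#'   `cdw_harvest` (g/L), `depletion_h` (time glucose reaches zero), and
#'   `truth` (noiseless series plus the scenario).
#' @examples
#' sc <- culture_scenario(mu_max = 0.693, glucose_0 = 10, noise_cv = 0)
#' prof <- simulate_batch_culture(sc)
#' tail(prof$series$lactate_g_l, 1) # = yield_lactate * 10
#' @export
simulate_batch_culture <- function(scenario, afu_per_gram_cdw = 1.25e9) {
  stopifnot(inherits(scenario, "culture_scenario"))
  sc <- scenario
  if (sc$yield_biomass <= 0) {
    abort("yield_biomass must be > 0: glucose consumption is growth-coupled")
  }
  x0 <- sc$od_0 * sc$cdw_per_od
  x_max <- x0 + sc$yield_biomass * sc$glucose_0
  t_dep <- sc$lag_h + log(x_max / x0) / sc$mu_max
  if (t_dep > sc$horizon_h) {
    abort("glucose depletion occurs at %.2f h but the horizon is %.2f h; extend horizon_h",
          t_dep, sc$horizon_h)
  }

  time_h <- seq(0, sc$horizon_h, by = sc$sample_interval_h)
  x <- biomass_at(time_h, x0, sc$mu_max, sc$lag_h, t_dep)
  consumed <- (x - x0) / sc$yield_biomass
  glucose <- pmax(sc$glucose_0 - consumed, 0)
  lactate <- sc$yield_lactate * consumed
  acetate <- sc$yield_acetate * consumed
  ethanol <- sc$yield_ethanol * consumed
  citrate <- if (sc$citrate_consumed) {
    pmax(sc$citrate_0 * (1 - time_h / sc$citrate_depletion_h), 0)
  } else {
    rep(sc$citrate_0, length(time_h))
  }
  dot <- dot_profile(time_h, sc$dot_0, sc$dot_depletion_h, t_dep, sc$aerated)
  od <- x / sc$cdw_per_od
  # 3 M KOH titrant: 1 mol base neutralises 1 mol organic acid.
  base_ml <- (lactate * mol_per_gram("lactate") +
                acetate * mol_per_gram("acetate")) / 3 * 1000
  fcm_total <- x * afu_per_gram_cdw

  clean <- data.frame(
    time_h = time_h, od620 = od, dot_pct = dot, base_ml = base_ml,
    glucose_g_l = glucose, citrate_g_l = citrate, lactate_g_l = lactate,
    acetate_g_l = acetate, ethanol_g_l = ethanol,
    succinate_g_l = rep(0, length(time_h)), fcm_total_afu_ml = fcm_total
  )

  noisy <- clean
  cdw_obs <- x_max
  if (sc$noise_cv > 0) {
    noisy_cols <- setdiff(names(clean), "time_h")
    noisy[noisy_cols] <- with_seed(sc$seed, {
      lapply(clean[noisy_cols], function(v) {
        pmax(v + stats::rnorm(length(v), sd = sc$noise_cv * abs(v)), 0)
      })
    })
    cdw_obs <- with_seed(derive_seed(sc$seed, 1L), {
      max(x_max + stats::rnorm(1, sd = sc$noise_cv * x_max), 0)
    })
  }

  structure(
    list(series = noisy, cdw_harvest = cdw_obs, depletion_h = t_dep,
         truth = list(series = clean, cdw_harvest = x_max, scenario = sc)),
    class = "culture_profile"
  )
}

# Biomass trajectory: flat lag, exponential growth, arrest at depletion.
biomass_at <- function(time_h, x0, mu, lag_h, t_dep) {
  x_max <- x0 * exp(mu * (t_dep - lag_h))
  ifelse(time_h < lag_h, x0,
         ifelse(time_h <= t_dep, x0 * exp(mu * (time_h - lag_h)), x_max))
}

# Piecewise DOT: linear decay to zero, anoxic plateau while glucose lasts,
# linear recovery after depletion when actively aerated.
dot_profile <- function(time_h, dot_0, t_zero, t_dep, aerated) {
  slope <- dot_0 / t_zero
  decay <- pmax(dot_0 - slope * time_h, 0)
  if (!aerated) {
    return(decay)
  }
  recover <- pmin(pmax(time_h - t_dep, 0) * slope, dot_0)
  pmax(decay, ifelse(time_h > t_dep, recover, 0))
}

#' @export
print.culture_profile <- function(x, ...) {
  s <- x$series
  cat("<culture_profile>\n")
  cat(sprintf("  %d samples over %.1f h, glucose depleted at %.2f h\n",
              nrow(s), max(s$time_h), x$depletion_h))
  cat(sprintf("  harvest CDW %.3f g/L, final OD620 %.2f\n",
              x$cdw_harvest, s$od620[nrow(s)]))
  invisible(x)
}

#' Write / read a culture profile as CSV plus metadata sidecar
#'
#' The time series is written as a plain CSV (one row per sampling time);
#' scalar metadata (harvest CDW) goes into a small YAML sidecar next to it.
#'
#' @param profile a `culture_profile`.
#' @param path CSV path; the sidecar is `<path>.meta.yaml`.
#' @return `write_culture_profile()` returns `path` invisibly;
#'   `read_culture_profile()` returns a `culture_profile` (without `truth`).
#' @export
write_culture_profile <- function(profile, path) {
  stopifnot(inherits(profile, "culture_profile"))
  utils::write.csv(profile$series, path, row.names = FALSE)
  yaml::write_yaml(list(cdw_harvest = profile$cdw_harvest,
                        depletion_h = profile$depletion_h),
                   paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname write_culture_profile
#' @param cdw_harvest harvest cell dry weight (g/L); read from the sidecar
#'   when `NULL`.
#' @export
read_culture_profile <- function(path, cdw_harvest = NULL) {
  if (!file.exists(path)) abort("profile file not found: %s", path)
  series <- utils::read.csv(path)
  need <- c("time_h", "glucose_g_l")
  miss <- setdiff(need, names(series))
  if (length(miss)) {
    abort("profile CSV lacks required columns: %s", paste(miss, collapse = ", "))
  }
  meta_path <- paste0(path, ".meta.yaml")
  depletion_h <- NA_real_
  if (is.null(cdw_harvest)) {
    if (!file.exists(meta_path)) {
      abort("no cdw_harvest supplied and no sidecar %s", meta_path)
    }
    meta <- yaml::read_yaml(meta_path)
    cdw_harvest <- meta$cdw_harvest
    depletion_h <- meta$depletion_h %||% NA_real_
  }
  structure(list(series = series, cdw_harvest = cdw_harvest,
                 depletion_h = depletion_h, truth = NULL),
            class = "culture_profile")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
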