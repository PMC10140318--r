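#' Define a batch-cultivation scenario
#'
#' A `culture_scenario` bundles the kinetic and stoichiometric parameters
#' that drive [simulate_batch_culture()]: exponential growth at `mu_max`
#' after a lag, glucose-limited growth arrest, product formation at fixed
#' yields, optional citrate co-consumption, and a piecewise dissolved-oxygen
#' profile.
#'
#' Defaults emulate a 1-L bench bioreactor batch of *L. reuteri* on MRS
#' medium under gentle air sparging: maximum specific growth rate
#' 0.74 h^-1, glucose exhausted about 7 h after inoculation, dissolved
#' oxygen depleted by 2.55 h, and product yields near the heterofermentative
#' optimum so that the end-point carbon balance closes close to 100%.
#'
#' @param mu_max maximum specific growth rate (1/h).
#' @param lag_h lag-phase duration before exponential growth starts (h).
#' @param glucose_0 initial glucose concentration (g/L).
#' @param citrate_0 initial citrate concentration (g/L).
#' @param yield_biomass,yield_lactate,yield_acetate,yield_ethanol product
#'   yields (g product per g glucose consumed).
#' @param citrate_consumed logical; is citrate co-consumed (depleted by
#'   `citrate_depletion_h`) or left untouched?
#' @param citrate_depletion_h time at which citrate reaches zero (h).
#' @param dot_0 initial dissolved-oxygen tension (% air saturation).
#' @param dot_depletion_h time at which DOT reaches zero (h).
#' @param aerated logical; if `TRUE` the DOT recovers after glucose
#'   depletion (active sparging), otherwise it stays at zero.
#' @param od_0 inoculation optical density (OD620).
#' @param cdw_per_od gravimetric conversion factor (g CDW per L per OD620
#'   unit); biomass is `od * cdw_per_od`.
#' @param sample_interval_h sampling interval for OD/HPLC series (h).
#' @param horizon_h total simulated cultivation time (h); must cover
#'   glucose depletion.
#' @param noise_cv coefficient of variation of the additive Gaussian
#'   measurement noise applied to every series (0 = noiseless).
#' @param seed integer seed for the measurement noise.
#'
#' @return An object of class `culture_scenario` (a named list).
#' @seealso [simulate_batch_culture()]
#' @examples
#' sc <- culture_scenario(mu_max = 0.693, glucose_0 = 10, noise_cv = 0)
#' sc$mu_max
#' @export
culture_scenario <- function(mu_max = 0.74,
                             lag_h = 3,
                             glucose_0 = 18,
                             citrate_0 = 2,
                             yield_biomass = 0.085,
                             yield_lactate = 0.48,
                             yield_acetate = 0.10,
                             yield_ethanol = 0.20,
                             citrate_consumed = TRUE,
                             citrate_depletion_h = 3,
                             dot_0 = 100,
                             dot_depletion_h = 2.55,
                             aerated = TRUE,
                             od_0 = 0.2,
                             cdw_per_od = 0.45,
                             sample_interval_h = 1,
                             horizon_h = 8,
                             noise_cv = 0.02,
                             seed = 1L) {
  stopifnot_scalar(mu_max, "mu_max", 0, strict = TRUE)
  stopifnot_scalar(lag_h, "lag_h", 0)
  stopifnot_scalar(glucose_0, "glucose_0", 0, strict = TRUE)
  stopifnot_scalar(citrate_0, "citrate_0", 0)
  for (nm in c("yield_biomass", "yield_lactate", "yield_acetate",
               "yield_ethanol")) {
    stopifnot_scalar(get(nm), nm, 0)
  }
  stopifnot_scalar(od_0, "od_0", 0, strict = TRUE)
  stopifnot_scalar(cdw_per_od, "cdw_per_od", 0, strict = TRUE)
  stopifnot_scalar(sample_interval_h, "sample_interval_h", 0, strict = TRUE)
  stopifnot_scalar(horizon_h, "horizon_h", 0, strict = TRUE)
  stopifnot_scalar(noise_cv, "noise_cv", 0)
  stopifnot(is.logical(citrate_consumed), is.logical(aerated))

  sc <- list(
    mu_max = mu_max, lag_h = lag_h,
    glucose_0 = glucose_0, citrate_0 = citrate_0,
    yield_biomass = yield_biomass, yield_lactate = yield_lactate,
    yield_acetate = yield_acetate, yield_ethanol = yield_ethanol,
    citrate_consumed = isTRUE(citrate_consumed),
    citrate_depletion_h = citrate_depletion_h,
    dot_0 = dot_0, dot_depletion_h = dot_depletion_h,
    aerated = isTRUE(aerated),
    od_0 = od_0, cdw_per_od = cdw_per_od,
    sample_interval_h = sample_interval_h, horizon_h = horizon_h,
    noise_cv = noise_cv, seed = as.integer(seed)
  )
  class(sc) <- "culture_scenario"

  # Stoichiometric sanity: carbon implied by the yields must not exceed
  # substrate carbon by more than 5% (complex-medium biomass carbon allows
  # a mild overshoot).
  implied <- yield_lactate * cmol_per_gram("lactate") +
    yield_acetate * cmol_per_gram("acetate") +
    yield_ethanol * cmol_per_gram("ethanol") +
    yield_biomass * cmol_per_gram("biomass")
  frac <- implied / cmol_per_gram("glucose")
  if (frac > 1.05) {
    abort("yields imply %.1f%% of substrate carbon in products (limit 105%%)",
          100 * frac)
  }
  sc
}

#' @export
print.culture_scenario <- function(x, ...) {
  cat("<culture_scenario>\n")
  cat(sprintf("  mu_max %.3f 1/h, lag %.2f h, glucose_0 %.2f g/L\n",
              x$mu_max, x$lag_h, x$glucose_0))
  cat(sprintf("  yields (g/g): biomass %.3f, lactate %.3f, acetate %.3f, ethanol %.3f\n",
              x$yield_biomass, x$yield_lactate, x$yield_acetate,
              x$yield_ethanol))
  cat(sprintf("  citrate %s, DOT depletes at %.2f h (%s), horizon %.1f h, seed %d\n",
              if (x$citrate_consumed) "consumed" else "not consumed",
              x$dot_depletion_h, if (x$aerated) "aerated" else "anoxic",
              x$horizon_h, x$seed))
  invisible(x)
}

#' Describe one flow-cytometry subpopulation
#'
#' A `population_spec` fixes the location and dispersion of one
#' subpopulation's event cloud in (log10 FL1-H, log10 FL3-H) space and its
#' abundance trajectory over the cultivation. SYBR Green I stains all
#' cells (FL1, green), propidium iodide only membrane-compromised cells
#' (FL3, red), so intact cells sit at high FL1:FL3 ratio while damaged
#' cells shift towards FL3.
#'
#' @param name one of `"intact"`, `"damaged_A"`, `"damaged_B"`, `"debris"`.
#' @param log10_fl1_mean,log10_fl3_mean cloud centre in log10 channel units.
#' @param log10_sd isotropic dispersion in log10 channel units.
#' @param fraction_trajectory function of time (h) returning the population
#'   fraction in `[0, 1]`.
#' @return An object of class `population_spec`.
#' @seealso [default_population_specs()], [simulate_fcm_timeseries()]
#' @export
population_spec <- function(name, log10_fl1_mean, log10_fl3_mean,
                            log10_sd, fraction_trajectory) {
  valid <- c("intact", "damaged_A", "damaged_B", "debris")
  if (!is.character(name) || length(name) != 1L || !(name %in% valid)) {
    abort("population name must be one of: %s", paste(valid, collapse = ", "))
  }
  stopifnot_scalar(log10_fl1_mean, "log10_fl1_mean")
  stopifnot_scalar(log10_fl3_mean, "log10_fl3_mean")
  stopifnot_scalar(log10_sd, "log10_sd", 0)
  stopifnot(is.function(fraction_trajectory))
  structure(
    list(name = name, log10_fl1_mean = log10_fl1_mean,
         log10_fl3_mean = log10_fl3_mean, log10_sd = log10_sd,
         fraction_trajectory = fraction_trajectory),
    class = "population_spec"
  )
}

#' Default subpopulation geometry for SYBR Green I / PI staining
#'
#' Returns the four standard viability subpopulations as log-normal clouds
#' whose angular positions in (log10 FL1, log10 FL3) space are well
#' separated (>4 angular SDs between neighbours), ordered debris < intact <
#' damaged A < damaged B by FL3:FL1 angle, with debris carrying the lowest
#' raw FL1 magnitude. Abundances drift slowly over the run: intact cells
#' dominate throughout while both damaged classes accumulate.
#'
#' @param sd isotropic log10 dispersion of each cloud.
#' @return Named list of four [population_spec()] objects.
#' @export
default_population_specs <- function(sd = 0.10) {
  w_intact <- function(t) 0.85 - 0.02 * t
  w_damA <- function(t) 0.06 + 0.010 * t
  w_damB <- function(t) 0.03 + 0.008 * t
  w_debris <- function(t) 1 - w_intact(t) - w_damA(t) - w_damB(t)
  list(
    intact = population_spec("intact", 4.7, 2.5, sd, w_intact),
    damaged_A = population_spec("damaged_A", 4.2, 3.5, sd, w_damA),
    damaged_B = population_spec("damaged_B", 3.6, 4.3, sd, w_damB),
    debris = population_spec("debris", 2.9, 0.8, sd, w_debris)
  )
}

# Check that fractions across specs sum to 1 at the supplied times.
check_fraction_sum <- function(specs, times, tol = 1e-9) {
  for (t in times) {
    s <- sum(vapply(specs, function(p) p$fraction_trajectory(t), numeric(1)))
    if (abs(s - 1) > tol) {
      abort("population fractions sum to %.6f (not 1) at t = %.2f h", s, t)
    }
  }
  invisible(TRUE)
}
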