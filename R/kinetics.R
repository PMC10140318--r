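#' Maximum specific growth rate from a log-linear sliding-window fit
#'
#' Estimates `mu_max` as the slope of `ln(signal)` versus time over the
#' sliding window (of at least `min_points` samples) that maximises the
#' slope subject to a goodness-of-fit floor `r2_min`. This selects the
#' steepest log-linear stretch of the curve — the unrestricted exponential
#' phase — without requiring a hand-picked window. Ties go to the
#' earliest window. The estimator works identically on OD readings and on
#' flow-cytometry total counts: rescaling the signal by any positive
#' constant shifts the intercept only.
#'
#' @param time_h sampling times (h).
#' @param signal positive growth signal (OD620 or AFU/mL); non-positive
#'   values are dropped before fitting.
#' @param min_points minimum window length (default 4).
#' @param r2_min minimum fit R^2 for a window to be eligible (default
#'   0.98).
#' @return List of class `mu_max_fit`: `mu_max` (1/h), `window` (start and
#'   end times), `r_squared`, `n_points`, and `degraded` (`TRUE` when no
#'   window met `r2_min` and the best-R^2 window was returned with a
#'   warning).
#' @examples
#' t <- 0:6
#' estimate_mu_max(t, 0.1 * 2^t)$mu_max  # ln(2)
#' @export
estimate_mu_max <- function(time_h, signal, min_points = 4, r2_min = 0.98) {
  stopifnot(length(time_h) == length(signal))
  ok <- is.finite(signal) & signal > 0 & is.finite(time_h)
  time_h <- time_h[ok]
  signal <- signal[ok]
  n <- length(time_h)
  if (n < min_points) {
    abort("need at least %d positive signal values (got %d)", min_points, n)
  }
  y <- log(signal)

  best <- NULL        # best eligible (max slope, earliest)
  fallback <- NULL    # best R^2 overall
  for (i in seq_len(n - min_points + 1)) {
    for (j in seq(i + min_points - 1, n)) {
      tt <- time_h[i:j]
      yy <- y[i:j]
      fit <- stats::lm.fit(cbind(1, tt), yy)
      slope <- fit$coefficients[2]
      ss_res <- sum(fit$residuals^2)
      ss_tot <- sum((yy - mean(yy))^2)
      r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 0
      cand <- list(mu_max = unname(slope), window = c(tt[1], tt[length(tt)]),
                   r_squared = r2, n_points = j - i + 1)
      if (is.null(fallback) || r2 > fallback$r_squared) fallback <- cand
      if (r2 >= r2_min &&
          (is.null(best) || cand$mu_max > best$mu_max + 1e-12)) {
        best <- cand
      }
    }
  }
  if (is.null(best)) {
    warn("no window of >= %d points reached R^2 >= %.3f; returning the best-fitting window (R^2 = %.3f)",
         min_points, r2_min, fallback$r_squared)
    best <- fallback
    best$degraded <- TRUE
  } else {
    best$degraded <- FALSE
  }
  class(best) <- "mu_max_fit"
  best
}

#' @export
print.mu_max_fit <- function(x, ...) {
  cat(sprintf("mu_max = %.4f 1/h over [%.2f, %.2f] h (%d points, R^2 = %.4f%s)\n",
              x$mu_max, x$window[1], x$window[2], x$n_points, x$r_squared,
              if (x$degraded) ", degraded fit" else ""))
  invisible(x)
}

#' Time at which dissolved oxygen is depleted
#'
#' First crossing of the DOT series below `threshold`, linearly
#' interpolated between the bracketing samples. A crossing exactly at a
#' sample point returns that sample's time.
#'
#' @param time_h sampling times (h).
#' @param dot dissolved-oxygen tension (% air saturation).
#' @param threshold depletion threshold (% saturation, default 1).
#' @return Depletion time (h), or `NA` with attribute `status =
#'   "never"` if the series never crosses the threshold.
#' @examples
#' dot_depletion_time(c(0, 2), c(100, 0)) # 1.98
#' @export
dot_depletion_time <- function(time_h, dot, threshold = 1.0) {
  stopifnot(length(time_h) == length(dot), length(dot) >= 2)
  if (dot[1] < threshold) {
    abort("DOT series starts below the threshold (%.2f%% < %.2f%%)",
          dot[1], threshold)
  }
  below <- which(dot < threshold)
  if (!length(below)) {
    return(structure(NA_real_, status = "never"))
  }
  j <- below[1]
  if (dot[j] == threshold) {
    return(time_h[j])
  }
  i <- j - 1L
  # interpolate the crossing of `threshold` between samples i and j
  t_cross <- time_h[i] + (dot[i] - threshold) * (time_h[j] - time_h[i]) /
    (dot[i] - dot[j])
  unname(t_cross)
}

#' End-point product yields per gram of glucose
#'
#' Net product formed divided by overall glucose consumed between the
#' first and last sampling points. The biomass yield uses the harvest cell
#' dry weight minus the inoculum biomass (default 0; the inoculation OD of
#' a typical batch is negligible).
#'
#' @param profile a `culture_profile`.
#' @param inoculum_cdw inoculum biomass (g/L) subtracted from the harvest
#'   CDW for the biomass yield.
#' @return Named numeric vector of yields (g per g glucose) for
#'   `biomass`, `lactate`, `acetate`, `ethanol`. Net-consumed products
#'   give negative yields with a warning.
#' @export
compute_yields <- function(profile, inoculum_cdw = 0) {
  stopifnot(inherits(profile, "culture_profile"))
  s <- profile$series
  d_glc <- s$glucose_g_l[1] - s$glucose_g_l[nrow(s)]
  if (d_glc <= 0) {
    abort("no glucose consumed between start (%.3f g/L) and end (%.3f g/L)",
          s$glucose_g_l[1], s$glucose_g_l[nrow(s)])
  }
  delta <- function(col) s[[col]][nrow(s)] - s[[col]][1]
  yields <- c(
    biomass = (profile$cdw_harvest - inoculum_cdw) / d_glc,
    lactate = delta("lactate_g_l") / d_glc,
    acetate = delta("acetate_g_l") / d_glc,
    ethanol = delta("ethanol_g_l") / d_glc
  )
  neg <- yields < 0
  if (any(neg)) {
    warn("net consumption (negative yield) for: %s",
         paste(names(yields)[neg], collapse = ", "))
  }
  yields
}

# First time glucose drops to or below `floor_g_l`; NA if it never does.
glucose_depletion_time <- function(profile, floor_g_l = 0.1) {
  s <- profile$series
  hit <- which(s$glucose_g_l <= floor_g_l)
  if (!length(hit)) NA_real_ else s$time_h[hit[1]]
}

#' Specific production and consumption rates
#'
#' Net amount of each compound formed (or consumed, for glucose) divided
#' by the harvest cell dry weight and the elapsed time from inoculation to
#' glucose depletion (first sample with glucose at or below
#' `glucose_floor`).
#'
#' @param profile a `culture_profile` with `cdw_harvest` set.
#' @param glucose_floor concentration (g/L) at which glucose counts as
#'   depleted (default 0.1).
#' @return Named numeric vector (g per g CDW per h) for `glucose`,
#'   `lactate`, `acetate`, `ethanol`; glucose is reported as a positive
#'   consumption rate.
#' @export
specific_rates <- function(profile, glucose_floor = 0.1) {
  stopifnot(inherits(profile, "culture_profile"))
  if (is.null(profile$cdw_harvest) || profile$cdw_harvest <= 0) {
    abort("specific rates require a positive harvest CDW")
  }
  t_dep <- glucose_depletion_time(profile, glucose_floor)
  if (is.na(t_dep)) {
    t_dep <- max(profile$series$time_h)
    warn("glucose never reached the %.2f g/L floor; using the full run (%.2f h)",
         glucose_floor, t_dep)
  }
  s <- profile$series
  dt <- t_dep - s$time_h[1]
  if (dt <= 0) abort("elapsed time to depletion is %.2f h; rates undefined", dt)
  at_dep <- which(s$time_h >= t_dep)[1]
  delta <- function(col) s[[col]][at_dep] - s[[col]][1]
  c(glucose = -delta("glucose_g_l") / (profile$cdw_harvest * dt),
    lactate = delta("lactate_g_l") / (profile$cdw_harvest * dt),
    acetate = delta("acetate_g_l") / (profile$cdw_harvest * dt),
    ethanol = delta("ethanol_g_l") / (profile$cdw_harvest * dt))
}

#' End-point carbon balance
#'
#' Percentage of substrate carbon recovered in products, biomass and
#' estimated CO2:
#' `100 * (C products + C biomass + C CO2) / (C glucose + C citrate)`,
#' all quantities as end-point net changes in C-mol. CO2 is not measured
#' off-gas but estimated from heterofermentative stoichiometry: one CO2
#' per glucose routed through the phosphoketolase split, i.e. moles of
#' ethanol plus acetate, net of acetate attributable to citrate
#' co-consumption (citrate lyase yields one acetate per citrate without a
#' phosphoketolase CO2); consumed citrate is counted on the substrate
#' side.
#'
#' @param profile a `culture_profile`.
#' @param biomass_gram_per_cmol biomass elemental composition as g CDW per
#'   C-mol (default 24.6, i.e. CH1.8O0.5N0.2).
#' @param include_biomass logical; set `FALSE` to exclude biomass carbon.
#' @return Carbon balance in %, with a warning outside [90, 110].
#' @examples
#' # homolactic toy case: all glucose carbon ends up in lactate
#' @export
carbon_balance <- function(profile, biomass_gram_per_cmol = 24.6,
                           include_biomass = TRUE) {
  stopifnot(inherits(profile, "culture_profile"))
  s <- profile$series
  last <- nrow(s)
  consumed <- function(col) {
    if (!col %in% names(s)) {
      warn("profile lacks column '%s'; treated as 0", col)
      return(0)
    }
    max(s[[col]][1] - s[[col]][last], 0)
  }
  formed <- function(col) {
    if (!col %in% names(s)) {
      warn("profile lacks column '%s'; treated as 0", col)
      return(0)
    }
    s[[col]][last] - s[[col]][1]
  }

  glc <- consumed("glucose_g_l")
  cit <- consumed("citrate_g_l")
  substrate_c <- glc * cmol_per_gram("glucose") + cit * cmol_per_gram("citrate")
  if (substrate_c <= 0) abort("no substrate carbon consumed; balance undefined")

  lac <- formed("lactate_g_l")
  ace <- formed("acetate_g_l")
  eth <- formed("ethanol_g_l")
  suc <- formed("succinate_g_l")
  product_c <- lac * cmol_per_gram("lactate") + ace * cmol_per_gram("acetate") +
    eth * cmol_per_gram("ethanol") + suc * cmol_per_gram("succinate")

  biomass_c <- 0
  if (include_biomass && !is.null(profile$cdw_harvest)) {
    biomass_c <- profile$cdw_harvest / biomass_gram_per_cmol
  }

  co2_mol <- max(eth * mol_per_gram("ethanol") + ace * mol_per_gram("acetate") -
                   cit * mol_per_gram("citrate"), 0)

  pct <- 100 * (product_c + biomass_c + co2_mol) / substrate_c
  if (pct < 90 || pct > 110) {
    warn("carbon balance %.1f%% is outside the plausible [90, 110]%% band", pct)
  }
  pct
}

#' Mean forward-scatter time series
#'
#' Arithmetic mean FSC-H of the retained (post-threshold) events of each
#' sample — a coarse cell-size proxy over the cultivation.
#'
#' @param samples list of [fcm_sample()] objects with an `fsc_h` channel.
#' @return Data frame with columns `time_h`, `mean_fsc_h`, `n_events`.
#' @export
summarize_scatter <- function(samples) {
  if (inherits(samples, "fcm_sample")) samples <- list(samples)
  rows <- lapply(samples, function(s) {
    if (!"fsc_h" %in% names(s$events)) {
      abort("sample at t = %.2f h lacks FSC-H; available channels: %s",
            s$time_h, paste(names(s$events), collapse = ", "))
    }
    ft <- preprocess_events(s)
    data.frame(time_h = s$time_h, mean_fsc_h = mean(ft$raw$fsc_h),
               n_events = ft$n_retained)
  })
  do.call(rbind, rows)
}

#' Full kinetic summary of one cultivation
#'
#' Bundles [estimate_mu_max()] (from OD and, when present, from
#' flow-cytometry total counts), [dot_depletion_time()],
#' [compute_yields()], [specific_rates()] and [carbon_balance()] into one
#' result object.
#'
#' @param profile a `culture_profile`.
#' @param r2_min fit floor passed to [estimate_mu_max()].
#' @inheritParams carbon_balance
#' @return List of class `kinetics_result`.
#' @export
summarize_kinetics <- function(profile, r2_min = 0.98,
                               biomass_gram_per_cmol = 24.6) {
  s <- profile$series
  mu_od <- estimate_mu_max(s$time_h, s$od620, r2_min = r2_min)
  mu_fcm <- NULL
  if ("fcm_total_afu_ml" %in% names(s)) {
    mu_fcm <- estimate_mu_max(s$time_h, s$fcm_total_afu_ml, r2_min = r2_min)
  }
  structure(
    list(mu_max_od = mu_od, mu_max_fcm = mu_fcm,
         dot_depletion_h = dot_depletion_time(s$time_h, s$dot_pct),
         yields = compute_yields(profile),
         specific_rates = specific_rates(profile),
         carbon_balance_pct = carbon_balance(
           profile, biomass_gram_per_cmol = biomass_gram_per_cmol),
         cdw_harvest = profile$cdw_harvest),
    class = "kinetics_result"
  )
}

#' @export
print.kinetics_result <- function(x, ...) {
  cat("<kinetics_result>\n")
  cat(sprintf("  mu_max (OD) %.3f 1/h%s\n", x$mu_max_od$mu_max,
              if (!is.null(x$mu_max_fcm))
                sprintf(", mu_max (FCM) %.3f 1/h", x$mu_max_fcm$mu_max)
              else ""))
  cat(sprintf("  DOT depleted at %s h\n",
              if (is.na(x$dot_depletion_h)) "never"
              else sprintf("%.2f", x$dot_depletion_h)))
  cat("  yields (g/g):",
      paste(sprintf("%s %.3f", names(x$yields), x$yields), collapse = ", "),
      "\n")
  cat(sprintf("  carbon balance %.1f%%, harvest CDW %.3f g/L\n",
              x$carbon_balance_pct, x$cdw_harvest))
  invisible(x)
}
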