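#' Default end-to-end run configuration
#'
#' Describes a three-condition oxygen-level study (air-sparged,
#' non-sparged, N2-sparged) run entirely on synthetic data: per-condition
#' cultivation scenarios anchored to typical bench-bioreactor magnitudes
#' (growth near 0.74-0.80 1/h, acetate shifted up and ethanol down under
#' air, citrate untouched without oxygen), gating parameters (k = 4,
#' 20 restarts, FL1 threshold 500), membrane FAME mean profiles from
#' [fame_reference_dsm17938()], and probiotic-marker settings (bile lag
#' targets of 8.75/7.5/9.75 h, acid death rates leaving only the
#' anaerobic condition detectable at 90 min, 5'NT activities of
#' 370/270/240 U/L).
#'
#' @param seed integer master seed for the whole run (mandatory for any
#'   config).
#' @param events_per_sample flow-cytometry events per sample at harvest
#'   biomass.
#' @return Nested list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L, events_per_sample = 2000) {
  ref <- fame_reference_dsm17938()
  fame_means <- lapply(split(ref, ref$condition), function(d) {
    stats::setNames(d$mean_ug_mg, d$fa_id)
  })
  bile_mu <- 0.8
  bile_offset <- log(0.5 * (1.2 - 0.05) / (0.05 * (1.2 - 0.5))) / bile_mu
  cond <- function(mu, dot_0, dot_dep, aerated, citrate, y_lac, y_ace, y_eth,
                   fd_pct, acid_rate, bile_cross_h, nt_u_l) {
    list(
      scenario = list(mu_max = mu, dot_0 = dot_0, dot_depletion_h = dot_dep,
                      aerated = aerated, citrate_consumed = citrate,
                      yield_lactate = y_lac, yield_acetate = y_ace,
                      yield_ethanol = y_eth),
      fd = list(cfu_before = 2.0e9, survival_pct = fd_pct),
      acid = list(cfu_0 = 1e8, death_rate = acid_rate, lod = 1e3,
                  n_replicates = 2),
      bile = list(lag_h = bile_cross_h - bile_offset, mu = bile_mu,
                  od_max = 1.2, od_0 = 0.05, n_wells = 2),
      nt = list(mean_u_per_l = nt_u_l, sd_u_per_l = 20,
                n_biological = 2, n_technical = 3)
    )
  }
  structure(list(
    seed = as.integer(seed),
    conditions = list(
      air_sparged = cond(0.74, 100, 2.55, TRUE, TRUE, 0.46, 0.11, 0.18,
                         61.8, 0.080, 8.75, 370),
      non_sparged = cond(0.75, 100, 1.39, FALSE, TRUE, 0.46, 0.08, 0.22,
                         60.5, 0.070, 7.50, 270),
      n2_sparged = cond(0.80, 5, 0.30, FALSE, FALSE, 0.42, 0.07, 0.20,
                        11.5, 0.050, 9.75, 240)
    ),
    gating = list(k = 4, restarts = 20, events_per_sample = events_per_sample,
                  interval_h = 0.5, compare_fixed = TRUE),
    analysis = list(r2_min = 0.98, bile_cutoff = 0.5,
                    biomass_gram_per_cmol = 24.6),
    fame = list(mean_profiles = fame_means, cv = 0.1, n_replicates = 3)
  ), class = "run_config")
}

#' Validate a run configuration
#'
#' Fail-fast structural validation: mandatory seed, at least one
#' condition, every scenario constructible, and any referenced input file
#' resolvable before a single stage runs.
#'
#' @param config a `run_config` (or plain nested list with that shape).
#' @return The config, invisibly; errors name the offending field or
#'   path.
#' @export
validate_run_config <- function(config) {
  if (is.null(config$seed)) abort("run config must carry a seed")
  if (!length(config$conditions)) abort("run config defines no conditions")
  for (nm in names(config$conditions)) {
    cc <- config$conditions[[nm]]
    do.call(culture_scenario, cc$scenario %||% list())
    for (f in c("fame_file", "fd_file", "acid_file", "bile_file", "nt_file")) {
      if (!is.null(cc[[f]]) && !file.exists(cc[[f]])) {
        abort("condition '%s': referenced input file does not exist: %s",
              nm, cc[[f]])
      }
    }
  }
  invisible(config)
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes the stages in dependency order for every condition: simulate
#' the batch culture, generate and gate the flow-cytometry time course
#' (k-means, optionally compared against fixed wedge gates), compute the
#' kinetic summary, simulate and summarise the FAME table, and compute
#' the probiotic-marker metrics. Each stage's tabular outputs are written
#' under `out_dir/<condition>/` before the next stage consumes them, so a
#' failed run leaves inspectable partial results. The master seed expands
#' deterministically into per-condition, per-stage seeds: identical
#' config and seed give identical reports.
#'
#' @param config a `run_config`, e.g. [default_run_config()].
#' @param out_dir output directory (created if missing).
#' @return An object of class `run_report`: per-condition results
#'   (`kinetics`, `subpop_counts`, `gating_agreement`, `lipids`,
#'   `markers`), plus a provenance block (seed, config hash, package
#'   version).
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = tempfile("run_")) {
  validate_run_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- config$seed

  results <- list()
  for (ci in seq_along(config$conditions)) {
    nm <- names(config$conditions)[ci]
    cc <- config$conditions[[ci]]
    cdir <- file.path(out_dir, nm)
    if (!dir.exists(cdir)) dir.create(cdir)
    stage <- function(what, expr) {
      tryCatch(expr, error = function(e) {
        abort("stage '%s' failed for condition '%s': %s", what, nm,
              conditionMessage(e))
      })
    }

    cseed <- derive_seed(seed, ci)
    profile <- stage("simulate_culture", {
      sc_args <- cc$scenario %||% list()
      sc_args$seed <- cseed
      p <- simulate_batch_culture(do.call(culture_scenario, sc_args))
      write_culture_profile(p, file.path(cdir, "profile.csv"))
      p
    })

    fcm <- stage("simulate_fcm", {
      simulate_fcm_timeseries(
        profile, events_per_sample = config$gating$events_per_sample %||% 2000,
        interval_h = config$gating$interval_h %||% 0.5,
        seed = derive_seed(cseed, 2))
    })

    counts_km <- stage("gate_kmeans", {
      x <- gate_fcm_series(fcm, method = "kmeans",
                           k = config$gating$k %||% 4,
                           restarts = config$gating$restarts %||% 20,
                           seed = derive_seed(cseed, 3))
      utils::write.csv(x, file.path(cdir, "subpop_counts.csv"),
                       row.names = FALSE)
      x
    })

    agreement <- NULL
    if (isTRUE(config$gating$compare_fixed %||% TRUE)) {
      agreement <- stage("gate_fixed", {
        counts_fx <- gate_fcm_series(fcm, method = "fixed")
        compare_gating(counts_km, counts_fx)
      })
    }

    kinetics <- stage("kinetics", {
      k <- summarize_kinetics(
        profile, r2_min = config$analysis$r2_min %||% 0.98,
        biomass_gram_per_cmol = config$analysis$biomass_gram_per_cmol %||% 24.6)
      utils::write.csv(
        data.frame(metric = c("mu_max_od", "mu_max_fcm", "dot_depletion_h",
                              paste0("yield_", names(k$yields)),
                              paste0("rate_", names(k$specific_rates)),
                              "carbon_balance_pct", "cdw_harvest"),
                   value = c(k$mu_max_od$mu_max,
                             if (is.null(k$mu_max_fcm)) NA else k$mu_max_fcm$mu_max,
                             k$dot_depletion_h, unname(k$yields),
                             unname(k$specific_rates),
                             k$carbon_balance_pct, k$cdw_harvest)),
        file.path(cdir, "kinetics.csv"), row.names = FALSE)
      k
    })

    lipids <- stage("lipids", {
      mp <- config$fame$mean_profiles[[nm]]
      if (is.null(mp)) {
        # fall back to the bundled reference composition
        ref <- fame_reference_dsm17938()
        pick <- if (nm %in% ref$condition) nm else ref$condition[1]
        d <- ref[ref$condition == pick, ]
        mp <- stats::setNames(d$mean_ug_mg, d$fa_id)
      }
      mp <- unlist(mp)
      ft <- simulate_fame_table(mp, cv = config$fame$cv %||% 0.1,
                                n_replicates = config$fame$n_replicates %||% 3,
                                seed = derive_seed(cseed, 4), condition = nm)
      write_fame_table(ft, file.path(cdir, "fames.csv"))
      summarize_fames(ft)
    })

    markers <- stage("markers", {
      fd <- fd_survivability(cc$fd$cfu_before,
                             cc$fd$cfu_before * cc$fd$survival_pct / 100)
      acid <- lapply(seq_len(cc$acid$n_replicates %||% 2), function(r) {
        acid_survival_summary(simulate_acid_challenge(
          cfu_0 = cc$acid$cfu_0, death_rate = cc$acid$death_rate,
          lod = cc$acid$lod %||% 1e3, seed = derive_seed(cseed, 10 + r),
          condition = nm, replicate = r))
      })
      bile <- lapply(seq_len(cc$bile$n_wells %||% 2), function(w) {
        bile_lag_time(simulate_bile_curve(
          lag_h = cc$bile$lag_h, mu = cc$bile$mu,
          od_max = cc$bile$od_max %||% 1.2, od_0 = cc$bile$od_0 %||% 0.05,
          noise_cv = 0.01, seed = derive_seed(cseed, 20 + w),
          condition = nm, well = paste0("W", w)),
          cutoff = config$analysis$bile_cutoff %||% 0.5)
      })
      nt_meas <- with_seed(derive_seed(cseed, 30), {
        expand <- expand.grid(technical_rep = seq_len(cc$nt$n_technical %||% 3),
                              biological_rep = seq_len(cc$nt$n_biological %||% 2))
        data.frame(condition = nm, expand,
                   u_per_l = stats::rnorm(nrow(expand), cc$nt$mean_u_per_l,
                                          cc$nt$sd_u_per_l %||% 20))
      })
      list(fd_survivability_pct = as.numeric(fd),
           acid = acid,
           acid_death_rate = mean(vapply(acid, `[[`, numeric(1),
                                         "death_rate"), na.rm = TRUE),
           acid_survived_at_end = vapply(acid, `[[`, logical(1),
                                         "survived_at_end"),
           bile_lag_h = vapply(bile, `[[`, numeric(1), "lag_h"),
           nt = nt_activity_summary(nt_meas))
    })

    results[[nm]] <- list(profile = profile, kinetics = kinetics,
                          subpop_counts = counts_km,
                          gating_agreement = agreement,
                          scatter = summarize_scatter(fcm),
                          lipids = lipids, markers = markers)
  }

  lipid_tbl <- compare_lipid_conditions(lapply(results, `[[`, "lipids"))
  utils::write.csv(lipid_tbl, file.path(out_dir, "lipid_comparison.csv"),
                   row.names = FALSE)

  structure(
    list(conditions = results, lipid_comparison = lipid_tbl,
         provenance = list(
           seed = seed,
           config_hash = config_hash(config),
           package_version = as.character(utils::packageVersion("probioflow")),
           out_dir = out_dir)),
    class = "run_report"
  )
}

# Order-insensitive structural hash of the config (no external digest
# dependency: sum over serialized bytes is enough for provenance tagging).
config_hash <- function(config) {
  raw_bytes <- serialize(config, NULL, version = 2)
  sprintf("%08x-%d", sum(as.integer(raw_bytes)) %% 0xFFFFFFF,
          length(raw_bytes))
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d condition(s), seed %d, config %s\n",
              length(x$conditions), x$provenance$seed,
              x$provenance$config_hash))
  for (nm in names(x$conditions)) {
    r <- x$conditions[[nm]]
    cat(sprintf("  %-12s mu(OD) %.3f /h  carbon %.1f%%  UFA:SFA %.2f  FD %.1f%%  bile %.2f h\n",
                nm, r$kinetics$mu_max_od$mu_max,
                r$kinetics$carbon_balance_pct, r$lipids$ufa_sfa_ratio,
                r$markers$fd_survivability_pct,
                mean(r$markers$bile_lag_h, na.rm = TRUE)))
  }
  invisible(x)
}

#' Render figures and summary tables from a run report
#'
#' Writes the figure families of a typical oxygen-cultivation study:
#' subpopulation time courses per condition, metabolite profiles, mean
#' forward-scatter profiles, freeze-drying survivability bars, and the
#' kinetic/lipid summary tables. Sections absent from the report are
#' skipped with a message.
#'
#' @param report a `run_report`.
#' @param out_dir output directory for figures (PDF) and tables (CSV).
#' @return Character vector of files written, invisibly.
#' @export
render_report <- function(report, out_dir = report$provenance$out_dir) {
  stopifnot(inherits(report, "run_report"))
  if (!length(report$conditions)) abort("report contains no conditions")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  written <- character()
  save_plot <- function(p, name) {
    f <- file.path(out_dir, name)
    ggplot2::ggsave(f, p, width = 7, height = 5)
    written <<- c(written, f)
  }

  counts_long <- do.call(rbind, lapply(names(report$conditions), function(nm) {
    d <- report$conditions[[nm]]$subpop_counts
    if (is.null(d)) return(NULL)
    do.call(rbind, lapply(c("total", "intact", "damaged_A", "damaged_B",
                            "debris"), function(p) {
      data.frame(condition = nm, time_h = d$time_h, population = p,
                 afu_per_ml = d[[p]])
    }))
  }))
  if (!is.null(counts_long)) {
    p <- ggplot2::ggplot(counts_long,
                         ggplot2::aes(x = time_h, y = afu_per_ml,
                                      colour = population)) +
      ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
      ggplot2::scale_y_log10() +
      ggplot2::facet_wrap(~condition) +
      ggplot2::labs(x = "Time (h)", y = "AFU/mL",
                    title = "Viability subpopulations (k-means gating)")
    save_plot(p, "subpopulations.pdf")
  } else {
    message("no flow-cytometry section in report; skipping subpopulation plot")
  }

  metab_long <- do.call(rbind, lapply(names(report$conditions), function(nm) {
    s <- report$conditions[[nm]]$profile$series
    do.call(rbind, lapply(c("glucose_g_l", "citrate_g_l", "lactate_g_l",
                            "acetate_g_l", "ethanol_g_l"), function(cp) {
      data.frame(condition = nm, time_h = s$time_h,
                 compound = sub("_g_l$", "", cp), g_per_l = s[[cp]])
    }))
  }))
  p <- ggplot2::ggplot(metab_long,
                       ggplot2::aes(x = time_h, y = g_per_l,
                                    colour = compound)) +
    ggplot2::geom_line() + ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = "Time (h)", y = "g/L", title = "Metabolite profiles")
  save_plot(p, "metabolites.pdf")

  scatter <- do.call(rbind, lapply(names(report$conditions), function(nm) {
    cbind(condition = nm, report$conditions[[nm]]$scatter)
  }))
  if (!is.null(scatter)) {
    p <- ggplot2::ggplot(scatter,
                         ggplot2::aes(x = time_h, y = mean_fsc_h,
                                      colour = condition)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "Time (h)", y = "Mean FSC-H",
                    title = "Forward-scatter profiles")
    save_plot(p, "forward_scatter.pdf")
  }

  fd <- data.frame(
    condition = names(report$conditions),
    survivability_pct = vapply(report$conditions, function(r) {
      r$markers$fd_survivability_pct
    }, numeric(1)))
  p <- ggplot2::ggplot(fd, ggplot2::aes(x = condition,
                                        y = survivability_pct)) +
    ggplot2::geom_col() +
    ggplot2::labs(y = "FD survivability (%)", x = NULL,
                  title = "Freeze-drying survivability")
  save_plot(p, "fd_survivability.pdf")

  summary_tbl <- do.call(rbind, lapply(names(report$conditions), function(nm) {
    r <- report$conditions[[nm]]
    data.frame(condition = nm,
               mu_max_od = r$kinetics$mu_max_od$mu_max,
               mu_max_fcm = if (is.null(r$kinetics$mu_max_fcm)) NA else
                 r$kinetics$mu_max_fcm$mu_max,
               dot_depletion_h = r$kinetics$dot_depletion_h,
               yield_lactate = r$kinetics$yields[["lactate"]],
               yield_acetate = r$kinetics$yields[["acetate"]],
               yield_ethanol = r$kinetics$yields[["ethanol"]],
               carbon_balance_pct = r$kinetics$carbon_balance_pct,
               total_fa = r$lipids$total_mean,
               ufa_sfa_ratio = r$lipids$ufa_sfa_ratio,
               fd_survivability_pct = r$markers$fd_survivability_pct,
               bile_lag_h = mean(r$markers$bile_lag_h, na.rm = TRUE),
               nt_u_per_l = r$markers$nt$mean_u_per_l)
  }))
  f <- file.path(out_dir, "summary.csv")
  utils::write.csv(summary_tbl, f, row.names = FALSE)
  written <- c(written, f)
  invisible(written)
}

#' Read / write run configurations as YAML
#'
#' @param path YAML file.
#' @param config a `run_config`.
#' @return `read_run_config()` returns a validated `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort("config file not found: %s", path)
  config <- yaml::read_yaml(path)
  class(config) <- "run_config"
  validate_run_config(config)
  config
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
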