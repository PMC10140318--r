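#' Construct a FAME table from replicate measurements
#'
#' Holds per-replicate fatty-acid methyl ester (FAME) quantities in ug
#' FAME per mg cell dry weight, as produced by GC-FID after
#' internal-standard (C17:0) normalisation. Cells below the limit of
#' quantification carry value 0 and a `below_loq` flag so that reports can
#' annotate them while sums remain well defined.
#'
#' @param condition condition label (e.g. `"air_sparged"`).
#' @param values numeric matrix of measurements, fatty acids in rows and
#'   replicates in columns; `rownames` are the fatty-acid identifiers
#'   (e.g. `"C16:0"`).
#' @param classes optional character vector (`"UFA"`, `"SFA"`,
#'   `"excluded"`) per fatty acid; derived with [classify_fatty_acids()]
#'   when `NULL`.
#' @param below_loq optional logical matrix matching `values`.
#' @param class_overrides passed to [classify_fatty_acids()].
#' @return An object of class `fame_table`.
#' @seealso [summarize_fames()], [fame_table_from_summary()]
#' @export
fame_table <- function(condition, values, classes = NULL, below_loq = NULL,
                       class_overrides = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) abort("values must carry fatty-acid rownames")
  if (any(!is.finite(values)) || any(values < 0)) {
    abort("FAME values must be finite and >= 0")
  }
  if (is.null(classes)) {
    classes <- classify_fatty_acids(rownames(values),
                                    overrides = class_overrides)
  }
  stopifnot(length(classes) == nrow(values))
  if (is.null(below_loq)) {
    below_loq <- matrix(FALSE, nrow(values), ncol(values),
                        dimnames = dimnames(values))
  }
  structure(
    list(condition = condition, values = values,
         classes = stats::setNames(classes, rownames(values)),
         below_loq = below_loq, form = "replicates"),
    class = "fame_table"
  )
}

#' Construct a FAME table from published per-FA means and SDs
#'
#' For reproducing summary statistics from a printed composition table
#' (per-fatty-acid mean and standard deviation, no replicate values).
#'
#' @inheritParams fame_table
#' @param mean,sd numeric vectors (ug FAME / mg CDW) named by fatty acid,
#'   or unnamed with `fa_id` supplied.
#' @param fa_id fatty-acid identifiers when `mean` is unnamed.
#' @param below_loq logical vector flagging below-LOQ fatty acids.
#' @return An object of class `fame_table` (summary form).
#' @export
fame_table_from_summary <- function(condition, mean, sd, fa_id = names(mean),
                                    classes = NULL, below_loq = NULL,
                                    class_overrides = NULL) {
  stopifnot(length(mean) == length(sd), !is.null(fa_id))
  if (any(mean < 0) || any(sd < 0)) abort("means and SDs must be >= 0")
  if (is.null(classes)) {
    classes <- classify_fatty_acids(fa_id, overrides = class_overrides)
  }
  if (is.null(below_loq)) below_loq <- rep(FALSE, length(mean))
  structure(
    list(condition = condition,
         mean = stats::setNames(as.numeric(mean), fa_id),
         sd = stats::setNames(as.numeric(sd), fa_id),
         classes = stats::setNames(classes, fa_id),
         below_loq = stats::setNames(below_loq, fa_id),
         form = "summary"),
    class = "fame_table"
  )
}

#' @export
print.fame_table <- function(x, ...) {
  n_fa <- length(x$classes)
  cat(sprintf("<fame_table> condition '%s', %d fatty acids (%s form)\n",
              x$condition, n_fa, x$form))
  invisible(x)
}

#' Classify fatty acids as saturated or unsaturated
#'
#' Parses standard shorthand (`"C16:0"` is saturated, `"C18:1"`,
#' `"C18:2"` etc. unsaturated). Cyclopropane fatty acids (identifier
#' containing `"cyc"`) are not covered by the shorthand rule; they default
#' to `cyclopropane_class` (`"UFA"`), reflecting their biosynthetic origin
#' from unsaturated precursors and their comparable effect on membrane
#' fluidity. Explicit `overrides` win over everything.
#'
#' @param fa_ids character vector of fatty-acid identifiers.
#' @param overrides named character vector of explicit class assignments.
#' @param cyclopropane_class class for cyclopropane fatty acids.
#' @return Character vector of `"SFA"` / `"UFA"` (or override values) per
#'   identifier; unknown identifiers raise an error listing them.
#' @examples
#' classify_fatty_acids(c("C16:0", "C18:1", "C19:0 cyc"))
#' @export
classify_fatty_acids <- function(fa_ids, overrides = NULL,
                                 cyclopropane_class = "UFA") {
  out <- character(length(fa_ids))
  for (i in seq_along(fa_ids)) {
    id <- fa_ids[i]
    if (!is.null(overrides) && id %in% names(overrides)) {
      out[i] <- overrides[[id]]
    } else if (grepl("cyc", id, ignore.case = TRUE)) {
      out[i] <- cyclopropane_class
    } else if (grepl("^C\\d+:(\\d+)", id)) {
      db <- as.integer(sub("^C\\d+:(\\d+).*$", "\\1", id))
      out[i] <- if (db == 0) "SFA" else "UFA"
    } else {
      out[i] <- NA_character_
    }
  }
  if (anyNA(out)) {
    abort("cannot classify fatty acid id(s): %s (supply overrides)",
          paste(fa_ids[is.na(out)], collapse = ", "))
  }
  out
}

#' Summarise a FAME table
#'
#' Computes the standard membrane-lipid summary: per-fatty-acid mean and
#' SD across replicates, total FAME (sum of per-FA means) with its SD
#' propagated as the square root of the summed per-FA variances, relative
#' abundance (%), class sums over the per-FA means (UFA and SFA), and the
#' UFA:SFA ratio of those sums.
#'
#' Relative abundance has two modes: `"per_replicate"` (primary) divides
#' each replicate's individual FAME by that replicate's total and averages
#' the resulting percentages; `"ratio_of_means"` divides the per-FA mean
#' by the total mean. Summary-form tables (printed means/SDs only) always
#' use ratio-of-means.
#'
#' @param table a [fame_table()] or [fame_table_from_summary()].
#' @param abundance_mode `"per_replicate"` or `"ratio_of_means"`.
#' @return An object of class `lipid_summary`: `per_fa` data frame
#'   (`fa_id`, `class`, `mean`, `sd`, `rel_abundance_pct`,
#'   `rel_abundance_sd`, `below_loq`), `total_mean`, `total_sd`,
#'   `ufa_sum`, `sfa_sum`, `ufa_sfa_ratio`, `condition`,
#'   `abundance_mode`.
#' @export
summarize_fames <- function(table,
                            abundance_mode = c("per_replicate",
                                               "ratio_of_means")) {
  stopifnot(inherits(table, "fame_table"))
  abundance_mode <- match.arg(abundance_mode)

  if (table$form == "replicates") {
    v <- table$values
    if (ncol(v) < 1) abort("need at least one replicate per fatty acid")
    fa_mean <- rowMeans(v)
    fa_sd <- if (ncol(v) > 1) apply(v, 1, stats::sd) else rep(0, nrow(v))
    loq <- apply(table$below_loq, 1, any)
    if (abundance_mode == "per_replicate") {
      totals <- colSums(v)
      if (any(totals <= 0)) {
        abort("replicate total of 0 makes relative abundance undefined")
      }
      pct <- sweep(v, 2, totals, "/") * 100
      rel_mean <- rowMeans(pct)
      rel_sd <- if (ncol(v) > 1) apply(pct, 1, stats::sd) else rep(0, nrow(v))
    } else {
      rel_mean <- fa_mean / sum(fa_mean) * 100
      rel_sd <- rep(NA_real_, length(fa_mean))
    }
  } else {
    fa_mean <- table$mean
    fa_sd <- table$sd
    loq <- table$below_loq
    if (abundance_mode == "per_replicate") {
      abundance_mode <- "ratio_of_means"  # only option without replicates
    }
    rel_mean <- fa_mean / sum(fa_mean) * 100
    rel_sd <- rep(NA_real_, length(fa_mean))
  }

  classes <- table$classes
  total_mean <- sum(fa_mean)
  total_sd <- sqrt(sum(fa_sd^2))
  ufa_sum <- sum(fa_mean[classes == "UFA"])
  sfa_sum <- sum(fa_mean[classes == "SFA"])
  ratio <- if (sfa_sum == 0) {
    warn("SFA sum is 0 for condition '%s'; UFA:SFA ratio is infinite",
         table$condition)
    Inf
  } else {
    ufa_sum / sfa_sum
  }

  structure(
    list(condition = table$condition,
         per_fa = data.frame(
           fa_id = names(fa_mean), class = unname(classes),
           mean = unname(fa_mean), sd = unname(fa_sd),
           rel_abundance_pct = unname(rel_mean),
           rel_abundance_sd = unname(rel_sd),
           below_loq = unname(loq), row.names = NULL),
         total_mean = total_mean, total_sd = total_sd,
         ufa_sum = ufa_sum, sfa_sum = sfa_sum, ufa_sfa_ratio = ratio,
         abundance_mode = abundance_mode),
    class = "lipid_summary"
  )
}

#' @export
print.lipid_summary <- function(x, ...) {
  cat(sprintf("<lipid_summary> condition '%s'\n", x$condition))
  cat(sprintf("  total FA %.2f +/- %.2f ug/mg CDW; UFA %.2f, SFA %.2f, UFA:SFA %.2f\n",
              x$total_mean, x$total_sd, x$ufa_sum, x$sfa_sum,
              x$ufa_sfa_ratio))
  invisible(x)
}

#' Compare lipid summaries across conditions
#'
#' Assembles per-fatty-acid and aggregate statistics from several
#' conditions into one long-format table suitable for downstream
#' statistical testing or plotting.
#'
#' @param summaries list of `lipid_summary` objects (at least 2).
#' @return Data frame with columns `condition`, `item` (fatty-acid id or
#'   one of `total_fa`, `ufa`, `sfa`, `ufa_sfa_ratio`), `mean`, `sd`,
#'   `rel_abundance_pct`.
#' @export
compare_lipid_conditions <- function(summaries) {
  if (length(summaries) < 2) {
    abort("need at least 2 lipid summaries to compare (got %d)",
          length(summaries))
  }
  stopifnot(all(vapply(summaries, inherits, logical(1), "lipid_summary")))
  do.call(rbind, lapply(summaries, function(s) {
    per_fa <- data.frame(condition = s$condition, item = s$per_fa$fa_id,
                         mean = s$per_fa$mean, sd = s$per_fa$sd,
                         rel_abundance_pct = s$per_fa$rel_abundance_pct)
    agg <- data.frame(
      condition = s$condition,
      item = c("total_fa", "ufa", "sfa", "ufa_sfa_ratio"),
      mean = c(s$total_mean, s$ufa_sum, s$sfa_sum, s$ufa_sfa_ratio),
      sd = c(s$total_sd, NA, NA, NA),
      rel_abundance_pct = NA_real_)
    rbind(per_fa, agg)
  }))
}

#' Simulate replicate FAME measurements around a mean profile
#'
#' Per-replicate values are multiplicative log-normal perturbations of the
#' per-fatty-acid means (the standard error structure of GC-FID
#' quantification), so negative values are impossible and `cv = 0`
#' reproduces the means exactly. Zero means (below-LOQ fatty acids) stay
#' zero and are flagged.
#'
#' @param mean_profile named numeric vector of per-FA means (ug/mg CDW).
#' @param cv coefficient of variation of the log-normal noise.
#' @param n_replicates number of replicates (>= 2).
#' @param seed integer seed.
#' @param condition condition label for the resulting table.
#' @inheritParams fame_table
#' @return A [fame_table()] in replicate form.
#' @export
simulate_fame_table <- function(mean_profile, cv = 0.1, n_replicates = 3,
                                seed = 1L, condition = "synthetic",
                                classes = NULL, class_overrides = NULL) {
  if (n_replicates < 2) abort("n_replicates must be >= 2 (got %d)",
                              n_replicates)
  stopifnot(!is.null(names(mean_profile)), all(mean_profile >= 0))
  sdlog <- sqrt(log(1 + cv^2))
  v <- with_seed(seed, {
    vapply(seq_len(n_replicates), function(r) {
      if (cv == 0) {
        as.numeric(mean_profile)
      } else {
        # mean-preserving log-normal: E[value] = mean_profile
        mean_profile * stats::rlnorm(length(mean_profile),
                                     meanlog = -sdlog^2 / 2, sdlog = sdlog)
      }
    }, numeric(length(mean_profile)))
  })
  v <- matrix(v, nrow = length(mean_profile),
              dimnames = list(names(mean_profile),
                              paste0("rep", seq_len(n_replicates))))
  loq <- matrix(rep(mean_profile == 0, n_replicates), nrow = nrow(v),
                dimnames = dimnames(v))
  fame_table(condition, v, classes = classes, below_loq = loq,
             class_overrides = class_overrides)
}

#' Reference membrane FAME composition of L. reuteri DSM 17938
#'
#' Per-fatty-acid means and standard deviations (ug FAME per mg CDW,
#' biological triplicates) for cells cultivated under air-sparged,
#' non-sparged and N2-sparged conditions, as compiled from published
#' GC-FID measurements of this strain. Only palmitic (C16:0) and oleic
#' (C18:1) acid identities are certain; the remaining identifiers are
#' synthetic placeholders chosen to be consistent with the published
#' saturated/unsaturated class totals (the cyclopropane fatty acid counts
#' as unsaturated). Stearic acid (C18:0) under air sparging was detectable
#' but below the limit of quantification.
#'
#' @return Data frame with columns `condition`, `fa_id`, `class`,
#'   `mean_ug_mg`, `sd_ug_mg`, `below_loq`.
#' @seealso [fame_table_from_summary()], [summarize_fames()]
#' @export
fame_reference_dsm17938 <- function() {
  fa_id <- c("C14:0", "C16:0", "C16:1", "C18:0", "C18:1", "C18:2",
             "C19:0 cyc", "C20:1")
  build <- function(condition, mean, sd) {
    data.frame(condition = condition, fa_id = fa_id,
               class = classify_fatty_acids(fa_id),
               mean_ug_mg = mean, sd_ug_mg = sd,
               below_loq = mean == 0)
  }
  rbind(
    build("air_sparged",
          c(2.36, 16.99, 4.48, 0.00, 137.01, 9.16, 32.89, 9.93),
          c(2.07, 3.80, 0.26, 0.00, 23.47, 1.15, 4.75, 1.78)),
    build("non_sparged",
          c(1.54, 44.72, 5.92, 6.64, 111.90, 10.16, 31.95, 9.39),
          c(1.37, 1.06, 1.77, 1.81, 19.21, 1.85, 4.80, 0.59)),
    build("n2_sparged",
          c(1.34, 37.29, 5.01, 2.35, 96.52, 7.61, 28.40, 9.57),
          c(1.20, 3.92, 0.94, 2.10, 13.95, 0.75, 2.69, 1.46))
  )
}

#' Read / write FAME tables as CSV
#'
#' Long-format interchange: columns `condition`, `fa_id`,
#' `class_override` (optional), `replicate`, `ug_per_mg_cdw`,
#' `below_loq` (optional).
#'
#' @param path CSV file.
#' @return `read_fame_tables()` returns a named list of [fame_table()]
#'   objects, one per condition.
#' @export
read_fame_tables <- function(path) {
  if (!file.exists(path)) abort("FAME file not found: %s", path)
  d <- utils::read.csv(path)
  need <- c("condition", "fa_id", "replicate", "ug_per_mg_cdw")
  miss <- setdiff(need, names(d))
  if (length(miss)) abort("FAME CSV lacks columns: %s",
                          paste(miss, collapse = ", "))
  out <- lapply(split(d, d$condition), function(dc) {
    fa <- unique(dc$fa_id)
    reps <- sort(unique(dc$replicate))
    v <- matrix(0, length(fa), length(reps),
                dimnames = list(fa, paste0("rep", reps)))
    loq <- matrix(FALSE, length(fa), length(reps), dimnames = dimnames(v))
    for (i in seq_len(nrow(dc))) {
      v[dc$fa_id[i], paste0("rep", dc$replicate[i])] <- dc$ug_per_mg_cdw[i]
      if ("below_loq" %in% names(dc)) {
        loq[dc$fa_id[i], paste0("rep", dc$replicate[i])] <-
          isTRUE(as.logical(dc$below_loq[i]))
      }
    }
    overrides <- NULL
    if ("class_override" %in% names(dc)) {
      has <- !is.na(dc$class_override) & nzchar(dc$class_override)
      if (any(has)) {
        overrides <- stats::setNames(dc$class_override[has], dc$fa_id[has])
        overrides <- overrides[!duplicated(names(overrides))]
      }
    }
    fame_table(dc$condition[1], v, below_loq = loq,
               class_overrides = overrides)
  })
  out
}

#' @rdname read_fame_tables
#' @param table a [fame_table()] in replicate form.
#' @export
write_fame_table <- function(table, path) {
  stopifnot(inherits(table, "fame_table"), table$form == "replicates")
  v <- table$values
  long <- data.frame(
    condition = table$condition,
    fa_id = rep(rownames(v), ncol(v)),
    class_override = rep(unname(table$classes), ncol(v)),
    replicate = rep(seq_len(ncol(v)), each = nrow(v)),
    ug_per_mg_cdw = as.vector(v),
    below_loq = as.vector(table$below_loq)
  )
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
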