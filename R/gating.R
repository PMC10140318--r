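#' Preprocess a flow-cytometry sample for gating
#'
#' Applies the acquisition threshold (events with FL1-H below
#' `instrument_threshold_fl1` are discarded, mirroring the instrument
#' trigger; no threshold on FL3-H) and transforms the retained events to
#' the gating feature space `(log10 FL1-H, log10 max(FL3-H, 1))`. The
#' floor of 1 on FL3-H keeps unstained-red events at coordinate 0 instead
#' of -Inf. Raw channel values of the retained events are kept alongside
#' the features because cluster labelling uses raw-intensity medians.
#'
#' @param sample an [fcm_sample()].
#' @return An object of class `fcm_features`: list with `features`
#'   (numeric matrix, columns `log10_fl1`, `log10_fl3`), `raw` (retained
#'   events), `n_input`, `n_retained`, `time_h`, and the acquisition
#'   metadata needed by [count_populations()].
#' @export
preprocess_events <- function(sample) {
  stopifnot(inherits(sample, "fcm_sample"))
  keep <- sample$events$fl1_h >= sample$instrument_threshold_fl1
  n_ret <- sum(keep)
  if (n_ret == 0L) {
    abort("no events at or above the FL1-H threshold of %g (input %d events)",
          sample$instrument_threshold_fl1, nrow(sample$events))
  }
  raw <- sample$events[keep, , drop = FALSE]
  features <- cbind(log10_fl1 = log10(raw$fl1_h),
                    log10_fl3 = log10(pmax(raw$fl3_h, 1)))
  structure(
    list(features = features, raw = raw,
         n_input = nrow(sample$events), n_retained = n_ret,
         time_h = sample$time_h,
         acquired_volume_ul = sample$acquired_volume_ul,
         dilution_factor = sample$dilution_factor),
    class = "fcm_features"
  )
}

feature_matrix <- function(x) {
  if (inherits(x, "fcm_features")) x$features
  else if (is.matrix(x)) x
  else abort("expected an 'fcm_features' object or a numeric matrix")
}

#' Gate events by multi-restart spherical k-means
#'
#' Clusters the transformed events with k-means under cosine distance
#' (spherical k-means): feature vectors are projected onto the unit
#' circle, Lloyd iterations minimise the total cosine distance
#' `sum(1 - cos(x_i, c_a(i)))`, and the best of `restarts` seeded random
#' initialisations is returned. Empty clusters are re-seeded from the
#' point farthest from its centroid. Because cosine distance is
#' magnitude-blind, clusters are separated by their FL3:FL1 angle; raw
#' magnitudes re-enter only during labelling ([label_clusters()]).
#'
#' @param x an `fcm_features` object from [preprocess_events()] or a
#'   numeric feature matrix.
#' @param k number of clusters (default 4, the standard viability
#'   subpopulations).
#' @param restarts number of random initialisations (default 20).
#' @param seed integer seed; expands deterministically into per-restart
#'   seeds.
#' @param max_iter Lloyd iteration cap per restart.
#' @return An object of class `gate_model`: method, `k`, unit-norm
#'   `centroids`, integer per-event `labels`, achieved `objective`,
#'   per-cluster raw-intensity medians (`cluster_stats`, when raw events
#'   are available), and the seed. `label_map` is `NULL` until
#'   [label_clusters()] is applied.
#' @examples
#' prof <- simulate_batch_culture(culture_scenario(noise_cv = 0))
#' smp <- simulate_fcm_timeseries(prof, events_per_sample = 500, seed = 3)[[6]]
#' gm <- label_clusters(kmeans_gate(preprocess_events(smp), seed = 1))
#' gm$label_map
#' @export
kmeans_gate <- function(x, k = 4, restarts = 20, seed = 1L,
                        max_iter = 300L) {
  feats <- feature_matrix(x)
  stopifnot_scalar(k, "k", 1)
  stopifnot_scalar(restarts, "restarts", 1)
  norms <- sqrt(rowSums(feats^2))
  if (any(norms == 0)) {
    abort("%d event(s) have zero-norm feature vectors; cosine distance is undefined for them",
          sum(norms == 0))
  }
  xu <- feats / norms
  distinct <- unique(round(xu, 12))
  if (nrow(distinct) < k) {
    abort("only %d distinct unit feature vectors for k = %d clusters",
          nrow(distinct), k)
  }

  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- with_seed(derive_seed(seed, r), {
      spherical_lloyd(xu, k, max_iter)
    })
    if (is.null(best) || fit$objective < best$objective - 1e-12) best <- fit
  }

  stats_df <- NULL
  if (inherits(x, "fcm_features")) {
    stats_df <- data.frame(
      cluster = seq_len(k),
      n = as.vector(tabulate(best$labels, k)),
      median_fl1 = vapply(seq_len(k), function(j) {
        stats::median(x$raw$fl1_h[best$labels == j])
      }, numeric(1)),
      median_fl3 = vapply(seq_len(k), function(j) {
        stats::median(x$raw$fl3_h[best$labels == j])
      }, numeric(1))
    )
  }

  structure(
    list(method = "kmeans", k = k, distance = "cosine",
         restarts = restarts, centroids = best$centroids,
         labels = best$labels, objective = best$objective,
         iterations = best$iterations, cluster_stats = stats_df,
         label_map = NULL, seed = as.integer(seed)),
    class = "gate_model"
  )
}

# One seeded Lloyd run on unit-normalised rows. Initial centroids use
# k-means++ seeding under cosine distance (squared-distance weighting):
# with strongly imbalanced populations, uniform seeding almost never
# places a centroid in every true cluster and Lloyd then splits the
# dominant population instead.
spherical_lloyd <- function(xu, k, max_iter) {
  n <- nrow(xu)
  starts <- integer(k)
  starts[1] <- sample.int(n, 1)
  if (k > 1) {
    d2 <- pmax(1 - drop(xu %*% xu[starts[1], ]), 0)^2
    for (j in 2:k) {
      if (sum(d2) <= 0) {
        starts[j] <- sample.int(n, 1)
      } else {
        starts[j] <- sample.int(n, 1, prob = d2)
      }
      d2 <- pmin(d2, pmax(1 - drop(xu %*% xu[starts[j], ]), 0)^2)
    }
  }
  centroids <- xu[starts, , drop = FALSE]
  labels <- rep(0L, n)
  for (it in seq_len(max_iter)) {
    sim <- xu %*% t(centroids)
    new_labels <- max.col(sim, ties.method = "first")
    # re-seed empty clusters from the globally worst-fitted point
    empties <- setdiff(seq_len(k), unique(new_labels))
    for (e in empties) {
      far <- which.min(sim[cbind(seq_len(n), new_labels)])
      centroids[e, ] <- xu[far, ]
      new_labels[far] <- e
    }
    if (identical(new_labels, labels)) break
    labels <- new_labels
    for (j in seq_len(k)) {
      v <- colSums(xu[labels == j, , drop = FALSE])
      nv <- sqrt(sum(v^2))
      if (nv > 0) centroids[j, ] <- v / nv
    }
  }
  sim <- xu %*% t(centroids)
  objective <- sum(1 - sim[cbind(seq_len(n), labels)])
  list(centroids = centroids, labels = labels, objective = objective,
       iterations = it)
}

#' @export
print.gate_model <- function(x, ...) {
  cat(sprintf("<gate_model> %s, k = %d (%s distance), objective %.4f\n",
              x$method, x$k, x$distance, x$objective))
  if (!is.null(x$label_map)) {
    cat("  label_map:",
        paste(sprintf("%d=%s", seq_along(x$label_map), x$label_map),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Map k-means clusters to viability subpopulations
#'
#' Assigns the four fitted clusters to the standard subpopulation names.
#' Debris is the cluster with the lowest median raw FL1-H (lowest overall
#' stain uptake; this is the one step where raw magnitudes re-enter the
#' otherwise angle-based gating). The remaining three clusters are ranked
#' by their centroid FL3:FL1 angle: propidium iodide only enters
#' membrane-compromised cells, so the lowest angle is `intact`, the middle
#' `damaged_A` and the highest `damaged_B`. Angle ties are broken by
#' median raw FL3-H.
#'
#' @param model a `gate_model` with `k = 4` fitted on an `fcm_features`
#'   object (so cluster medians are available).
#' @return The model with `label_map` (character vector, cluster index ->
#'   population) and `populations` (per-event population labels) filled
#'   in.
#' @export
label_clusters <- function(model) {
  stopifnot(inherits(model, "gate_model"))
  if (model$k != 4L) {
    abort("automatic labelling requires k = 4 (got k = %d); supply an explicit cluster-to-population map instead",
          model$k)
  }
  if (is.null(model$cluster_stats)) {
    abort("cluster medians unavailable; fit the model on preprocess_events() output")
  }
  st <- model$cluster_stats
  debris <- which.min(st$median_fl1)
  rest <- setdiff(seq_len(4L), debris)
  ang <- atan2(model$centroids[rest, 2], model$centroids[rest, 1])
  ord <- rest[order(ang, st$median_fl3[rest])]
  map <- character(4)
  map[debris] <- "debris"
  map[ord] <- c("intact", "damaged_A", "damaged_B")
  model$label_map <- map
  model$populations <- map[model$labels]
  model
}

#' Build wedge-shaped fixed gates from boundary angles
#'
#' Constructs the fixed-gate counterpart of the angular k-means gating:
#' straight boundary lines through the origin of (log10 FL1, log10 FL3)
#' space at the given angles split the first quadrant into four wedges.
#' Populations in ascending-angle order are debris, intact, damaged A,
#' damaged B (debris carries little of either stain but proportionally
#' the least red signal).
#'
#' @param boundary_angles_deg three increasing angles (degrees from the
#'   FL1 axis) separating the four wedges.
#' @param labels population names of the wedges in ascending-angle order.
#' @return A fixed-gate region list consumable by [fixed_gate()].
#' @export
wedge_gates <- function(boundary_angles_deg = c(22.5, 35, 45),
                        labels = c("debris", "intact", "damaged_A",
                                   "damaged_B")) {
  stopifnot(length(boundary_angles_deg) == 3,
            !is.unsorted(boundary_angles_deg, strictly = TRUE),
            length(labels) == 4)
  th <- boundary_angles_deg * pi / 180
  below <- function(t) c(sin(t), -cos(t), 0)  # sin(t)*x - cos(t)*y >= 0
  above <- function(t) c(-sin(t), cos(t), 0)
  list(
    structure(list(name = labels[1], halfplanes = rbind(below(th[1])))),
    structure(list(name = labels[2],
                   halfplanes = rbind(above(th[1]), below(th[2])))),
    structure(list(name = labels[3],
                   halfplanes = rbind(above(th[2]), below(th[3])))),
    structure(list(name = labels[4], halfplanes = rbind(above(th[3]))))
  )
}

#' Build quadrant fixed gates from one vertical and one horizontal split
#'
#' @param x_split,y_split boundary coordinates in feature space.
#' @param labels population names for the (low x, low y), (high x, low y),
#'   (low x, high y), (high x, high y) quadrants, in that order.
#' @return A fixed-gate region list consumable by [fixed_gate()].
#' @export
quadrant_gates <- function(x_split, y_split,
                           labels = c("debris", "intact", "damaged_A",
                                      "damaged_B")) {
  stopifnot(length(labels) == 4)
  lo_x <- c(-1, 0, x_split)   # x <= x_split
  hi_x <- c(1, 0, -x_split)   # x >= x_split
  lo_y <- c(0, -1, y_split)
  hi_y <- c(0, 1, -y_split)
  list(
    list(name = labels[1], halfplanes = rbind(lo_x, lo_y)),
    list(name = labels[2], halfplanes = rbind(hi_x, lo_y)),
    list(name = labels[3], halfplanes = rbind(lo_x, hi_y)),
    list(name = labels[4], halfplanes = rbind(hi_x, hi_y))
  )
}

#' Gate events with fixed linear boundaries
#'
#' Labels each event by the first region (in list order) whose linear
#' constraints it satisfies. Each region is a named list with a
#' `halfplanes` matrix whose rows `(a, b, c)` encode the oriented
#' inequality `a*x + b*y + c >= 0`; all inequalities are non-strict, so a
#' point lying exactly on a boundary belongs to the non-negative side of
#' that boundary and, where two regions share it, to the earlier-listed
#' region — a deterministic convention.
#'
#' @param x an `fcm_features` object or feature matrix.
#' @param regions list of regions, e.g. from [wedge_gates()] or
#'   [quadrant_gates()]; together they must cover every event.
#' @return Character vector of per-event population labels.
#' @export
fixed_gate <- function(x, regions) {
  feats <- feature_matrix(x)
  if (length(regions) != 4L) {
    abort("fixed gating requires exactly 4 labelled regions (got %d)",
          length(regions))
  }
  nms <- vapply(regions, function(r) r$name, "")
  if (anyDuplicated(nms)) abort("region names must be distinct")
  labels <- rep(NA_character_, nrow(feats))
  for (r in regions) {
    hp <- r$halfplanes
    inside <- rep(TRUE, nrow(feats))
    for (i in seq_len(nrow(hp))) {
      inside <- inside &
        (hp[i, 1] * feats[, 1] + hp[i, 2] * feats[, 2] + hp[i, 3] >= 0)
    }
    labels[is.na(labels) & inside] <- r$name
  }
  if (anyNA(labels)) {
    abort("%d event(s) fall outside every gate region; regions must cover the observed feature space",
          sum(is.na(labels)))
  }
  labels
}

#' Convert per-event labels to subpopulation concentrations
#'
#' Counts events per population among the retained (post-threshold)
#' events and converts to events per mL of undiluted culture:
#' `count / acquired_volume * dilution_factor`. The four subpopulation
#' counts sum exactly to the total by construction.
#'
#' @param labels character vector of population labels, aligned with the
#'   retained events of `x`.
#' @param x the `fcm_features` object the labels were derived from (or an
#'   [fcm_sample()], which is preprocessed first).
#' @return One-row data frame of class `subpop_counts` with columns
#'   `time_h`, `total`, `intact`, `damaged_A`, `damaged_B`, `debris`
#'   (AFU/mL) and attribute `raw_counts` (integer event counts).
#' @export
count_populations <- function(labels, x) {
  if (inherits(x, "fcm_sample")) x <- preprocess_events(x)
  stopifnot(inherits(x, "fcm_features"))
  if (length(labels) != x$n_retained) {
    abort("labels (%d) do not align with retained events (%d)",
          length(labels), x$n_retained)
  }
  pops <- c("intact", "damaged_A", "damaged_B", "debris")
  unknown <- setdiff(unique(labels), pops)
  if (length(unknown)) {
    abort("unknown population label(s): %s", paste(unknown, collapse = ", "))
  }
  raw_counts <- vapply(pops, function(p) sum(labels == p), integer(1))
  per_event <- x$dilution_factor / (x$acquired_volume_ul / 1000)
  out <- data.frame(time_h = x$time_h,
                    total = sum(raw_counts) * per_event,
                    intact = raw_counts[["intact"]] * per_event,
                    damaged_A = raw_counts[["damaged_A"]] * per_event,
                    damaged_B = raw_counts[["damaged_B"]] * per_event,
                    debris = raw_counts[["debris"]] * per_event)
  attr(out, "raw_counts") <- c(raw_counts, total = sum(raw_counts))
  class(out) <- c("subpop_counts", "data.frame")
  out
}

#' Gate a flow-cytometry time course
#'
#' Convenience wrapper running [preprocess_events()], the chosen gating
#' method, and [count_populations()] over a list of samples. With
#' `method = "kmeans"` a fresh model is fitted per sample (per-sample
#' clustering); per-sample seeds are derived deterministically from
#' `seed`.
#'
#' @param samples list of [fcm_sample()] objects.
#' @param method `"kmeans"` or `"fixed"`.
#' @param regions fixed-gate regions (default [wedge_gates()]), used when
#'   `method = "fixed"`.
#' @param k,restarts,seed passed to [kmeans_gate()].
#' @return Data frame (one row per sample) of subpopulation
#'   concentrations, with the per-sample gate models attached as attribute
#'   `models` when k-means is used.
#' @export
gate_fcm_series <- function(samples, method = c("kmeans", "fixed"),
                            regions = wedge_gates(), k = 4, restarts = 20,
                            seed = 1L) {
  method <- match.arg(method)
  stopifnot(length(samples) >= 1)
  models <- vector("list", length(samples))
  rows <- lapply(seq_along(samples), function(i) {
    ft <- preprocess_events(samples[[i]])
    if (method == "kmeans") {
      gm <- label_clusters(kmeans_gate(ft, k = k, restarts = restarts,
                                       seed = derive_seed(seed, i)))
      models[[i]] <<- gm
      count_populations(gm$populations, ft)
    } else {
      count_populations(fixed_gate(ft, regions), ft)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "models") <- if (method == "kmeans") models else NULL
  out
}

#' Agreement between two gating methods
#'
#' Per-population coefficient of determination (squared Pearson
#' correlation) between two subpopulation time courses obtained with
#' different gating methods on the same samples, the standard way
#' automated gating is benchmarked against manual or fixed gating.
#'
#' @param series_a,series_b data frames as returned by
#'   [gate_fcm_series()], with matching `time_h` values (at least 3).
#' @return Data frame with columns `population` and `r_squared`.
#' @export
compare_gating <- function(series_a, series_b) {
  common <- intersect(series_a$time_h, series_b$time_h)
  if (length(common) < 3) {
    abort("need at least 3 matched time points (got %d)", length(common))
  }
  a <- series_a[match(common, series_a$time_h), ]
  b <- series_b[match(common, series_b$time_h), ]
  pops <- c("total", "intact", "damaged_A", "damaged_B", "debris")
  r2 <- vapply(pops, function(p) {
    va <- a[[p]]; vb <- b[[p]]
    if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
      warn("population '%s' has zero variance in one series; R^2 undefined", p)
      return(NA_real_)
    }
    stats::cor(va, vb)^2
  }, numeric(1))
  data.frame(population = pops, r_squared = unname(r2))
}

#' Export a fitted gate model as structured text
#'
#' Writes centroids, the cluster-to-population map, the achieved
#' objective, and the seed as YAML for audit trails.
#'
#' @param model a `gate_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gate_model <- function(model, path) {
  stopifnot(inherits(model, "gate_model"))
  yaml::write_yaml(list(
    method = model$method, k = model$k, distance = model$distance,
    restarts = model$restarts, seed = model$seed,
    objective = model$objective,
    centroids = apply(model$centroids, 1, as.list),
    label_map = as.list(model$label_map %||% character())
  ), path)
  invisible(path)
}
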