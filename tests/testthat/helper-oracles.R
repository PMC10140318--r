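# Independent oracles and fixture builders used across the test files.
# These deliberately avoid the package's own code paths wherever they
# check one.

# Minimal culture_profile built directly from vectors (bypasses the
# generator) for endpoint arithmetic checks.
toy_profile <- function(time_h, glucose, lactate = 0, acetate = 0,
                        ethanol = 0, citrate = 0, succinate = 0,
                        od = 1, dot = 100, cdw_harvest = NULL) {
  expand <- function(v) if (length(v) == 1) rep(v, length(time_h)) else v
  structure(
    list(series = data.frame(
      time_h = time_h, od620 = expand(od), dot_pct = expand(dot),
      base_ml = 0, glucose_g_l = expand(glucose),
      citrate_g_l = expand(citrate), lactate_g_l = expand(lactate),
      acetate_g_l = expand(acetate), ethanol_g_l = expand(ethanol),
      succinate_g_l = expand(succinate)),
      cdw_harvest = cdw_harvest, depletion_h = NA_real_, truth = NULL),
    class = "culture_profile")
}

# Cosine k-means objective for a fixed assignment, with the optimal
# (normalised-mean) centroid per cluster.
cosine_partition_objective <- function(xu, labels) {
  obj <- 0
  for (j in unique(labels)) {
    rows <- xu[labels == j, , drop = FALSE]
    v <- colSums(rows)
    nv <- sqrt(sum(v^2))
    obj <- obj + if (nv > 0) sum(1 - rows %*% (v / nv)) else nrow(rows)
  }
  obj
}

# Exhaustive best 2-partition by full enumeration (n <= 16).
best_two_partition_enum <- function(xu) {
  n <- nrow(xu)
  stopifnot(n <= 16)
  best <- Inf
  for (mask in 0:(2^(n - 1) - 1)) {
    labels <- c(1L, as.integer(intToBits(mask))[seq_len(n - 1)] + 1L)
    if (length(unique(labels)) < 2) next
    best <- min(best, cosine_partition_objective(xu, labels))
  }
  best
}

# Best 2-partition over angular splits: for points within a quadrant the
# optimal cosine 2-clustering is contiguous in angle, so scanning all
# n - 1 splits of the angle-sorted points is exhaustive.
best_two_partition_arc <- function(xu) {
  ang <- atan2(xu[, 2], xu[, 1])
  ord <- order(ang)
  n <- nrow(xu)
  best <- Inf
  for (i in seq_len(n - 1)) {
    labels <- integer(n)
    labels[ord[seq_len(i)]] <- 1L
    labels[ord[(i + 1):n]] <- 2L
    best <- min(best, cosine_partition_objective(xu, labels))
  }
  best
}

# Two well-separated unit-direction clouds in the first quadrant.
make_two_cluster_features <- function(n, angles_deg = c(20, 60),
                                      sd = 0.01, seed = 1) {
  set.seed(seed)
  half <- n %/% 2
  ang <- c(stats::rnorm(half, angles_deg[1] * pi / 180, sd),
           stats::rnorm(n - half, angles_deg[2] * pi / 180, sd))
  r <- stats::runif(n, 1, 5)
  cbind(r * cos(ang), r * sin(ang))
}

# Population specs with constant fractions, for proportion checks.
constant_fraction_specs <- function(w = c(intact = 0.4, damaged_A = 0.3,
                                          damaged_B = 0.2, debris = 0.1)) {
  base <- default_population_specs()
  for (nm in names(base)) {
    base[[nm]]$fraction_trajectory <- local({
      wi <- w[[nm]]
      function(t) wi
    })
  }
  base
}

# Published-scale membrane FAME composition as summary-form tables.
reference_fame_summaries <- function() {
  ref <- fame_reference_dsm17938()
  lapply(split(ref, ref$condition), function(d) {
    summarize_fames(fame_table_from_summary(
      d$condition[1], d$mean_ug_mg, d$sd_ug_mg, d$fa_id,
      below_loq = d$below_loq))
  })
}
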