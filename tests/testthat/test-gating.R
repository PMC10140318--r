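prof0 <- simulate_batch_culture(culture_scenario(noise_cv = 0))

test_that("preprocessing applies the FL1 threshold and log transform", {
  smp <- fcm_sample(1, data.frame(fl1_h = c(400, 600), fl3_h = c(10, 0)))
  ft <- preprocess_events(smp)
  expect_equal(ft$n_retained, 1L)
  expect_equal(ft$n_input, 2L)
  expect_equal(unname(ft$features[1, ]), c(log10(600), 0)) # FL3 floored at 1
  all_below <- fcm_sample(1, data.frame(fl1_h = c(10, 20), fl3_h = c(1, 1)))
  expect_error(preprocess_events(all_below), "threshold")
})

test_that("k-means gating recovers generating labels on separated clouds", {
  smp <- simulate_fcm_timeseries(prof0, events_per_sample = 4000,
                                 seed = 31)[[15]]
  ft <- preprocess_events(smp)
  gm <- label_clusters(kmeans_gate(ft, seed = 5))
  expect_gte(mean(gm$populations == ft$raw$true_label), 0.99)
  # exact confusion matrix is computable from the stored labels
  cm <- table(gm$populations, ft$raw$true_label)
  expect_equal(sum(cm), ft$n_retained)
})

test_that("cosine gating is invariant to per-event positive rescaling", {
  x <- make_two_cluster_features(300, seed = 2)
  a <- kmeans_gate(x, k = 2, restarts = 5, seed = 1)
  scales <- stats::runif(300, 0.1, 10)
  b <- kmeans_gate(x * scales, k = 2, restarts = 5, seed = 1)
  expect_identical(a$labels, b$labels)
  expect_equal(a$objective, b$objective, tolerance = 1e-9)
})

test_that("the best-of-restarts objective is non-increasing in restarts", {
  x <- make_two_cluster_features(400, angles_deg = c(15, 40, 65)[1:2],
                                 sd = 0.15, seed = 3)
  objs <- vapply(c(1, 2, 5, 10, 20), function(r) {
    kmeans_gate(x, k = 3, restarts = r, seed = 7)$objective
  }, numeric(1))
  expect_true(all(diff(objs) <= 1e-12))
})

test_that("gating is deterministic for a fixed seed and errors on k > distinct points", {
  x <- make_two_cluster_features(200, seed = 4)
  a <- kmeans_gate(x, k = 2, restarts = 3, seed = 11)
  b <- kmeans_gate(x, k = 2, restarts = 3, seed = 11)
  expect_identical(a$labels, b$labels)
  same_dir <- cbind(rep(1, 5), rep(1, 5))
  expect_error(kmeans_gate(same_dir, k = 2), "distinct")
  one <- kmeans_gate(same_dir, k = 1, restarts = 1, seed = 1)
  expect_equal(one$objective, 0, tolerance = 1e-12)
})

test_that("Lloyd matches the exhaustive 2-cluster oracle", {
  # full enumeration at tiny n
  x_small <- make_two_cluster_features(12, sd = 0.02, seed = 6)
  xu <- x_small / sqrt(rowSums(x_small^2))
  fit <- kmeans_gate(x_small, k = 2, restarts = 10, seed = 2)
  expect_equal(fit$objective, best_two_partition_enum(xu), tolerance = 1e-9)
  # angular-split search at n = 200 with >10x separation-to-dispersion
  x_big <- make_two_cluster_features(200, angles_deg = c(20, 60), sd = 0.03,
                                     seed = 7)
  xu_big <- x_big / sqrt(rowSums(x_big^2))
  fit_big <- kmeans_gate(x_big, k = 2, restarts = 10, seed = 3)
  expect_equal(fit_big$objective, best_two_partition_arc(xu_big),
               tolerance = 1e-9)
})

test_that("cluster labelling follows the debris/angle ordering rule", {
  smp <- simulate_fcm_timeseries(prof0, events_per_sample = 3000,
                                 seed = 41)[[13]]
  ft <- preprocess_events(smp)
  gm <- label_clusters(kmeans_gate(ft, seed = 9))
  # debris cluster is the one with lowest median raw FL1
  debris_cluster <- which(gm$label_map == "debris")
  expect_equal(debris_cluster, which.min(gm$cluster_stats$median_fl1))
  # remaining ordered by centroid angle
  rest <- setdiff(seq_len(4), debris_cluster)
  ang <- atan2(gm$centroids[rest, 2], gm$centroids[rest, 1])
  expect_identical(gm$label_map[rest[order(ang)]],
                   c("intact", "damaged_A", "damaged_B"))
  bad <- kmeans_gate(ft, k = 3, seed = 1)
  expect_error(label_clusters(bad), "k = 4")
})

test_that("angle ties in labelling are broken by median FL3, deterministically", {
  model <- structure(
    list(method = "kmeans", k = 4L, distance = "cosine",
         centroids = rbind(c(1, 0), c(1, 1) / sqrt(2), c(1, 1) / sqrt(2),
                           c(0.6, 0.8)),
         labels = rep(1:4, each = 5), objective = 0,
         cluster_stats = data.frame(cluster = 1:4, n = 5,
                                    median_fl1 = c(100, 5000, 6000, 4000),
                                    median_fl3 = c(5, 900, 100, 2000))),
    class = "gate_model")
  m <- label_clusters(model)
  expect_identical(m$label_map[1], "debris")
  # clusters 2 and 3 share the 45-degree angle: lower median FL3 wins the
  # lower (less damaged) rank
  expect_identical(m$label_map[3], "intact")
  expect_identical(m$label_map[2], "damaged_A")
  expect_identical(m$label_map[4], "damaged_B")
})

test_that("fixed quadrant gates reproduce exact quadrant membership", {
  set.seed(8)
  x <- cbind(stats::runif(500, 2, 5), stats::runif(500, 0, 4))
  gates <- quadrant_gates(3.5, 2)
  labels <- fixed_gate(x, gates)
  oracle <- ifelse(x[, 1] <= 3.5,
                   ifelse(x[, 2] <= 2, "debris", "damaged_A"),
                   ifelse(x[, 2] <= 2, "intact", "damaged_B"))
  expect_identical(labels, oracle)
  # boundary point: non-strict inequalities, first-listed region wins
  on_edge <- rbind(c(3.5, 1))
  expect_identical(fixed_gate(on_edge, gates),
                   fixed_gate(on_edge, gates)) # stable
  expect_identical(fixed_gate(on_edge, gates), "debris")
})

test_that("gates that do not cover the plane are rejected", {
  x <- cbind(c(1, 2), c(1, 2))
  gates <- quadrant_gates(10, 10)
  gates[[1]]$halfplanes <- rbind(c(0, 1, -100)) # y >= 100: hole at origin
  gates[[2]]$halfplanes <- rbind(c(0, 1, -100))
  gates[[3]]$halfplanes <- rbind(c(0, 1, -100))
  gates[[4]]$halfplanes <- rbind(c(0, 1, -100))
  expect_error(fixed_gate(x, gates), "cover")
})

test_that("population counting applies the volume and dilution arithmetic", {
  ev <- data.frame(fl1_h = rep(1000, 2000), fl3_h = rep(10, 2000))
  smp <- fcm_sample(2, ev, acquired_volume_ul = 20, dilution_factor = 1000)
  ft <- preprocess_events(smp)
  labels <- rep(c("intact", "debris"), 1000)
  counts <- count_populations(labels, ft)
  expect_equal(counts$total, 1.0e8)
  expect_equal(counts$intact, 5.0e7)
  expect_equal(counts$damaged_B, 0)
  # halving the dilution halves every concentration
  smp2 <- fcm_sample(2, ev, acquired_volume_ul = 20, dilution_factor = 500)
  counts2 <- count_populations(labels, preprocess_events(smp2))
  expect_equal(counts2$total, counts$total / 2)
  # partition identity on the raw integer counts
  raw <- attr(counts, "raw_counts")
  expect_identical(sum(raw[c("intact", "damaged_A", "damaged_B", "debris")]),
                   raw[["total"]])
})

test_that("gating method agreement scores R^2 per population", {
  t <- 1:6
  base <- data.frame(time_h = t, total = 10 * t, intact = 8 * t,
                     damaged_A = t, damaged_B = 0.5 * t, debris = 0.5 * t)
  expect_equal(compare_gating(base, base)$r_squared, rep(1, 5),
               tolerance = 1e-9)
  doubled <- base
  doubled[-1] <- base[-1] * 2
  expect_equal(compare_gating(base, doubled)$r_squared, rep(1, 5),
               tolerance = 1e-9)
  expect_error(compare_gating(base[1:2, ], base[1:2, ]), "3")
})

test_that("per-sample counts sum exactly to totals across a gated run", {
  fcm <- simulate_fcm_timeseries(prof0, events_per_sample = 800, seed = 12)
  counts <- gate_fcm_series(fcm[seq(1, 17, 4)], method = "kmeans",
                            restarts = 5, seed = 2)
  expect_equal(counts$intact + counts$damaged_A + counts$damaged_B +
                 counts$debris, counts$total, tolerance = 1e-12)
})

test_that("gate models serialise to auditable YAML", {
  smp <- simulate_fcm_timeseries(prof0, events_per_sample = 500, seed = 3)[[9]]
  gm <- label_clusters(kmeans_gate(preprocess_events(smp), seed = 4))
  path <- file.path(tempdir(), "gate.yaml")
  write_gate_model(gm, path)
  back <- yaml::read_yaml(path)
  expect_equal(back$k, 4)
  expect_setequal(unlist(back$label_map),
                  c("intact", "damaged_A", "damaged_B", "debris"))
})
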