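test_that("freeze-drying survivability is a scale-invariant percentage", {
  expect_equal(as.numeric(fd_survivability(2.0e9, 1.236e9)), 61.8)
  expect_equal(as.numeric(fd_survivability(5e8, 5e8)), 100)
  # scale invariance
  expect_equal(as.numeric(fd_survivability(2e9 * 7, 1.236e9 * 7)), 61.8)
  expect_warning(over <- fd_survivability(1e9, 1.1e9), "exceeds")
  expect_true(attr(over, "above_100"))
  expect_warning(gone <- fd_survivability(1e9, 0), "extinction")
  expect_equal(as.numeric(gone), 0)
  expect_true(attr(gone, "extinct"))
})

test_that("acid summaries are exact on noiseless log-linear series", {
  a <- data.frame(minute = c(0, 20, 40), cfu = c(1e8, 1e7, 1e6),
                  censored = FALSE)
  s <- acid_survival_summary(a)
  expect_equal(s$death_rate, 0.05, tolerance = 1e-12)
  expect_equal(s$log10_reduction$log10_reduction, c(0, -1, -2))
  expect_true(s$survived_at_end)
  expect_equal(s$n_censored, 0)
})

test_that("censored points are excluded and can leave the rate undefined", {
  a <- data.frame(minute = c(0, 20, 50, 90), cfu = c(1e8, 1e3, 1e3, 1e3),
                  censored = c(FALSE, TRUE, TRUE, TRUE))
  expect_warning(s <- acid_survival_summary(a), "undefined")
  expect_true(is.na(s$death_rate))
  expect_equal(s$n_censored, 3)
  expect_false(s$survived_at_end)
  bad <- data.frame(minute = c(0, 20), cfu = c(1e3, 1e2),
                    censored = c(TRUE, FALSE))
  expect_error(acid_survival_summary(bad), "timepoint-0")
})

test_that("a death rate crossing the LOD at 60 min censors the 90-min point", {
  # log10 drops from 8 to the LOD (10^3) in 60 min: rate = 5/60
  assay <- simulate_acid_challenge(1e8, death_rate = 5 / 60, lod = 1e3,
                                   seed = 11)
  expect_false(assay$data$censored[1])
  expect_true(assay$data$censored[4])
  expect_equal(assay$data$cfu[4], 1e3) # reported at the LOD, not zero
  # zero death rate: every timepoint near the inoculum
  flat <- simulate_acid_challenge(1e8, death_rate = 0, seed = 2)
  expect_equal(flat$data$cfu, rep(1e8, 4), tolerance = 0.3)
  expect_false(any(flat$data$censored))
})

test_that("the death-rate estimator recovers the generating rate", {
  rates <- vapply(1:30, function(s) {
    acid_survival_summary(simulate_acid_challenge(
      1e8, death_rate = 0.05, lod = 10, seed = s))$death_rate
  }, numeric(1))
  expect_lt(abs(stats::median(rates) - 0.05) / 0.05, 0.10)
})

test_that("bile lag time inverts a logistic curve built to cross at 7.5 h", {
  od_0 <- 0.05; od_max <- 1.2; mu <- 0.8
  offset <- log(0.5 * (od_max - od_0) / (od_0 * (od_max - 0.5))) / mu
  curve <- simulate_bile_curve(lag_h = 7.5 - offset, mu = mu,
                               od_max = od_max, od_0 = od_0, noise_cv = 0)
  res <- bile_lag_time(curve)
  expect_true(res$reached)
  expect_equal(res$lag_h, 7.5, tolerance = 0.125 / 7.5) # one grid step
  # finer grid refines the estimate
  fine <- simulate_bile_curve(lag_h = 7.5 - offset, mu = mu,
                              od_max = od_max, od_0 = od_0,
                              interval_min = 1, noise_cv = 0)
  expect_equal(bile_lag_time(fine)$lag_h, 7.5, tolerance = (1 / 60) / 7.5)
})

test_that("bile curves that never reach the cutoff say so", {
  low <- simulate_bile_curve(lag_h = 2, mu = 1, od_max = 0.4, noise_cv = 0)
  res <- bile_lag_time(low)
  expect_false(res$reached)
  expect_true(is.na(res$lag_h))
  flat <- data.frame(time_h = seq(0, 24, 0.25), od = 0.2)
  expect_false(bile_lag_time(flat)$reached)
})

test_that("curves starting above the cutoff report a zero lag with warning", {
  d <- data.frame(time_h = seq(0, 4, 0.25), od = seq(0.6, 1.2, length.out = 17))
  expect_warning(res <- bile_lag_time(d), "already")
  expect_equal(res$lag_h, 0)
  expect_true(res$started_above)
})

test_that("shifting a bile curve in time shifts the lag by the same amount", {
  curve <- simulate_bile_curve(lag_h = 4, mu = 0.9, noise_cv = 0)
  base <- bile_lag_time(curve)$lag_h
  shifted <- curve$data
  shifted$time_h <- shifted$time_h + 2
  expect_equal(bile_lag_time(shifted)$lag_h, base + 2, tolerance = 1e-9)
})

test_that("5'NT summaries average technical replicates within biology first", {
  m <- data.frame(condition = "air",
                  biological_rep = c(1, 1, 1, 2, 2, 2),
                  technical_rep = rep(1:3, 2),
                  u_per_l = c(350, 360, 370, 380, 390, 400))
  nested <- nt_activity_summary(m)
  expect_equal(nested$mean_u_per_l, 375)
  expect_equal(nested$sd_u_per_l, stats::sd(c(360, 390)))
  expect_equal(nested$n, 2)
  pooled <- nt_activity_summary(m, mode = "pooled")
  expect_equal(pooled$n, 6)
  expect_equal(nt_activity_summary(
    data.frame(condition = "x", biological_rep = 1:2,
               u_per_l = c(370, 370)))$sd_u_per_l, 0)
  expect_error(nt_activity_summary(m[0, ]), "no measurements")
})
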