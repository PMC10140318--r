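test_that("mu_max recovers closed-form exponentials and is scale-invariant", {
  t <- 0:6
  fit <- estimate_mu_max(t, 0.1 * 2^t)
  expect_equal(fit$mu_max, log(2), tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  # multiplying the signal by any positive constant changes nothing
  fit2 <- estimate_mu_max(t, 7.3e8 * 2^t)
  expect_equal(fit2$mu_max, fit$mu_max, tolerance = 1e-10)
  expect_equal(fit2$window, fit$window)
})

test_that("a constant signal yields slope 0 with a degraded-fit warning", {
  expect_warning(fit <- estimate_mu_max(0:5, rep(2, 6)), "R\\^2")
  expect_equal(fit$mu_max, 0, tolerance = 1e-12)
  expect_true(fit$degraded)
})

test_that("window selection finds the exponential phase inside a full batch curve", {
  # lag, exponential at mu = 0.6, then stationary
  t <- seq(0, 10, 0.5)
  x <- ifelse(t < 2, 0.1, ifelse(t <= 7, 0.1 * exp(0.6 * (t - 2)),
                                 0.1 * exp(0.6 * 5)))
  fit <- estimate_mu_max(t, x)
  expect_equal(fit$mu_max, 0.6, tolerance = 1e-8)
  expect_gte(fit$window[1], 2)
  expect_lte(fit$window[2], 7)
})

test_that("DOT depletion time interpolates the first crossing", {
  expect_equal(dot_depletion_time(c(0, 2), c(100, 0)), 1.98)
  never <- dot_depletion_time(c(0, 1, 2), c(100, 80, 60))
  expect_true(is.na(never))
  expect_identical(attr(never, "status"), "never")
  # crossing exactly at a sample point returns that time
  expect_equal(dot_depletion_time(c(0, 1, 2), c(100, 1, 0), threshold = 1), 1)
  expect_error(dot_depletion_time(c(0, 1), c(0.5, 0.2)), "below")
})

test_that("yields follow the net-product-over-glucose definition", {
  prof <- toy_profile(time_h = c(0, 7), glucose = c(10, 0),
                      lactate = c(0, 5), acetate = c(0.5, 0.2),
                      cdw_harvest = 1.2)
  expect_warning(y <- compute_yields(prof), "negative")
  expect_equal(y[["lactate"]], 0.5)
  expect_equal(y[["biomass"]], 0.12)
  expect_lt(y[["acetate"]], 0) # net consumption reported, not clamped
  flat <- toy_profile(c(0, 7), glucose = c(10, 10), cdw_harvest = 1)
  expect_error(compute_yields(flat), "consumed")
})

test_that("generator yields are recovered by the analysis round trip", {
  prof <- simulate_batch_culture(culture_scenario(yield_acetate = 0.11,
                                                  noise_cv = 0))
  y <- compute_yields(prof, inoculum_cdw = 0.2 * 0.45)
  expect_equal(y[["acetate"]], 0.11, tolerance = 1e-9)
  expect_equal(y[["biomass"]], 0.085, tolerance = 1e-9)
})

test_that("specific rates divide by CDW and time-to-depletion", {
  prof <- toy_profile(time_h = 0:7, glucose = c(10, 9, 7, 5, 3, 2, 1, 0.05),
                      lactate = seq(0, 5, length.out = 8) * c(rep(1, 8)),
                      cdw_harvest = 1.56)
  q <- specific_rates(prof)
  expect_equal(q[["lactate"]], 5 / (1.56 * 7), tolerance = 1e-6)
  # doubling CDW halves every rate
  prof2 <- prof
  prof2$cdw_harvest <- 2 * 1.56
  expect_equal(specific_rates(prof2), q / 2, tolerance = 1e-12)
  # glucose already depleted at time zero: undefined
  dead <- toy_profile(0:2, glucose = c(0.05, 0.02, 0), cdw_harvest = 1)
  expect_error(specific_rates(dead), "rates undefined")
})

test_that("the homolactic toy case closes the carbon balance at exactly 100%", {
  prof <- toy_profile(c(0, 8), glucose = c(10, 0), lactate = c(0, 10))
  expect_equal(carbon_balance(prof), 100, tolerance = 1e-9)
  # no products at all: 0% (with the out-of-band warning)
  none <- toy_profile(c(0, 8), glucose = c(10, 0))
  expect_warning(pct <- carbon_balance(none), "outside")
  expect_equal(pct, 0)
})

test_that("stoichiometric heterofermentative scenarios close at 100 +/- 0.5%", {
  # 1 glucose -> 1 lactate + 1 ethanol + 1 CO2 (phosphoketolase split)
  y_eth <- 46.068 / 180.156
  sc <- culture_scenario(yield_lactate = 0.5, yield_ethanol = y_eth,
                         yield_acetate = 0, yield_biomass = 1e-6,
                         od_0 = 0.001, citrate_0 = 0, noise_cv = 0)
  expect_equal(carbon_balance(simulate_batch_culture(sc)), 100,
               tolerance = 0.005)
  # 30% of the C2 flux to acetate instead of ethanol
  sc2 <- culture_scenario(yield_lactate = 0.5,
                          yield_ethanol = 0.7 * 46.068 / 180.156,
                          yield_acetate = 0.3 * 60.052 / 180.156,
                          yield_biomass = 1e-6, od_0 = 0.001,
                          citrate_0 = 0, noise_cv = 0)
  expect_equal(carbon_balance(simulate_batch_culture(sc2)), 100,
               tolerance = 0.005)
})

test_that("missing compound series are treated as zero with a warning", {
  prof <- toy_profile(c(0, 8), glucose = c(10, 0), lactate = c(0, 10))
  prof$series$succinate_g_l <- NULL
  expect_warning(pct <- carbon_balance(prof), "succinate")
  expect_equal(pct, 100, tolerance = 1e-9)
})

test_that("forward-scatter summaries are per-sample means of retained events", {
  ev <- data.frame(fl1_h = rep(1000, 50), fl3_h = rep(10, 50),
                   fsc_h = rep(100, 50))
  expect_equal(summarize_scatter(fcm_sample(1, ev))$mean_fsc_h, 100)
  no_fsc <- fcm_sample(1, ev[c("fl1_h", "fl3_h")])
  expect_error(summarize_scatter(no_fsc), "FSC-H")
  # log-normal draws: sample mean within 3 SE of the analytic mean
  set.seed(99)
  n <- 20000
  mu <- 4; s <- 0.15
  ev2 <- data.frame(fl1_h = rep(1000, n), fl3_h = rep(10, n),
                    fsc_h = 10^stats::rnorm(n, mu, s))
  analytic <- exp(mu * log(10) + (s * log(10))^2 / 2)
  analytic_sd <- sqrt((exp((s * log(10))^2) - 1)) * analytic
  got <- summarize_scatter(fcm_sample(1, ev2))$mean_fsc_h
  expect_lt(abs(got - analytic), 3 * analytic_sd / sqrt(n))
})

test_that("the full kinetic summary assembles every component", {
  prof <- simulate_batch_culture(culture_scenario(seed = 5))
  k <- summarize_kinetics(prof)
  expect_s3_class(k, "kinetics_result")
  expect_equal(k$mu_max_od$mu_max, 0.74, tolerance = 0.1)
  expect_equal(k$mu_max_fcm$mu_max, k$mu_max_od$mu_max, tolerance = 0.15)
  expect_true(k$carbon_balance_pct > 90 && k$carbon_balance_pct < 110)
})
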