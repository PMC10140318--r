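prof_clean <- simulate_batch_culture(culture_scenario(noise_cv = 0))

test_that("generated events honour the requested population proportions", {
  specs <- constant_fraction_specs(c(intact = 0.4, damaged_A = 0.3,
                                     damaged_B = 0.2, debris = 0.1))
  smp <- simulate_fcm_timeseries(prof_clean, specs = specs,
                                 events_per_sample = 10000, seed = 21)
  last <- smp[[length(smp)]]
  frac <- table(last$events$true_label) / nrow(last$events)
  expect_equal(unname(frac[["intact"]]), 0.4, tolerance = 0.05)
  expect_equal(unname(frac[["damaged_A"]]), 0.3, tolerance = 0.07)
  expect_equal(unname(frac[["damaged_B"]]), 0.2, tolerance = 0.1)
  expect_equal(unname(frac[["debris"]]), 0.1, tolerance = 0.2)
})

test_that("a population with weight 1 contributes every event", {
  specs <- constant_fraction_specs(c(intact = 1, damaged_A = 0,
                                     damaged_B = 0, debris = 0))
  smp <- simulate_fcm_timeseries(prof_clean, specs = specs,
                                 events_per_sample = 500, seed = 3)
  expect_true(all(smp[[5]]$events$true_label == "intact"))
})

test_that("the same seed reproduces the event lists exactly", {
  a <- simulate_fcm_timeseries(prof_clean, events_per_sample = 300, seed = 9)
  b <- simulate_fcm_timeseries(prof_clean, events_per_sample = 300, seed = 9)
  expect_identical(lapply(a, `[[`, "events"), lapply(b, `[[`, "events"))
})

test_that("fractions that do not sum to one are rejected", {
  bad <- constant_fraction_specs(c(intact = 0.5, damaged_A = 0.3,
                                   damaged_B = 0.2, debris = 0.2))
  expect_error(simulate_fcm_timeseries(prof_clean, specs = bad,
                                       events_per_sample = 200, seed = 1),
               "sum")
})

test_that("event counts track culture biomass", {
  smp <- simulate_fcm_timeseries(prof_clean, events_per_sample = 5000,
                                 seed = 2)
  n <- vapply(smp, function(s) nrow(s$events), numeric(1))
  expect_lt(n[1], n[length(n)] / 5) # strong growth over the batch
  expect_equal(max(n), 5000, tolerance = 0.02)
})

test_that("tidy CSV round-trips samples with metadata", {
  smp <- simulate_fcm_timeseries(prof_clean, events_per_sample = 200,
                                 seed = 4)[1:3]
  path <- file.path(tempdir(), "events.csv")
  write_fcm_events(smp, path)
  back <- read_fcm_events(path)
  expect_length(back, 3)
  expect_equal(back[[2]]$events$fl1_h, smp[[2]]$events$fl1_h,
               tolerance = 1e-9)
  expect_equal(back[[1]]$dilution_factor, smp[[1]]$dilution_factor,
               tolerance = 1e-9)
})

test_that("FCS 3.1 files round-trip channel values at float precision", {
  smp <- simulate_fcm_timeseries(prof_clean, events_per_sample = 200,
                                 seed = 5)[[4]]
  dir <- file.path(tempdir(), "fcs_out")
  files <- write_fcm_events(smp, dir, format = "fcs")
  back <- read_fcm_events(files[[1]])
  expect_s3_class(back, "fcm_sample")
  expect_equal(back$events$fl1_h, smp$events$fl1_h, tolerance = 1e-6)
  expect_equal(back$events$fl3_h, smp$events$fl3_h, tolerance = 1e-6)
  expect_equal(back$time_h, smp$time_h)
})

test_that("missing channels are reported with the available ones", {
  path <- file.path(tempdir(), "nofl3.csv")
  utils::write.csv(data.frame(fl1_h = c(600, 700), fsc_h = c(1, 2)), path,
                   row.names = FALSE)
  err <- expect_error(suppressWarnings(read_fcm_events(path)), "FL3-H")
  expect_match(conditionMessage(err), "fsc_h")
})
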