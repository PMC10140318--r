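test_that("fatty-acid shorthand classifies saturation correctly", {
  expect_identical(classify_fatty_acids(c("C16:0", "C18:1", "C18:2")),
                   c("SFA", "UFA", "UFA"))
  expect_identical(classify_fatty_acids("C19:0 cyc"), "UFA")
  expect_identical(classify_fatty_acids("C19:0 cyc",
                                        cyclopropane_class = "SFA"), "SFA")
  expect_identical(
    classify_fatty_acids("weird", overrides = c(weird = "UFA")), "UFA")
  expect_error(classify_fatty_acids(c("C16:0", "X")), "X")
})

test_that("summaries reproduce hand-computed totals, SDs and ratios", {
  # single FA, single replicate: degenerate but well-defined
  ft1 <- fame_table("x", matrix(5, 1, 1, dimnames = list("C18:1", "r1")))
  s1 <- suppressWarnings(summarize_fames(ft1)) # no SFA present: ratio Inf
  expect_equal(s1$total_mean, 5)
  expect_equal(s1$total_sd, 0)
  expect_equal(s1$per_fa$rel_abundance_pct, 100)
  # two FAs, two replicates: means, sqrt-sum-of-variances, class sums
  v <- matrix(c(10, 14, 2, 4), 2, 2, byrow = TRUE,
              dimnames = list(c("C18:1", "C16:0"), c("r1", "r2")))
  s2 <- summarize_fames(fame_table("y", v))
  expect_equal(s2$per_fa$mean, c(12, 3))
  expect_equal(s2$total_mean, 15)
  expect_equal(s2$total_sd,
               sqrt(stats::sd(c(10, 14))^2 + stats::sd(c(2, 4))^2))
  expect_equal(s2$ufa_sum, 12)
  expect_equal(s2$sfa_sum, 3)
  expect_equal(s2$ufa_sfa_ratio, 4)
  # per-replicate abundance averages the within-replicate percentages
  expect_equal(s2$per_fa$rel_abundance_pct[1],
               mean(c(10 / 12, 14 / 18)) * 100)
  rom <- summarize_fames(fame_table("y", v), abundance_mode = "ratio_of_means")
  expect_equal(rom$per_fa$rel_abundance_pct[1], 80)
})

test_that("an all-zero SFA class reports an infinite ratio with warning", {
  v <- matrix(c(3, 0), 2, 1, dimnames = list(c("C18:1", "C16:0"), "r1"))
  expect_warning(s <- summarize_fames(fame_table("z", v)), "infinite")
  expect_identical(s$ufa_sfa_ratio, Inf)
})

test_that("summaries are scale-equivariant and ratio-monotone", {
  set.seed(31)
  v <- matrix(stats::runif(12, 1, 50), 4, 3,
              dimnames = list(c("C14:0", "C16:1", "C18:1", "C16:0"), NULL))
  s <- summarize_fames(fame_table("c", v))
  s_scaled <- summarize_fames(fame_table("c", v * 3))
  expect_equal(s_scaled$total_mean, 3 * s$total_mean)
  expect_equal(s_scaled$ufa_sum, 3 * s$ufa_sum)
  expect_equal(s_scaled$ufa_sfa_ratio, s$ufa_sfa_ratio, tolerance = 1e-12)
  expect_equal(s_scaled$per_fa$rel_abundance_pct, s$per_fa$rel_abundance_pct,
               tolerance = 1e-12)
  # raising any UFA replicate strictly raises the ratio
  v2 <- v
  v2["C18:1", 2] <- v2["C18:1", 2] + 5
  expect_gt(summarize_fames(fame_table("c", v2))$ufa_sfa_ratio,
            s$ufa_sfa_ratio)
})

test_that("propagated total SD matches the direct SD of replicate totals", {
  # with independent per-FA noise the two routes agree in expectation
  ft <- simulate_fame_table(c("C16:0" = 20, "C18:1" = 120, "C19:0 cyc" = 30),
                            cv = 0.1, n_replicates = 400, seed = 17)
  s <- summarize_fames(ft)
  direct <- stats::sd(colSums(ft$values))
  expect_equal(s$total_sd, direct, tolerance = 0.15)
})

test_that("simulated FAME tables honour cv = 0, seeding, and below-LOQ zeros", {
  means <- c("C16:0" = 20, "C18:0" = 0, "C18:1" = 120)
  exact <- simulate_fame_table(means, cv = 0, n_replicates = 3, seed = 1)
  expect_true(all(exact$values == matrix(means, 3, 3)))
  expect_true(all(exact$below_loq["C18:0", ]))
  a <- simulate_fame_table(means, cv = 0.1, n_replicates = 3, seed = 5)
  b <- simulate_fame_table(means, cv = 0.1, n_replicates = 3, seed = 5)
  expect_identical(a$values, b$values)
  expect_true(all(a$values >= 0))
  expect_true(all(a$values["C18:0", ] == 0)) # zero mean stays zero
  expect_error(simulate_fame_table(means, n_replicates = 1), "replicates")
})

test_that("condition comparison assembles the published-scale ratios", {
  sums <- reference_fame_summaries()
  tbl <- compare_lipid_conditions(sums)
  ratios <- tbl[tbl$item == "ufa_sfa_ratio", ]
  ratios <- ratios[match(c("air_sparged", "non_sparged", "n2_sparged"),
                         ratios$condition), ]
  expect_equal(ratios$mean, c(10.00, 3.20, 3.59), tolerance = 0.002)
  expect_error(compare_lipid_conditions(sums[1]), "at least 2")
  # identical summaries under two labels: zero between-condition differences
  twin <- sums[[1]]
  twin$condition <- "twin"
  same <- compare_lipid_conditions(list(sums[[1]], twin))
  wide <- split(same$mean, same$condition)
  expect_equal(wide[[1]], wide[[2]])
})

test_that("FAME tables round-trip through the long CSV format", {
  ft <- simulate_fame_table(c("C16:0" = 20, "C18:1" = 120), cv = 0.05,
                            n_replicates = 3, seed = 2, condition = "air")
  path <- file.path(tempdir(), "fames.csv")
  write_fame_table(ft, path)
  back <- read_fame_tables(path)[["air"]]
  expect_equal(back$values, ft$values, tolerance = 1e-9)
  expect_identical(unname(back$classes), unname(ft$classes))
})
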