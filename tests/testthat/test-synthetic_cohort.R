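test_that("moment matching reproduces a printed median/mean pair", {
  # acetic acid, control group: median 1124.0 ppb, arithmetic mean 1336.8
  d <- lognormal_from_summary(1124.0, 1336.8, "acetic_acid")
  expect_equal(d$log_mu, log(1124.0))
  expect_equal(d$log_sigma, sqrt(2 * log(1336.8 / 1124.0)))
  # Monte-Carlo verification of the closed form
  set.seed(1)
  draws <- rlnorm(1e6, d$log_mu, d$log_sigma)
  expect_lt(abs(median(draws) - 1124.0) / 1124.0, 0.02)
  expect_lt(abs(mean(draws) - 1336.8) / 1336.8, 0.02)
})

test_that("moment recovery holds across table-parameterized distributions", {
  rows <- rbind(
    cbind(compound_summary_table("control")[c(2, 4, 10), ], n = 45),
    cbind(compound_summary_table("lung_sqcc")[c(1, 6), ], n = 25))
  set.seed(42)
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    d <- lognormal_from_summary(r$median, r$mean, r$compound)
    draws <- rlnorm(1e6, d$log_mu, d$log_sigma)
    expect_lt(abs(median(draws) - r$median) / r$median, 0.02)
    expect_lt(abs(mean(draws) - r$mean) / r$mean, 0.02)
  }
})

test_that("degenerate and forbidden summary pairs are handled", {
  d <- lognormal_from_summary(10, 10, "flat")
  expect_identical(d$log_sigma, 0)
  set.seed(1)
  draws <- rlnorm(50, d$log_mu, d$log_sigma)
  expect_length(unique(draws), 1)
  expect_equal(draws[1], 10)
  expect_error(lognormal_from_summary(10, 5, "impossible"), "impossible")
  expect_error(lognormal_from_summary(10, 5, "impossible"),
               "mean.*below the median")
})

test_that("range-based fallback keeps the median and yields a sane scale", {
  # N2O controls: printed mean sits below the median, so the scale comes
  # from the printed range instead
  d <- lognormal_from_range(6438.0, 2323.5, 11934.3, 45, "N2O")
  expect_equal(exp(d$log_mu), 6438.0)
  expect_gt(d$log_sigma, 0.1)
  expect_lt(d$log_sigma, 1)
})

test_that("the four-group default cohort has the published structure", {
  spec <- default_cohort_spec("all", seed = 7)
  expect_equal(sum(spec$group_sizes), 158)
  expect_equal(unname(spec$group_sizes[c("control", "lung_adk",
                                         "lung_sqcc", "colon_adk")]),
               c(45L, 36L, 25L, 52L))
  co <- generate_cohort(spec)
  expect_equal(nrow(co), 158)
  expect_equal(length(cohort_compounds(co)), 95)
  expect_true(all(as.matrix(co[, grep("^(alv|env)_", names(co))]) >= 0))
  expect_true(all(co$sex %in% c(0L, 1L)))
  # ages inside the printed group ranges
  ctrl <- co[co$group == "control", ]
  expect_true(all(ctrl$age >= 43 & ctrl$age <= 87))
})

test_that("generation is deterministic given the seed", {
  spec <- default_cohort_spec("lung_sqcc", seed = 3)
  expect_identical(generate_cohort(spec), generate_cohort(spec))
  co2 <- generate_cohort(spec, seed = 4)
  expect_false(identical(generate_cohort(spec), co2))
})

test_that("CO2 draws respect the configured failure fraction", {
  spec0 <- default_cohort_spec("lung_adk", qc_fail_fraction = 0, seed = 5)
  expect_true(all(generate_cohort(spec0)$co2_percent >= 2))
  spec5 <- default_cohort_spec("lung_adk", qc_fail_fraction = 0.5, seed = 5)
  frac <- mean(generate_cohort(spec5)$co2_percent < 2)
  expect_gt(frac, 0.35)
  expect_lt(frac, 0.65)
  spec1 <- default_cohort_spec("lung_adk", qc_fail_fraction = 1, seed = 5)
  expect_true(all(generate_cohort(spec1)$co2_percent < 2))
})

test_that("default specs encode the printed case/control contrasts", {
  spec <- default_cohort_spec("lung_adk")
  d <- spec$distributions
  mu <- function(g, cmp) d$log_mu[d$group == g & d$compound == cmp]
  expect_equal(mu("control", "pentane"), log(64.3))
  expect_equal(mu("lung_adk", "pentane"), log(78.8))
  speck <- default_cohort_spec("colon_adk")
  dk <- speck$distributions
  muk <- function(g, cmp) dk$log_mu[dk$group == g & dk$compound == cmp]
  expect_equal(muk("control", "N2O"), log(6438.0))
  expect_equal(muk("colon_adk", "N2O"), log(7306.1))
  # null compounds: identical distribution in both groups
  ctrl <- d[d$group == "control" & d$compound == "acetone", ]
  case <- d[d$group == "lung_adk" & d$compound == "acetone", ]
  expect_equal(ctrl$log_mu, case$log_mu)
  expect_equal(ctrl$log_sigma, case$log_sigma)
})

test_that("invalid specifications are rejected", {
  spec <- default_cohort_spec("lung_adk")
  bad <- spec
  bad$distributions <- bad$distributions[-1, ]  # breaks panel consistency
  expect_error(validate_cohort_spec(bad), "same compound panel")
  bad2 <- spec
  bad2$qc_fail_fraction <- 1.5
  expect_error(validate_cohort_spec(bad2), "qc_fail_fraction")
  expect_error(new_compound_distribution("x", 1, -0.1, 1), "log_sigma")
  expect_error(new_compound_distribution("x", 1, 0.1, 0), "env_factor")
  expect_error(default_cohort_spec("pancreas"))
})
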