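make_mini_cohort <- function(alv, env, co2 = NULL, group = NULL) {
  n <- nrow(alv)
  if (is.null(co2)) co2 <- rep(4, n)
  if (is.null(group)) group <- rep(c("control", "lung_adk"), length.out = n)
  colnames(alv) <- paste0("alv_", colnames(alv))
  colnames(env) <- paste0("env_", colnames(env))
  df <- data.frame(subject_id = sprintf("s%02d", seq_len(n)),
                   group = group, age = 60, sex = 0L,
                   co2_percent = co2, alv, env,
                   stringsAsFactors = FALSE)
  class(df) <- c("breath_cohort", "data.frame")
  df
}

test_that("the CO2 filter discards strictly-below-threshold samples", {
  x <- matrix(1, 4, 1, dimnames = list(NULL, "a"))
  co <- make_mini_cohort(x, x, co2 = c(1.9, 2.0, 4.5, NA))
  res <- suppressMessages(filter_co2(co))
  expect_equal(res$retained$subject_id, c("s02", "s03"))
  expect_equal(res$discarded$reason, c("low_co2", "missing_co2"))
  # boundary: exactly 2.0 is retained ("lower than" is strict)
  expect_true("s02" %in% res$retained$subject_id)
  all_good <- filter_co2(make_mini_cohort(x, x, co2 = c(2, 3, 4, 5)))
  expect_equal(nrow(all_good$discarded), 0)
})

test_that("environmental exclusion is one-directional and paired", {
  set.seed(11)
  n <- 60
  alv <- cbind(same = rep(5, n),                  # env identical
               breath_high = rlnorm(n, 3, 0.4),   # alveolar >> env
               contaminated = rlnorm(n, 1, 0.3))  # env >> alveolar
  env <- cbind(same = rep(5, n),
               breath_high = rlnorm(n, 1, 0.4),
               contaminated = rlnorm(n, 3, 0.3))
  co <- make_mini_cohort(alv, env)
  res <- environmental_exclusion(co)
  tests <- res$tests
  expect_equal(res$excluded_compounds, "contaminated")
  expect_setequal(res$retained_compounds, c("same", "breath_high"))
  # identical vectors: zero statistic, retained
  expect_equal(tests$statistic[tests$compound == "same"], 0)
  # breath_high is significant but in the protected direction
  expect_lt(tests$p_value[tests$compound == "breath_high"], 0.001)
  expect_false(tests$excluded[tests$compound == "breath_high"])
})

test_that("the paired t-test p-value agrees with a sign-flip permutation", {
  set.seed(21)
  n <- 100
  alv <- cbind(m1 = rnorm(n, 10, 1))
  env <- cbind(m1 = alv[, 1] + rnorm(n, 0.2, 1))  # moderate positive excess
  co <- make_mini_cohort(alv, env)
  res <- environmental_exclusion(co)
  p_t <- res$tests$p_value
  p_perm <- perm_paired_p(env[, 1] - alv[, 1], B = 10000, seed = 3)
  expect_lt(abs(p_t - p_perm), 0.02)
})

test_that("default cohort QC retains 84 of 95 compounds", {
  co <- generate_cohort(default_cohort_spec("all", seed = 2))
  qc <- qc_cohort(co)
  expect_equal(length(qc$retained_compounds), 84)
  expect_equal(length(qc$excluded_compounds), 11)
  expect_length(intersect(qc$retained_compounds, qc$excluded_compounds), 0)
})

test_that("QC partitions samples and compounds on random inputs", {
  for (seed in 1:3) {
    spec <- default_cohort_spec("lung_sqcc", qc_fail_fraction = 0.3,
                                seed = seed)
    co <- generate_cohort(spec)
    qc <- qc_cohort(co)
    expect_equal(nrow(qc$retained) + nrow(qc$discarded_samples), nrow(co))
    expect_length(intersect(qc$retained$subject_id,
                            qc$discarded_samples$subject_id), 0)
    expect_equal(sort(c(qc$retained_compounds, qc$excluded_compounds)),
                 sort(cohort_compounds(co)))
  }
})

test_that("too few paired observations retains the compound with a warning", {
  x <- matrix(rnorm(2), 2, 1, dimnames = list(NULL, "tiny"))
  co <- make_mini_cohort(x, x + 5)
  expect_warning(res <- environmental_exclusion(co), "fewer than 3")
  expect_equal(res$retained_compounds, "tiny")
})

test_that("standardization centers, scales and round-trips", {
  x <- cbind(a = c(1, 2, 3), b = c(2, 4, 9))
  s <- standardize_columns(x)
  expect_equal(unname(s$x[, "a"]), c(-1, 0, 1))
  expect_equal(unname(s$center), c(2, 5))
  expect_equal(unname(s$scale[1]), 1)
  # stored params re-applied to the same data give the same matrix
  expect_equal(apply_standardization(x, s), s$x, ignore_attr = TRUE)
  # round-trip
  expect_equal(destandardize(s$x, s), x, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(standardize_columns(cbind(a = c(1, 1, 1), b = 1:3)), "a")
})

test_that("standardized-scale coefficients back-transform to the raw fit", {
  set.seed(5)
  n <- 120
  x <- cbind(u = rnorm(n, 50, 10), v = rnorm(n, 5, 2))
  y <- rbinom(n, 1, plogis(0.05 * (x[, 1] - 50)))
  s <- standardize_columns(x)
  fit <- penalized_logistic(s$x, y, lambda = 0)
  back <- original_scale_coefficients(fit, s)
  raw <- glm(y ~ x, family = binomial)   # oracle: unpenalized ML, raw scale
  expect_equal(unname(back$coefficients), unname(coef(raw)[-1]),
               tolerance = 1e-6)
  expect_equal(back$intercept, unname(coef(raw)[1]), tolerance = 1e-6)
})
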