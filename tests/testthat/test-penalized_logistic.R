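test_that("lambda = 0 reproduces the unpenalized maximum-likelihood fit", {
  inst <- random_instance(101, n = 60, p = 4)
  fit <- penalized_logistic(inst$x, inst$y, lambda = 0)
  ml <- glm(inst$y ~ inst$x, family = binomial)
  expect_lt(max(abs(coef(fit) - coef(ml))), 1e-6)
  expect_true(fit$converged)
})

test_that("penalties at or above lambda_max give the null model exactly", {
  for (seed in c(7, 8, 9)) {
    inst <- random_instance(seed)
    lmax <- lambda_max(inst$x, inst$y)
    for (lam in c(lmax, 2 * lmax)) {
      fit <- penalized_logistic(inst$x, inst$y, lam)
      expect_true(all(fit$coefficients == 0))
      expect_equal(fit$intercept, qlogis(mean(inst$y)), tolerance = 1e-8)
    }
    # just below lambda_max the null model is no longer stationary
    fit2 <- penalized_logistic(inst$x, inst$y, 0.95 * lmax)
    expect_gt(sum(fit2$coefficients != 0), 0)
  }
})

test_that("lambda_max matches a dense grid search and scales with weights", {
  inst <- random_instance(55, n = 40, p = 3)
  w <- c(1, 2, 0.5)
  lmax <- lambda_max(inst$x, inst$y, w)
  # oracle: smallest all-zero lambda located by bisection-free dense grid
  grid <- lmax * seq(0.9, 1.1, length.out = 41)
  allzero <- vapply(grid, function(l) {
    all(penalized_logistic(inst$x, inst$y, l, w)$coefficients == 0)
  }, logical(1))
  first <- grid[which(allzero)[1]]
  expect_lt(abs(first - lmax) / lmax, 0.01)
  # doubling all weights halves lambda_max
  expect_equal(lambda_max(inst$x, inst$y, 2 * w), lmax / 2)
  # a duplicated column never decreases lambda_max
  x2 <- cbind(inst$x, dup = inst$x[, 1])
  expect_gte(lambda_max(x2, inst$y, rep(1, 4)),
             lambda_max(inst$x, inst$y, rep(1, 3)))
  expect_error(lambda_max(inst$x, inst$y, rep(Inf, 3)), "infinite")
})

test_that("infinite penalty weight excludes a variable exactly", {
  inst <- random_instance(3, n = 40, p = 2)
  lam <- 0.3 * lambda_max(inst$x, inst$y)
  fit <- penalized_logistic(inst$x, inst$y, lam, weights = c(1, Inf))
  expect_identical(unname(fit$coefficients[2]), 0)
  solo <- penalized_logistic(inst$x[, 1, drop = FALSE], inst$y, lam)
  expect_equal(unname(fit$coefficients[1]), unname(solo$coefficients[1]),
               tolerance = 1e-7)
  expect_equal(fit$intercept, solo$intercept, tolerance = 1e-7)
})

test_that("objective value matches a proximal-gradient oracle", {
  for (seed in 1:50) {
    inst <- random_instance(seed)
    set.seed(seed + 500)
    w <- runif(ncol(inst$x), 0.5, 2)
    if (seed %% 7 == 0) w[1] <- Inf
    lam <- runif(1, 0.1, 0.8) * lambda_max(inst$x, inst$y, w)
    fit <- penalized_logistic(inst$x, inst$y, lam, w)
    ours <- penalized_objective(inst$x, inst$y, fit$intercept,
                                fit$coefficients, lam, w)
    orc <- oracle_weighted_l1(inst$x, inst$y, lam, w)
    expect_lt(abs(ours - orc$objective), 1e-6)
    expect_lt(check_kkt(fit, inst$x, inst$y), 1e-6)
  }
})

test_that("KKT conditions hold and sparsity shrinks along a penalty path", {
  set.seed(77)
  n <- 60; p <- 8
  x <- scale(matrix(rnorm(n * p), n, p))
  colnames(x) <- paste0("v", 1:p)
  y <- rbinom(n, 1, plogis(x[, 1] - 0.8 * x[, 2]))
  lmax <- lambda_max(x, y)
  grid <- exp(seq(log(lmax), log(lmax * 1e-3), length.out = 30))
  nnz <- integer(30)
  for (k in seq_along(grid)) {
    fit <- penalized_logistic(x, y, grid[k])
    expect_lt(check_kkt(fit, x, y), 1e-6)
    nnz[k] <- sum(fit$coefficients != 0)
  }
  # descending lambda: model size never shrinks (ties allowed)
  expect_true(all(diff(nnz) >= 0))
  expect_equal(nnz[1], 0)
})

test_that("the solver agrees with glmnet on a shared instance", {
  skip_if_not_installed("glmnet")
  inst <- random_instance(12, n = 50, p = 5)
  n <- nrow(inst$x)
  lam <- 0.25 * lambda_max(inst$x, inst$y)
  fit <- penalized_logistic(inst$x, inst$y, lam)
  # glmnet minimizes the mean-scaled objective; lambda converts by 1/n
  g <- glmnet::glmnet(inst$x, inst$y, family = "binomial",
                      lambda = lam / n, standardize = FALSE,
                      thresh = 1e-14)
  expect_equal(unname(fit$coefficients),
               unname(as.numeric(g$beta)), tolerance = 1e-5)
  expect_equal(fit$intercept, unname(g$a0), tolerance = 1e-5)
})

test_that("predicted probabilities follow the logistic formula", {
  fit <- structure(list(intercept = 0,
                        coefficients = c(a = 0, b = 0),
                        lambda = 1, penalty_weights = c(a = 1, b = 1),
                        converged = TRUE, capped = FALSE,
                        n_iterations = 0L),
                   class = "penalized_fit")
  expect_equal(unname(predict(fit, c(a = 3, b = -2))), 0.5)
  fit$coefficients <- c(a = 1.2, b = -0.4)
  p1 <- predict(fit, c(a = 1, b = 1))
  p2 <- predict(fit, c(a = 2, b = 1))  # increase a positive-coef variable
  expect_gt(p2, p1)
  expect_equal(unname(p1), plogis(1.2 - 0.4))
})

test_that("published model coefficients give a probability inside (0,1)", {
  # lung-adenocarcinoma model, coefficients as printed (raw ppb scale),
  # evaluated at the printed control medians with age 66
  coefs <- c(age = -0.0002355, acetic_acid = 0.0018644,
             ammonia = -0.0007868, M43 = -0.0009794,
             acetaldehyde = -0.0003237, M48 = 0.0179830,
             M62 = 0.0851835, M67 = -0.0833412, pentane = 0.0285685,
             M93 = -0.0418881, M98 = -0.0065165, M103 = 0.0161747)
  medians <- c(age = 66, acetic_acid = 1124.0, ammonia = 160.6,
               M43 = 1193.0, acetaldehyde = 818.0, M48 = 6.8, M62 = 8.7,
               M67 = 34.4, pentane = 64.3, M93 = 31.9, M98 = 58.4,
               M103 = 4.2)
  fit <- structure(list(intercept = 0.0307786, coefficients = coefs,
                        lambda = NA, penalty_weights = coefs * 0 + 1,
                        converged = TRUE, capped = FALSE,
                        n_iterations = 0L),
                   class = "penalized_fit")
  p <- unname(predict(fit, medians))
  # independent hand evaluation of the logistic formula
  expect_equal(p, 1 / (1 + exp(-(0.0307786 + sum(coefs * medians)))))
  expect_gt(p, 0)
  expect_lt(p, 1)
})

test_that("separable data triggers the coefficient cap with a warning", {
  x <- matrix(c(rep(-1, 10), rep(1, 10)), ncol = 1,
              dimnames = list(NULL, "s"))
  y <- c(rep(0, 10), rep(1, 10))
  expect_warning(
    fit <- penalized_logistic(scale(x), y, lambda = 0, beta_cap = 5),
    "separable")
  expect_true(fit$capped)
  expect_equal(abs(unname(fit$coefficients)), 5, tolerance = 1e-6)
})

test_that("input validation rejects malformed problems", {
  inst <- random_instance(1, n = 20, p = 2)
  expect_error(penalized_logistic(inst$x, inst$y[-1], 1), "length")
  expect_error(penalized_logistic(inst$x, inst$y + 0.5, 1), "binary")
  expect_error(penalized_logistic(inst$x, inst$y, -1), "lambda")
  expect_error(penalized_logistic(inst$x, inst$y, 1, weights = c(-1, 1)),
               "non-negative")
})
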