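# OLS and coordinate-descent elastic net: closed-form oracles, limits,
# objective monotonicity, split evaluation, under-tuned demo.

test_that("OLS recovers exact linear relations", {
  x <- matrix(seq(0, 1, length.out = 20), ncol = 1)
  f <- fit_ols(x, 2 * x[, 1] + 1)
  expect_equal(unname(f$weights), 2, tolerance = 1e-10)
  expect_equal(f$intercept, 1, tolerance = 1e-10)

  fc <- fit_ols(matrix(rnorm(30), ncol = 1), rep(3.5, 30))
  expect_equal(unname(fc$weights), 0, tolerance = 1e-10)
  expect_equal(fc$intercept, 3.5, tolerance = 1e-10)
})

test_that("OLS matches the normal-equations oracle on a random design", {
  set.seed(31)
  X <- matrix(rnorm(150), 50, 3)
  y <- drop(X %*% c(1, -2, 0.5)) + rnorm(50, 0, 0.3)
  f <- fit_ols(X, y)
  # oracle: pseudo-inverse solution of the augmented system
  A <- cbind(1, X)
  oracle <- solve(crossprod(A), crossprod(A, y))
  expect_equal(unname(c(f$intercept, f$weights)), drop(oracle), tolerance = 1e-8)
})

test_that("OLS refuses rank-deficient and underdetermined designs", {
  set.seed(5)
  X <- matrix(rnorm(40), 20, 2)
  X <- cbind(X, dup = 0.5 * X[, 1])
  colnames(X) <- c("a", "b", "dup")
  expect_error(fit_ols(X, rnorm(20)), "dup")
  expect_error(fit_ols(matrix(rnorm(12), 3, 4), rnorm(3)), "elastic net")
})

test_that("full shrinkage drives all weights to zero", {
  set.seed(6)
  X <- matrix(rnorm(100), 25, 4)
  y <- rnorm(25, 50, 10)
  f <- fit_elastic_net(X, y, en_config(alpha = 1e6, l1_ratio = 1))
  expect_true(all(f$weights == 0))
  expect_equal(f$intercept, mean(y), tolerance = 1e-10)
})

test_that("alpha -> 0 recovers OLS", {
  set.seed(7)
  X <- matrix(rnorm(200), 50, 4)
  y <- drop(X %*% c(2, -1, 0.5, 3)) + rnorm(50, 0, 0.5)
  f_en <- fit_elastic_net(X, y, en_config(alpha = 0, tol = 1e-10))
  f_ols <- fit_ols(X, y)
  expect_equal(f_en$weights, f_ols$weights, tolerance = 1e-6)
  expect_equal(f_en$intercept, f_ols$intercept, tolerance = 1e-6)
})

test_that("univariate fit matches the soft-threshold closed form", {
  set.seed(8)
  n <- 40
  x <- rnorm(n)
  x <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))  # standardized, population SD
  y <- 2 * x + rnorm(n, 0, 0.2)
  yc <- y - mean(y)
  for (alpha in c(0.1, 0.5, 1.5)) {
    for (l1 in c(0.2, 0.8, 1)) {
      f <- fit_elastic_net(matrix(x), y, en_config(alpha = alpha, l1_ratio = l1,
                                                   tol = 1e-12))
      z <- mean(x * yc)
      expected <- sign(z) * max(abs(z) - alpha * l1, 0) / (1 + alpha * (1 - l1))
      expect_equal(unname(f$weights), expected, tolerance = 1e-8)
    }
  }
})

test_that("l1_ratio = 0 equals the ridge closed form on standardized data", {
  set.seed(9)
  n <- 60
  X <- matrix(rnorm(n * 3), n, 3)
  X <- sweep(X, 2, colMeans(X))
  X <- sweep(X, 2, sqrt(colMeans(X^2)), "/")
  y <- drop(X %*% c(1, 2, -1)) + rnorm(n, 0, 0.3)
  alpha <- 0.7
  f <- fit_elastic_net(X, y, en_config(alpha = alpha, l1_ratio = 0, tol = 1e-12))
  yc <- y - mean(y)
  oracle <- solve(crossprod(X) + n * alpha * diag(3), crossprod(X, yc))
  expect_equal(unname(f$weights), drop(oracle), tolerance = 1e-6)
})

test_that("objective is non-increasing across coordinate-descent sweeps", {
  set.seed(10)
  X <- matrix(rnorm(600), 100, 6)
  X[, 6] <- X[, 1] + rnorm(100, 0, 0.01)   # near-collinear pair
  y <- drop(X %*% c(3, 0, -2, 0, 1, 3)) + rnorm(100)
  for (cfg in list(en_config(alpha = 0.05, l1_ratio = 0.8),
                   en_config(alpha = 1, l1_ratio = 0.2),
                   en_config(alpha = 0, l1_ratio = 1))) {
    f <- suppressWarnings(fit_elastic_net(X, y, cfg))
    expect_true(all(diff(f$objective) <= 1e-10))
  }
})

test_that("selected-feature count is non-increasing in alpha", {
  set.seed(11)
  X <- matrix(rnorm(500), 100, 5)
  y <- drop(X %*% c(2, -1, 0.5, 0.2, 0)) + rnorm(100, 0, 0.5)
  ns <- sapply(c(0.001, 0.01, 0.1, 0.5, 2, 10), function(a) {
    fit_elastic_net(X, y, en_config(alpha = a, l1_ratio = 0.8))$n_selected
  })
  expect_true(all(diff(ns) <= 0))
})

test_that("non-convergence is flagged, not hidden", {
  set.seed(12)
  X <- matrix(rnorm(300), 50, 6)
  y <- rnorm(50)
  expect_warning(f <- fit_elastic_net(X, y, en_config(alpha = 0, tol = 1e-14,
                                                      max_iter = 2L)),
                 "converge")
  expect_false(f$converged)
})

test_that("repeated splits are sized, deterministic and error-checked", {
  set.seed(13)
  X <- matrix(runif(100 * 3), 100, 3)
  y <- drop(X %*% c(10, 5, -2)) + rnorm(100, 0, 0.1)
  ev <- repeated_split_eval(X, y, fit_ols, n_repeats = 5, test_fraction = 0.2,
                            seed = 77)
  expect_equal(ev$per_repeat$n_test, rep(20L, 5L), ignore_attr = TRUE)
  ev2 <- repeated_split_eval(X, y, fit_ols, n_repeats = 5, test_fraction = 0.2,
                             seed = 77)
  expect_identical(ev$splits, ev2$splits)
  expect_equal(ev$per_repeat$mae, ev2$per_repeat$mae)
  expect_error(repeated_split_eval(X, y, fit_ols, test_fraction = 0.005),
               "< 2 samples")

  # perfect linear data: pooled MAE 0, training residuals centered at 0
  yp <- drop(X %*% c(1, 2, 3)) + 4
  evp <- repeated_split_eval(X, yp, fit_ols, n_repeats = 3, seed = 1)
  expect_lt(evp$pooled$mae, 1e-8)
})

test_that("OLS training residuals have mean zero within tolerance", {
  set.seed(14)
  X <- matrix(rnorm(240), 80, 3)
  y <- drop(X %*% c(1, -1, 2)) + rnorm(80)
  f <- fit_ols(X, y)
  resid <- y - predict(f, X)
  expect_lt(abs(mean(resid)), 1e-10)
})

test_that("under-tuned EN zeroes collinear CpGs; OLS recovers the slope", {
  # exact-collinear block: pure-lasso under-tuned preset zeroes the
  # redundant half-CpG while OLS refuses the rank-deficient design
  co <- generate_cohort(cohort_spec(500, seed = 11,
                                    n_cpgs_by_archetype = c(age_linear = 2,
                                                            collinear = 1,
                                                            normal = 1,
                                                            uniform = 1)))
  d <- under_tuned_en_demo(co, seed = 2)
  expect_gte(length(d$zeroed_collinear), 1L)
  expect_null(d$ols_fit)
  expect_match(d$ols_error, "rank deficient")

  # shrinkage underpredicts the older half of the test samples
  old <- d$test_predictions[d$test_predictions$age > mean(co$metadata$age), ]
  expect_lt(mean(old$en_pred), mean(old$age))

  # noisy-collinear variant: OLS runs, and the univariate generative slope
  # 0.008/year is recovered within 3 standard errors
  con <- generate_cohort(cohort_spec(500, seed = 11, collinear_mode = "noisy",
                                     n_cpgs_by_archetype = c(age_linear = 2,
                                                             collinear = 1,
                                                             normal = 1,
                                                             uniform = 1)))
  dn <- under_tuned_en_demo(con, seed = 2)
  expect_s3_class(dn$ols_fit, "fit_result")
  age <- con$metadata$age
  b1 <- unclass(con$beta)[, "cg_age0001"]
  f <- fit_ols(matrix(age, ncol = 1), b1)
  res <- b1 - predict(f, matrix(age, ncol = 1))
  se <- sqrt(sum(res^2) / (length(age) - 2)) / sqrt(sum((age - mean(age))^2))
  expect_lt(abs(unname(f$weights) - 0.008), 3 * se)
})
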