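test_that("unit deviance is zero at the mean, positive elsewhere, with the gamma limit", {
  for (p in c(1.2, 1.5, 1.9, 2)) {
    expect_equal(tweedie_unit_deviance(1, 1, p), 0)
    expect_equal(tweedie_unit_deviance(3.7, 3.7, p), 0, tolerance = 1e-12)
  }
  # p = 2 closed form at y = 2, mu = 1: 2*(1 - log 2)
  expect_equal(tweedie_unit_deviance(2, 1, 2), 2 * (1 - log(2)))
  # the p -> 2 limit of the general expression approaches the gamma deviance
  expect_equal(tweedie_unit_deviance(2, 1, 2 - 1e-8),
               2 * (1 - log(2)), tolerance = 1e-6)
  set.seed(2)
  y <- rexp(50) + 0.1; mu <- rexp(50) + 0.1
  for (p in c(1.3, 1.7, 2)) {
    d <- tweedie_unit_deviance(y, mu, p)
    expect_true(all(d[abs(y - mu) > 1e-12] > 0))
  }
  expect_error(tweedie_unit_deviance(1, 1, 2.5), "power")
  expect_error(tweedie_unit_deviance(1, 1, 1), "power")
  # y = 0 admissible strictly inside (1, 2) but not at the gamma limit
  expect_gt(tweedie_unit_deviance(0, 1, 1.5), 0)
  expect_error(tweedie_unit_deviance(0, 1, 2), "strictly positive")
})

test_that("IRLS at p = 2 matches an independent gamma GLM to 1e-6", {
  set.seed(42)
  x <- cbind(T = rnorm(30), P = rnorm(30))
  mu <- exp(0.3 + 0.7 * x[, 1] - 0.4 * x[, 2])
  y <- rgamma(30, shape = 5, rate = 5 / mu)
  td <- fit_tdr(x, y, p = 2)
  g <- stats::glm(y ~ x, family = Gamma(link = "log"),
                  control = stats::glm.control(epsilon = 1e-12))
  expect_lt(max(abs(td$coefficients - unname(coef(g)))), 1e-6)
  expect_true(td$converged)
})

test_that("noiseless log-linear data is recovered exactly", {
  set.seed(7)
  x <- cbind(T = runif(25, -1.5, 1.5), P = runif(25, -1.5, 1.5))
  y <- exp(-9 + 0.9 * x[, "T"] + 0.2 * x[, "P"])
  for (p in c(1.4, 2)) {
    td <- fit_tdr(x, y, p = p)
    expect_equal(unname(td$coefficients), c(-9, 0.9, 0.2), tolerance = 1e-8)
  }
})

test_that("all-equal targets give an intercept-only fit at that constant", {
  set.seed(9)
  x <- cbind(rnorm(12), rnorm(12))
  td <- fit_tdr(x, rep(3e-4, 12), p = 1.5)
  expect_equal(unname(td$coefficients), c(log(3e-4), 0, 0), tolerance = 1e-10)
  expect_equal(unname(td$fitted), rep(3e-4, 12), tolerance = 1e-10)
})

test_that("predictions are positive, exp(intercept) at the origin, monotone in T", {
  set.seed(11)
  x <- cbind(T = rnorm(20), P = rnorm(20))
  y <- exp(-8 + 0.5 * x[, 1]) * exp(rnorm(20, 0, 0.2))
  td <- fit_tdr(x, y, p = 1.6)
  expect_equal(predict(td, cbind(0, 0)), exp(td$coefficients[1]),
               ignore_attr = TRUE)
  q <- cbind(runif(50, -3, 3), runif(50, -3, 3))
  expect_true(all(predict(td, q) > 0))
  expect_gt(td$coefficients[2], 0)
  tq <- cbind(seq(-2, 2, length.out = 20), 0)
  expect_true(all(diff(predict(td, tq)) > 0))
})

test_that("Pearson residuals center at zero at convergence", {
  set.seed(15)
  x <- cbind(T = rnorm(40), P = rnorm(40))
  mu <- exp(-2 + 0.6 * x[, 1] + 0.3 * x[, 2])
  y <- rgamma(40, shape = 8, rate = 8 / mu)
  td2 <- fit_tdr(x, y, p = 2)
  pearson2 <- (y - td2$fitted) / sqrt(td2$fitted^2)
  expect_lt(abs(mean(pearson2)), 1e-9)  # exact score identity at p = 2
  td15 <- fit_tdr(x, y, p = 1.5)
  pearson15 <- (y - td15$fitted) / sqrt(td15$fitted^1.5)
  expect_lt(abs(mean(pearson15)), 0.1 * sd(pearson15))
})

test_that("invalid inputs and divergence are reported", {
  x <- cbind(rnorm(10), rnorm(10))
  expect_error(fit_tdr(x, rep(0, 10), p = 1.5), "two positive")
  expect_error(fit_tdr(x, c(rep(1, 9), 0), p = 2), "strictly positive")
  expect_error(fit_tdr(x, abs(rnorm(10)) + 0.1, p = 2.4), "power")
})

test_that("fitting is invariant to the order of training rows", {
  set.seed(19)
  x <- cbind(rnorm(20), rnorm(20))
  y <- exp(-1 + 0.4 * x[, 1]) * exp(rnorm(20, 0, 0.1))
  perm <- sample(20)
  a <- fit_tdr(x, y, p = 1.7)
  b <- fit_tdr(x[perm, ], y[perm], p = 1.7)
  expect_equal(a$coefficients, b$coefficients, tolerance = 1e-9)
})
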