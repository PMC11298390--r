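test_that("metrics match hand arithmetic and satisfy their identities", {
  m <- compute_metrics(c(1, 2, 3), c(1, 2, 5), k = 2)
  expect_equal(m$mse, 4 / 3)
  expect_equal(m$mae, 2 / 3)
  expect_equal(m$r2, -1)
  expect_equal(m$aic, 3 * log(4 / 3) + 4)

  perfect <- compute_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$mse, 0)
  expect_equal(perfect$mae, 0)

  at_mean <- compute_metrics(c(1, 2, 3), rep(2, 3))
  expect_equal(at_mean$r2, 0)

  expect_warning(z <- compute_metrics(rep(2, 4), 1:4), "zero variance")
  expect_true(is.na(z$r2))
  expect_equal(z$mse, mean((rep(2, 4) - 1:4)^2))
})

test_that("metrics agree with an independent brute-force reimplementation", {
  set.seed(123)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    obs <- rnorm(n); pred <- obs + rnorm(n, 0, 0.5)
    m <- compute_metrics(obs, pred)
    # independent arithmetic: explicit loops over the defining sums
    sse <- 0; sae <- 0; sst <- 0; ybar <- sum(obs) / n
    for (j in seq_len(n)) {
      sse <- sse + (obs[j] - pred[j])^2
      sae <- sae + abs(obs[j] - pred[j])
      sst <- sst + (obs[j] - ybar)^2
    }
    expect_equal(m$mse, sse / n, tolerance = 1e-12)
    expect_equal(m$mae, sae / n, tolerance = 1e-12)
    expect_equal(m$r2, 1 - sse / sst, tolerance = 1e-12)
    expect_equal(m$rmse, sqrt(m$mse), tolerance = 1e-12)
    expect_lte(m$mae, m$rmse + 1e-12)
  }
})

test_that("AIC prefers the smaller model at equal error", {
  a <- compute_metrics(1:10, 1:10 + 0.1, k = 3)
  b <- compute_metrics(1:10, 1:10 + 0.1, k = 12)
  expect_lt(a$aic, b$aic)
})

test_that("the CV objective penalizes failures and rewards dominance", {
  ds <- noiseless_fixture()
  df <- as.data.frame(ds)[1:12, ]
  folds <- scfsol:::make_cv_folds(nrow(df), 4, seed = 1)
  obj_ppr <- make_objective("PPR", df, folds)
  # cubic segments need 10 points; 9-point training folds cannot fit one
  expect_equal(obj_ppr(list(degree = 3, max_segments = 1, penalty_weight = 0)),
               Inf)
  obj <- make_objective("KRR", as.data.frame(ds),
                        scfsol:::make_cv_folds(28, 5, seed = 2))
  good <- obj(list(lambda = 1e-6, gamma = 0.5))
  bad <- obj(list(lambda = 1, gamma = 100))
  expect_true(is.finite(good))
  expect_lt(good, bad)
})

test_that("KRR cross-validated error falls with lambda on clean smooth data", {
  ds <- noiseless_fixture()
  obj <- make_objective("KRR", as.data.frame(ds),
                        scfsol:::make_cv_folds(28, 5, seed = 3))
  costs <- vapply(c(1, 1e-2, 1e-4, 1e-6), function(l) {
    obj(list(lambda = l, gamma = 0.5))
  }, 0)
  expect_true(all(diff(costs) < 0))
})

test_that("tuning a noiseless surface reaches test R^2 >= 0.99 for every family", {
  ds <- noiseless_fixture()
  cfg <- fast_config(seed = 2)
  split <- split_dataset(ds, 0.2, seed = 2)
  for (fam in c("PPR", "KRR", "TDR")) {
    tr <- tune_model(fam, ds, split, cfg, wca_seed = 11, cv_seed = 12)
    expect_gte(tr$test_metrics$r2, 0.99)
    expect_true(all(diff(tr$wca_history) <= 0))
  }
})

test_that("the pipeline is reproducible and its table is ordered by test R^2", {
  ds <- load_dataset("bundled")
  cfg <- fast_config(seed = 5)
  a <- run_pipeline(ds, cfg, split_seed = 4)
  b <- run_pipeline(ds, cfg, split_seed = 4)
  expect_identical(a$comparison, b$comparison)
  expect_equal(nrow(a$comparison), 3)
  expect_setequal(a$comparison$family, c("PPR", "KRR", "TDR"))
  expect_true(all(diff(a$comparison$r2) <= 0))
  expect_error(run_pipeline(ds[1:10, ], cfg), "at least 15")
})

test_that("trend slices: exact exponential in T and exact linear in P on the
           noiseless surface; strong trends in the real data", {
  ds0 <- noiseless_fixture()
  tt <- trend_analysis(ds0, "T")
  expect_equal(tt$r_squared, rep(1, nrow(tt)), tolerance = 1e-9)
  tp <- trend_analysis(ds0, "P")
  expect_equal(tp$r_squared, rep(1, nrow(tp)), tolerance = 1e-9)

  real <- load_dataset("bundled")
  rp <- trend_analysis(real, "P")
  expect_gt(rp$r_squared[rp$slice == 308.15], 0.9)
  expect_error(trend_analysis(real[real$pressure_bar <= 200, ], "P"),
               "at least 3 levels")
})
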