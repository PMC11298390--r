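test_that("bundled dataset is the full 4 x 7 isothermal table", {
  ds <- load_dataset("bundled")
  expect_s3_class(ds, "solubility_dataset")
  expect_equal(nrow(ds), 28)
  expect_equal(sort(unique(ds$temperature_K)),
               c(308.15, 318.15, 328.15, 338.15))
  expect_equal(sort(unique(ds$pressure_bar)),
               c(160, 200, 240, 280, 320, 360, 400))
  at <- function(T, P) ds$solubility[ds$temperature_K == T & ds$pressure_bar == P]
  expect_equal(at(308.15, 160), 2.21e-5)
  expect_equal(at(338.15, 400), 7.12e-4)
  expect_equal(max(ds$solubility), at(338.15, 400))
})

test_that("validation rejects malformed CSV input", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("temperature_K,pressure_bar", "300,100"), tmp)
  expect_error(load_dataset(tmp), "missing required column")

  writeLines(c("temperature_K,pressure_bar,solubility", "300,100,abc"), tmp)
  expect_error(load_dataset(tmp), "non-numeric")

  writeLines(c("temperature_K,pressure_bar,solubility", "300,100,0"), tmp)
  expect_error(load_dataset(tmp), "strictly positive")

  writeLines(c("temperature_K,pressure_bar,solubility",
               "300,100,1e-5", "300,100,2e-5"), tmp)
  expect_error(load_dataset(tmp), "duplicate")
})

test_that("write then load round-trips the record list", {
  ds <- load_dataset("bundled")
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_dataset(ds, tmp)
  back <- load_dataset(tmp)
  # identical record list (labels/provenance legitimately differ)
  for (col in c("temperature_K", "pressure_bar", "solubility")) {
    expect_equal(back[[col]], ds[[col]])
  }
})

test_that("splitting is sized by round-half-up, reproducible, and errors on empty sides", {
  ds <- load_dataset("bundled")
  sp <- split_dataset(ds, 0.2, seed = 7)
  expect_length(sp$test, 6)
  expect_length(sp$train, 22)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), 1:28)
  expect_identical(sp$test, split_dataset(ds, 0.2, seed = 7)$test)
  expect_error(split_dataset(ds, 0.999), "empty train or test")
  expect_error(split_dataset(ds[1:3, ], 0.2), "at least 5")
})

test_that("over many seeds each row lands in the test set about fraction_test of the time", {
  ds <- load_dataset("bundled")
  counts <- integer(28)
  n_seeds <- 1000
  for (s in seq_len(n_seeds)) {
    counts[split_dataset(ds, 0.2, seed = s)$test] <-
      counts[split_dataset(ds, 0.2, seed = s)$test] + 1L
  }
  freq <- counts / n_seeds
  expect_true(all(abs(freq - 6 / 28) < 0.05))
})

test_that("scaler standardizes, inverts, and rejects constant features", {
  ds <- load_dataset("bundled")
  sc <- fit_scaler(ds)
  xs <- apply_scaler(sc, ds)
  expect_lt(abs(mean(xs[, "temperature_K"])), 1e-12)
  expect_lt(abs(mean(xs[, "pressure_bar"])), 1e-12)
  expect_equal(unname(apply(xs, 2, sd)), c(1, 1), tolerance = 1e-12)
  back <- invert_scaler(sc, xs)
  expect_equal(unname(back[, 1]), ds$temperature_K, tolerance = 1e-12)
  expect_equal(unname(back[, 2]), ds$pressure_bar, tolerance = 1e-12)

  const <- data.frame(temperature_K = rep(300, 5), pressure_bar = 1:5 * 10,
                      solubility = 1:5 * 1e-5)
  expect_error(fit_scaler(const), "constant")

  # already-standardized features come back with center ~ 0, scale ~ 1
  std <- data.frame(temperature_K = scale(ds$temperature_K)[, 1],
                    pressure_bar = scale(ds$pressure_bar)[, 1])
  sc2 <- fit_scaler(std)
  expect_equal(unname(sc2$center), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(sc2$scale), c(1, 1), tolerance = 1e-12)
})
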