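sphere_space <- function(d = 3) {
  search_space(lapply(seq_len(d), function(j) {
    dim_continuous(paste0("x", j), -5, 5)
  }))
}
sphere <- function(p) sum(unlist(p)^2)

test_that("initialization assigns roles, allocates streams, and is seeded", {
  cfg <- wca_config(population_size = 10, n_rivers_plus_sea = 3,
                    max_iterations = 10, seed = 4)
  pop <- initialize_population(sphere_space(), cfg, sphere)
  expect_equal(sum(pop$role == "sea"), 1)
  expect_equal(sum(pop$role == "river"), 2)
  expect_equal(sum(pop$role == "stream"), 7)
  expect_equal(sum(pop$n_streams_per_target), 7)
  expect_equal(which.min(pop$cost), 1L)
  expect_true(all(pop$target[pop$role == "stream"] %in% 1:3))
  pop2 <- initialize_population(sphere_space(), cfg, sphere)
  expect_identical(pop$pos, pop2$pos)
  expect_error(
    initialize_population(sphere_space(), cfg, function(p) NaN),
    "non-finite"
  )
})

test_that("flow never worsens the sea and exchanges roles with better drops", {
  cfg <- wca_config(population_size = 12, n_rivers_plus_sea = 3,
                    max_iterations = 10, seed = 9)
  pop <- initialize_population(sphere_space(), cfg, sphere)
  for (rep in 1:5) {
    before <- pop$cost[1]
    pop <- flow_step(pop, cfg, sphere)
    expect_lte(pop$cost[1], before)
    expect_equal(which.min(pop$cost), 1L)  # sea holds the best cost
  }
})

test_that("evaporation rains drops near the sea and d_max decays linearly to ~0", {
  cfg <- wca_config(population_size = 8, n_rivers_plus_sea = 2,
                    max_iterations = 50, seed = 2)
  pop <- initialize_population(sphere_space(), cfg, sphere)
  # force a river onto the sea: it must be re-sampled within bounds
  pop$pos[2, ] <- pop$pos[1, ]
  set.seed(31)
  er <- evaporate_and_rain(pop, 0.1, cfg, sphere)
  moved <- er$population$pos[2, ]
  expect_false(isTRUE(all.equal(moved, pop$pos[1, ])))
  expect_true(all(moved >= -5 & moved <= 5))
  # with no drop within d_max, positions are untouched
  er2 <- evaporate_and_rain(er$population, 0, cfg, sphere)
  expect_identical(er2$population$pos, er$population$pos)
  # linear decay reaches (numerically) zero after max_iterations steps
  d <- cfg$d_max_initial
  for (i in seq_len(cfg$max_iterations)) {
    d <- evaporate_and_rain(pop, d, cfg, sphere)$d_max
  }
  expect_lt(d, 1e-6 * cfg$d_max_initial)
})

test_that("the optimizer solves simple landscapes and honors its contracts", {
  r <- wca_optimize(sphere, sphere_space(), wca_config(seed = 1))
  expect_lt(r$best_cost, 1e-3)
  expect_true(all(diff(r$cost_history) <= 0))

  flat <- wca_optimize(function(p) 42, sphere_space(),
                       wca_config(population_size = 8, n_rivers_plus_sea = 2,
                                  max_iterations = 5, seed = 1))
  expect_equal(flat$best_cost, 42)
  expect_equal(unique(flat$cost_history), 42)

  ri <- wca_optimize(function(p) abs(p$k - 7),
                     search_space(dim_integer("k", 1, 10)),
                     wca_config(population_size = 10, n_rivers_plus_sea = 2,
                                max_iterations = 30, seed = 3))
  expect_equal(ri$best_position$k, 7L)

  zero <- wca_optimize(sphere, sphere_space(),
                       wca_config(population_size = 6, n_rivers_plus_sea = 2,
                                  max_iterations = 0, seed = 5))
  expect_length(zero$cost_history, 1)
  expect_true(is.finite(zero$best_cost))
})

test_that("runs are deterministic for a fixed seed", {
  cfg <- wca_config(population_size = 10, n_rivers_plus_sea = 3,
                    max_iterations = 20, seed = 77)
  a <- wca_optimize(sphere, sphere_space(), cfg)
  b <- wca_optimize(sphere, sphere_space(), cfg)
  expect_identical(a$best_cost, b$best_cost)
  expect_identical(a$cost_history, b$cost_history)
})

test_that("positions stay in bounds and mixed dimensions decode to valid values", {
  space <- search_space(dim_continuous("a", -2, 3),
                        dim_continuous("b", 1e-4, 10, log10 = TRUE),
                        dim_integer("k", 2, 9),
                        dim_categorical("f", c("lo", "mid", "hi")))
  bumpy <- function(p) {
    p$a^2 + log10(p$b)^2 + (p$k - 4)^2 + switch(p$f, lo = 1, mid = 0, hi = 2)
  }
  for (seed in 1:5) {
    r <- wca_optimize(bumpy, space,
                      wca_config(population_size = 10, n_rivers_plus_sea = 3,
                                 max_iterations = 25, seed = seed))
    pos <- r$population$pos
    bd <- scfsol:::space_bounds(space)
    expect_true(all(t(pos) >= bd$lower - 1e-12 & t(pos) <= bd$upper + 1e-12))
    for (i in seq_len(nrow(pos))) {
      v <- decode_position(space, pos[i, ])
      expect_true(v$k %in% 2:9)
      expect_true(v$f %in% c("lo", "mid", "hi"))
      expect_true(v$b >= 1e-4 && v$b <= 10)
    }
  }
})

test_that("a larger iteration budget does not hurt on a 2-D quadratic", {
  space <- search_space(dim_continuous("x", -4, 4), dim_continuous("y", -4, 4))
  quad <- function(p) (p$x - 1)^2 + 2 * (p$y + 0.5)^2
  run <- function(iters, seed) {
    wca_optimize(quad, space,
                 wca_config(population_size = 10, n_rivers_plus_sea = 3,
                            max_iterations = iters, seed = seed))$best_cost
  }
  small <- vapply(1:20, function(s) run(100, s), 0)
  large <- vapply(1:20, function(s) run(400, s), 0)
  expect_lte(median(large), median(small))
})
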