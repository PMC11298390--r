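# Small programmatic fixtures shared across test files.

# a 2-regime piecewise dataset in scaled coordinates: step-plus-slope in T,
# flat in P; the true split sits at T = 0
piecewise_fixture <- function() {
  t <- c(-3, -2.5, -2, -1.5, -1, -0.5, 0.5, 1, 1.5, 2, 2.5, 3)
  p <- rep(c(-1, 1), 6)
  y <- ifelse(t < 0, 1 + 0.5 * t, 5 + 2 * t)
  list(x = cbind(T = t, P = p), y = y)
}

# exhaustive single-split oracle for the piecewise fit: tries every candidate
# split on every axis, OLS per side, returns the best (split, axis, rss)
brute_force_single_split <- function(x, y, degree) {
  m <- scfsol:::n_monomials(degree)
  best <- list(rss = Inf)
  for (axis in 1:2) {
    u <- sort(unique(x[, axis]))
    if (length(u) < 2) next
    for (s in (u[-1] + u[-length(u)]) / 2) {
      il <- which(x[, axis] < s); ir <- which(x[, axis] >= s)
      if (length(il) < m || length(ir) < m) next
      rss <- 0
      for (idx in list(il, ir)) {
        X <- scfsol:::poly_design(x[idx, , drop = FALSE], degree)
        fit <- lm.fit(X, y[idx])
        rss <- rss + sum(fit$residuals^2)
      }
      if (rss < best$rss) best <- list(rss = rss, axis = axis, split = s)
    }
  }
  best
}

# a small noiseless synthetic dataset on the standard 4 x 7 grid
noiseless_fixture <- function() {
  generate_dataset(surface_params(), sigma = 0, seed = 1, name = "noiseless")
}

# a fast tuner configuration for tests that loop over many seeds
fast_config <- function(seed = 1L, split_seeds = 1:10) {
  cfg <- default_config(seed = seed, split_seeds = split_seeds)
  cfg$wca <- wca_config(population_size = 8, n_rivers_plus_sea = 3,
                        d_max_initial = 0.1, max_iterations = 6, seed = seed)
  cfg
}

sample_skewness <- function(v) {
  mean((v - mean(v))^3) / stats::sd(v)^3
}
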