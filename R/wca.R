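#' Search-space dimensions
#'
#' A search space is an ordered list of named dimensions over which the Water
#' Cycle Algorithm optimizes. Continuous dimensions may be searched on a
#' log10 scale; integer and categorical dimensions are relaxed to continuous
#' coordinates internally and repaired by rounding / nearest-index mapping.
#'
#' @param name Dimension name.
#' @param lower,upper Bounds (`lower < upper`).
#' @param log10 Search on the log10 scale (continuous only)?
#' @param values Nonempty vector of admissible values (categorical only).
#' @return A dimension description for [search_space()].
#' @export
dim_continuous <- function(name, lower, upper, log10 = FALSE) {
  stopifnot(is.numeric(lower), is.numeric(upper), lower < upper)
  if (log10 && lower <= 0) stop("log10-scaled dimension needs lower > 0")
  list(name = name, kind = "continuous", lower = lower, upper = upper,
       log10 = log10)
}

#' @rdname dim_continuous
#' @export
dim_integer <- function(name, lower, upper) {
  stopifnot(lower < upper, lower == round(lower), upper == round(upper))
  list(name = name, kind = "integer", lower = lower, upper = upper,
       log10 = FALSE)
}

#' @rdname dim_continuous
#' @export
dim_categorical <- function(name, values) {
  if (length(values) == 0) stop("categorical dimension needs a nonempty value set")
  list(name = name, kind = "categorical", values = values, log10 = FALSE)
}

#' Assemble a search space
#'
#' @param ... Dimensions from [dim_continuous()], [dim_integer()],
#'   [dim_categorical()].
#' @return A `search_space`.
#' @export
search_space <- function(...) {
  dims <- list(...)
  if (length(dims) == 1 && is.null(dims[[1]]$kind)) dims <- dims[[1]]
  nm <- vapply(dims, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicate dimension names")
  structure(list(dims = dims, names = nm), class = "search_space")
}

# relaxed continuous bounds for every dimension (log10 coords where flagged,
# category index range for categoricals)
space_bounds <- function(space) {
  lo <- hi <- numeric(length(space$dims))
  for (j in seq_along(space$dims)) {
    d <- space$dims[[j]]
    if (d$kind == "categorical") {
      lo[j] <- 1; hi[j] <- length(d$values)
      if (hi[j] == lo[j]) hi[j] <- lo[j] + 1e-9  # single category: degenerate box
    } else if (d$log10) {
      lo[j] <- log10(d$lower); hi[j] <- log10(d$upper)
    } else {
      lo[j] <- d$lower; hi[j] <- d$upper
    }
  }
  list(lower = lo, upper = hi)
}

clip_position <- function(space, pos) {
  b <- space_bounds(space)
  pmin(pmax(pos, b$lower), b$upper)
}

#' Decode a relaxed position into typed hyperparameter values
#'
#' Continuous coordinates pass through (back-transformed from log10 where
#' flagged); integer coordinates are rounded and clipped; categorical
#' coordinates are mapped to the nearest category index.
#'
#' @param space A `search_space`.
#' @param pos Numeric vector in the space's relaxed coordinates.
#' @return Named list of hyperparameter values.
#' @export
decode_position <- function(space, pos) {
  out <- vector("list", length(space$dims))
  names(out) <- space$names
  for (j in seq_along(space$dims)) {
    d <- space$dims[[j]]
    x <- pos[j]
    if (d$kind == "continuous") {
      out[[j]] <- if (d$log10) 10^x else x
    } else if (d$kind == "integer") {
      out[[j]] <- as.integer(min(max(round(x), d$lower), d$upper))
    } else {
      k <- min(max(round(x), 1), length(d$values))
      out[[j]] <- d$values[[k]]
    }
  }
  out
}

sample_positions <- function(space, n) {
  b <- space_bounds(space)
  m <- matrix(stats::runif(n * length(b$lower)), nrow = n)
  sweep(sweep(m, 2, b$upper - b$lower, `*`), 2, b$lower, `+`)
}

# Euclidean distance in range-normalized relaxed coordinates, so d_max has a
# consistent meaning across heterogeneous dimensions
position_distance <- function(space, a, b) {
  bd <- space_bounds(space)
  sqrt(sum(((a - b) / (bd$upper - bd$lower))^2))
}

#' Water Cycle Algorithm configuration
#'
#' @param population_size Total raindrops (> `n_rivers_plus_sea`).
#' @param n_rivers_plus_sea Number of rivers plus the sea (N_sr >= 1).
#' @param d_max_initial Initial evaporation distance threshold, in
#'   range-normalized coordinates; decays linearly to 0 over the run.
#' @param max_iterations Iteration budget (0 returns the best of the
#'   initialization).
#' @param seed Integer seed; the whole run is reproducible.
#' @return A `wca_config`.
#' @export
wca_config <- function(population_size = 30, n_rivers_plus_sea = 4,
                       d_max_initial = 0.1, max_iterations = 200, seed = 1L) {
  if (!(population_size > n_rivers_plus_sea && n_rivers_plus_sea >= 1)) {
    stop("need population_size > n_rivers_plus_sea >= 1")
  }
  if (max_iterations < 0) stop("max_iterations must be >= 0")
  if (d_max_initial <= 0) stop("d_max_initial must be > 0")
  structure(list(population_size = as.integer(population_size),
                 n_rivers_plus_sea = as.integer(n_rivers_plus_sea),
                 d_max_initial = d_max_initial,
                 max_iterations = as.integer(max_iterations),
                 seed = as.integer(seed)),
            class = "wca_config")
}

eval_cost <- function(objective, space, pos) {
  v <- tryCatch(objective(decode_position(space, pos)), error = function(e) Inf)
  if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) Inf else as.numeric(v)
}

# largest-remainder apportionment of n_streams across N_sr intensities;
# guarantees nonnegative integers summing exactly to n_streams
apportion_streams <- function(intensity, n_streams) {
  if (sum(intensity) <= 0 || !all(is.finite(intensity))) {
    intensity <- rep(1, length(intensity))
  }
  share <- intensity / sum(intensity) * n_streams
  ns <- floor(share)
  rem <- n_streams - sum(ns)
  if (rem > 0) {
    idx <- order(share - ns, decreasing = TRUE)[seq_len(rem)]
    ns[idx] <- ns[idx] + 1
  }
  as.integer(ns)
}

#' Initialize the raindrop population
#'
#' Samples `population_size` positions uniformly within bounds (log-uniform on
#' log10 dimensions), evaluates their costs, sorts them, and assigns roles:
#' the best drop is the sea, the next `N_sr - 1` are rivers, the rest are
#' streams. Streams are allocated to the sea and rivers in proportion to a
#' cost-derived intensity (better sea/rivers attract more streams).
#'
#' @param space A `search_space`.
#' @param config A `wca_config`.
#' @param objective Function from a decoded named parameter list to a scalar
#'   cost (lower is better); non-finite values are treated as +Inf.
#' @param reseed Seed the RNG from `config$seed` before sampling (set to
#'   FALSE when called inside an already-seeded run).
#' @return A `wca_population`: positions, costs, roles, flow targets.
#' @export
initialize_population <- function(space, config, objective, reseed = TRUE) {
  draw <- function() sample_positions(space, config$population_size)
  pos <- if (reseed) with_seed(config$seed, draw()) else draw()
  cost <- apply(pos, 1, function(p) eval_cost(objective, space, p))
  if (all(!is.finite(cost))) {
    stop("objective returned a non-finite cost for every initial raindrop")
  }
  ord <- order(cost)
  pos <- pos[ord, , drop = FALSE]
  cost <- cost[ord]
  nsr <- config$n_rivers_plus_sea
  npop <- config$population_size
  role <- c("sea", rep("river", nsr - 1), rep("stream", npop - nsr))
  # intensity: cost gap to the best stream (canonical cost-difference rule)
  ref <- cost[nsr + 1]
  intensity <- abs(cost[seq_len(nsr)] - ref)
  if (!all(is.finite(intensity))) intensity <- rep(1, nsr)
  ns <- apportion_streams(intensity, npop - nsr)
  target <- rep(NA_integer_, npop)
  target[seq_len(nsr)[-1]] <- 1L                 # rivers flow to the sea
  target[(nsr + 1):npop] <- rep(seq_len(nsr), times = ns)
  structure(list(pos = pos, cost = cost, role = role, target = target,
                 space = space, n_streams_per_target = ns),
            class = "wca_population")
}

swap_drops <- function(pop, i, j) {
  pop$pos[c(i, j), ] <- pop$pos[c(j, i), , drop = FALSE]
  pop$cost[c(i, j)] <- pop$cost[c(j, i)]
  pop
}

#' One flow step: streams run to rivers, rivers to the sea
#'
#' Each moving drop updates `X_new = X + U(0, 2) * (X_target - X)`
#' componentwise, is clipped to the bounds, and is re-evaluated. A drop that
#' becomes better than its target exchanges roles with it, so the sea always
#' holds the best cost found.
#'
#' @param pop A `wca_population`.
#' @param config A `wca_config`.
#' @param objective The cost function (see [initialize_population()]).
#' @return The updated population.
#' @export
flow_step <- function(pop, config, objective) {
  space <- pop$space
  d <- ncol(pop$pos)
  move <- function(i, tgt) {
    new <- pop$pos[i, ] + stats::runif(d, 0, 2) * (pop$pos[tgt, ] - pop$pos[i, ])
    new <- clip_position(space, new)
    pop$pos[i, ] <<- new
    pop$cost[i] <<- eval_cost(objective, space, new)
    if (pop$cost[i] < pop$cost[tgt]) pop <<- swap_drops(pop, i, tgt)
  }
  for (i in which(pop$role == "stream")) move(i, pop$target[i])
  for (i in which(pop$role == "river")) move(i, 1L)
  # a stream can outrun its river within one step (the river moves on and may
  # re-evaluate worse); restore the sea-holds-the-minimum invariant
  wm <- which.min(pop$cost)
  if (wm != 1L) pop <- swap_drops(pop, 1L, wm)
  pop
}

#' Evaporation and raining
#'
#' Rivers (and streams that flow directly into the sea) lying within
#' `d_max_current` of the sea evaporate and rain back as fresh uniform samples,
#' the algorithm's restart mechanism against premature convergence. The
#' threshold decays linearly: `d_next = max(0, d - d_max_initial /
#' max_iterations)`, reaching 0 at the final iteration.
#'
#' @param pop A `wca_population`.
#' @param d_max_current Current evaporation threshold.
#' @param config A `wca_config`.
#' @param objective The cost function, used to score rained drops.
#' @return List with the updated `population` and `d_max` for the next
#'   iteration.
#' @export
evaporate_and_rain <- function(pop, d_max_current, config, objective) {
  space <- pop$space
  near_sea <- which((pop$role == "river") |
                      (pop$role == "stream" & pop$target == 1L))
  for (i in near_sea) {
    if (position_distance(space, pop$pos[1, ], pop$pos[i, ]) < d_max_current) {
      pop$pos[i, ] <- sample_positions(space, 1)[1, ]
      pop$cost[i] <- eval_cost(objective, space, pop$pos[i, ])
      if (pop$cost[i] < pop$cost[1]) pop <- swap_drops(pop, i, 1L)
    }
  }
  d_next <- max(0, d_max_current - config$d_max_initial / max(1L, config$max_iterations))
  list(population = pop, d_max = d_next)
}

#' Run the Water Cycle Algorithm
#'
#' Initializes the population, then alternates flow and evaporation/raining
#' for `max_iterations` iterations. The best cost is carried by the sea and
#' never worsens, so the returned history is non-increasing. Fully
#' reproducible for a fixed `config$seed`.
#'
#' @param objective Function from a decoded named parameter list to scalar
#'   cost (minimized); non-finite values count as +Inf.
#' @param space A `search_space`.
#' @param config A `wca_config`.
#' @return A `wca_result`: `best_position` (decoded named list), `best_cost`,
#'   `cost_history` (initialization + one entry per iteration),
#'   `evaluations`, and the final `population`.
#' @export
wca_optimize <- function(objective, space, config = wca_config()) {
  n_eval <- 0L
  counted <- function(p) { n_eval <<- n_eval + 1L; objective(p) }
  run <- function() {
    pop <- initialize_population(space, config, counted, reseed = FALSE)
    d_max <- config$d_max_initial
    history <- numeric(config$max_iterations + 1L)
    history[1] <- pop$cost[1]
    if (config$max_iterations >= 1) {
      for (it in seq_len(config$max_iterations)) {
        pop <- flow_step(pop, config, counted)
        er <- evaporate_and_rain(pop, d_max, config, counted)
        pop <- er$population
        d_max <- er$d_max
        history[it + 1L] <- pop$cost[1]
      }
    }
    list(pop = pop, history = history)
  }
  out <- with_seed(config$seed, run())
  structure(list(best_position = decode_position(space, out$pop$pos[1, ]),
                 best_cost = out$pop$cost[1],
                 cost_history = out$history,
                 evaluations = n_eval,
                 population = out$pop,
                 config = config),
            class = "wca_result")
}

#' Final population as candidate hyperparameter sets
#'
#' Returns the `q` best distinct positions of a finished run's population,
#' decoded, best first. Used by the AIC filter downstream.
#'
#' @param result A `wca_result`.
#' @param q Number of candidates.
#' @return List of decoded named parameter lists.
#' @export
top_candidates <- function(result, q = 5) {
  pop <- result$population
  ord <- order(pop$cost)
  seen <- character(0)
  out <- list()
  for (i in ord) {
    if (!is.finite(pop$cost[i])) next
    key <- paste(signif(pop$pos[i, ], 12), collapse = "|")
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- decode_position(pop$space, pop$pos[i, ])
    if (length(out) >= q) break
  }
  out
}
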