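#' Parametric solubility surface
#'
#' The generator's mean surface combines the two trends seen in isothermal
#' solubility data for drugs in supercritical CO2: solubility grows
#' exponentially with temperature and linearly with pressure. The separable
#' form is
#'
#'   y(T, P) = base * (1 + pressure_slope * (P - P0)) * exp(temp_rate * (T - T0))
#'             * exp(interaction * (T - T0) * (P - P0))          (interaction = 0 by default)
#'
#' with `base` the mole-fraction solubility at the reference point `(T0, P0)`.
#'
#' @param base Mole fraction at `(T0, P0)`; must be > 0.
#' @param temp_rate Exponential temperature coefficient, per kelvin; >= 0.
#' @param pressure_slope Relative linear pressure coefficient, per bar.
#' @param T0,P0 Reference temperature (K) and pressure (bar); default the
#'   lower corner of the ketoprofen design grid.
#' @param interaction Optional T-by-P log-scale interaction, per (K * bar);
#'   default 0 (separable surface).
#' @return A `surface_params` object.
#' @export
surface_params <- function(base = 2.21e-5, temp_rate = 0.065,
                           pressure_slope = 0.004, T0 = 308.15, P0 = 160,
                           interaction = 0) {
  if (base <= 0) stop("base solubility must be > 0")
  if (temp_rate < 0) stop("temp_rate must be >= 0")
  structure(list(base = base, temp_rate = temp_rate,
                 pressure_slope = pressure_slope, T0 = T0, P0 = P0,
                 interaction = interaction),
            class = "surface_params")
}

#' Evaluate the mean solubility surface
#'
#' @param params A `surface_params`.
#' @param temperature_K,pressure_bar Numeric vectors (recycled together).
#' @return Mole-fraction solubility, strictly positive; errors if the linear
#'   pressure factor is non-positive anywhere in the requested points.
#' @export
surface_value <- function(params, temperature_K, pressure_bar) {
  stopifnot(inherits(params, "surface_params"))
  pf <- 1 + params$pressure_slope * (pressure_bar - params$P0)
  if (any(pf <= 0)) {
    stop("pressure factor (1 + pressure_slope*(P - P0)) is non-positive at ",
         "P = ", paste(unique(pressure_bar[pf <= 0]), collapse = ", "),
         " bar; surface would not be strictly positive")
  }
  dT <- temperature_K - params$T0
  dP <- pressure_bar - params$P0
  params$base * pf * exp(params$temp_rate * dT + params$interaction * dT * dP)
}

#' Generate a synthetic solubility dataset
#'
#' Evaluates the mean surface on a `T x P` lattice and applies multiplicative
#' lognormal noise: `y = surface * exp(rnorm(0, sigma))`. Multiplicative
#' lognormal noise keeps solubility strictly positive and right-skewed, the
#' two distributional features of the real data.
#'
#' @param params A `surface_params`.
#' @param temperatures,pressures Grid levels (K, bar); the full lattice is
#'   used.
#' @param sigma Log-scale noise standard deviation; `sigma = 0` returns the
#'   noiseless surface. Default 0.05.
#' @param seed Integer seed; the draw is reproducible.
#' @param name Dataset label.
#' @return A `solubility_dataset`.
#' @export
generate_dataset <- function(params,
                             temperatures = c(308.15, 318.15, 328.15, 338.15),
                             pressures = c(160, 200, 240, 280, 320, 360, 400),
                             sigma = 0.05, seed = 1L, name = "synthetic") {
  if (sigma < 0) stop("sigma must be >= 0")
  if (length(temperatures) == 0 || length(pressures) == 0) {
    stop("grid must be nonempty")
  }
  grid <- expand.grid(pressure_bar = pressures, temperature_K = temperatures,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[c("temperature_K", "pressure_bar")]
  mu <- surface_value(params, grid$temperature_K, grid$pressure_bar)
  noise <- if (sigma == 0) rep(1, nrow(grid)) else {
    with_seed(seed, exp(stats::rnorm(nrow(grid), 0, sigma)))
  }
  grid$solubility <- mu * noise
  as_solubility_dataset(grid, name = name,
                        provenance = sprintf(
                          "synthetic surface (sigma = %g, seed = %d)", sigma,
                          as.integer(seed)))
}

#' Recover surface parameters from data
#'
#' Least-squares fit of the surface on the log scale:
#' `log y = log(base) + temp_rate*(T - T0) + log(1 + pressure_slope*(P - P0))`,
#' solved by Levenberg-Marquardt with starting values from the linearized
#' regression of `log y` on `(T - T0)` and `(P - P0)`.
#'
#' @param ds A `solubility_dataset` with at least 6 records spanning at least
#'   2 temperature and 2 pressure levels.
#' @param T0,P0 Reference point; defaults to the dataset minimum.
#' @return A `surface_params` estimate with attributes `residual_sd` (log-scale
#'   residual standard deviation) and `r_squared` (on the log scale).
#' @export
recover_params <- function(ds, T0 = NULL, P0 = NULL) {
  df <- as.data.frame(ds)
  if (nrow(df) < 6) stop("need at least 6 records to recover surface parameters")
  if (length(unique(df$temperature_K)) < 2 || length(unique(df$pressure_bar)) < 2) {
    stop("degenerate design: need at least 2 temperature and 2 pressure levels")
  }
  T0 <- T0 %||% min(df$temperature_K)
  P0 <- P0 %||% min(df$pressure_bar)
  dat <- data.frame(ly = log(df$solubility),
                    dT = df$temperature_K - T0,
                    dP = df$pressure_bar - P0)
  lin <- stats::lm(ly ~ dT + dP, data = dat)
  start <- list(lb = unname(stats::coef(lin)[1]),
                k = max(0, unname(stats::coef(lin)[2])),
                c = unname(stats::coef(lin)[3]))
  # keep the start inside the admissible region (1 + c*dP > 0)
  if (1 + start$c * max(dat$dP) <= 0) start$c <- 0
  fit <- minpack.lm::nlsLM(
    ly ~ lb + k * dT + log(1 + c * dP), data = dat, start = start,
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                         ptol = 1e-14))
  co <- stats::coef(fit)
  res <- stats::resid(fit)
  est <- surface_params(base = exp(unname(co["lb"])),
                        temp_rate = max(0, unname(co["k"])),
                        pressure_slope = unname(co["c"]),
                        T0 = T0, P0 = P0)
  attr(est, "residual_sd") <- stats::sd(res)
  attr(est, "r_squared") <- 1 - sum(res^2) / sum((dat$ly - mean(dat$ly))^2)
  est
}
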