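# Piecewise polynomial regression over a CART-style axis-aligned partition.
# The partition is grown greedily under the penalized least squares criterion
#   RSS + penalty_weight * n_parameters,
# n_parameters counting every free polynomial coefficient across segments.

# total-degree monomial basis in two variables; column order: intercept,
# T, P, T^2, T*P, P^2, T^3, ...
poly_design <- function(x, degree) {
  x <- as.matrix(x)
  cols <- list()
  nm <- character(0)
  for (t in 0:degree) {
    for (a in t:0) {
      b <- t - a
      cols[[length(cols) + 1L]] <- x[, 1]^a * x[, 2]^b
      nm <- c(nm, paste0("T", a, "P", b))
    }
  }
  m <- do.call(cbind, cols)
  colnames(m) <- nm
  m
}

n_monomials <- function(degree) (degree + 1) * (degree + 2) / 2

# OLS with rank-deficiency guard: aliased coefficients are zeroed so the
# fitted polynomial stays evaluable
fit_ols <- function(X, y) {
  qr_ <- qr(X)
  coef <- qr.coef(qr_, y)
  coef[is.na(coef)] <- 0
  fitted <- drop(X %*% coef)
  list(coef = coef, rss = sum((y - fitted)^2))
}

leaf_fit <- function(x, y, idx, box, degree) {
  X <- poly_design(x[idx, , drop = FALSE], degree)
  f <- fit_ols(X, y[idx])
  list(idx = idx, box = box, coef = f$coef, rss = f$rss, n = length(idx))
}

# candidate split points: midpoints between consecutive sorted unique
# coordinates of the leaf's training points along one axis
split_candidates <- function(v) {
  u <- sort(unique(v))
  if (length(u) < 2) return(numeric(0))
  (u[-1] + u[-length(u)]) / 2
}

#' Fit a piecewise polynomial regression
#'
#' Grows an axis-aligned binary partition of the (scaled) temperature by
#' pressure box greedily, CART-style: at each step the single split that most
#' decreases `RSS + penalty_weight * n_parameters` is accepted, where each new
#' segment adds one full polynomial's worth of coefficients. Growth stops when
#' no split decreases the criterion, when `max_segments` is reached, or when a
#' child would hold fewer points than polynomial coefficients. Segments are
#' fitted independently by ordinary least squares (no continuity constraint at
#' segment boundaries).
#'
#' Ties between equally good splits are broken deterministically: earlier
#' leaf, then first axis (temperature before pressure), then lower split
#' coordinate.
#'
#' @param x Numeric matrix of scaled features, columns (temperature, pressure).
#' @param y Response vector (raw mole-fraction solubility).
#' @param degree Polynomial total degree per segment (1--3).
#' @param max_segments Maximum number of segments.
#' @param penalty_weight Nonnegative weight on the parameter count in the
#'   penalized criterion. Very large values force a single global polynomial.
#' @return An object of class `scfsol_ppr` with the leaf list, the parameter
#'   count `n_parameters`, and the criterion trace across accepted splits.
#' @export
fit_ppr <- function(x, y, degree = 2, max_segments = 4, penalty_weight = 0) {
  x <- as.matrix(x)
  stopifnot(ncol(x) == 2, nrow(x) == length(y), degree >= 1,
            max_segments >= 1, penalty_weight >= 0)
  m <- n_monomials(degree)
  if (nrow(x) < m) {
    stop("degree ", degree, " needs at least ", m,
         " training points per segment; have ", nrow(x))
  }
  box <- list(lo = apply(x, 2, min), hi = apply(x, 2, max))
  leaves <- list(leaf_fit(x, y, seq_len(nrow(x)), box, degree))
  criterion <- sum(vapply(leaves, `[[`, 0, "rss")) + penalty_weight * m
  trace <- criterion
  while (length(leaves) < max_segments) {
    best <- NULL  # list(leaf, axis, value, gain, left, right)
    for (li in seq_along(leaves)) {
      lf <- leaves[[li]]
      if (lf$n < 2 * m) next
      for (axis in 1:2) {
        for (s in split_candidates(x[lf$idx, axis])) {
          il <- lf$idx[x[lf$idx, axis] < s]
          ir <- lf$idx[x[lf$idx, axis] >= s]
          if (length(il) < m || length(ir) < m) next
          bl <- lf$box; bl$hi[axis] <- s
          br <- lf$box; br$lo[axis] <- s
          left <- leaf_fit(x, y, il, bl, degree)
          right <- leaf_fit(x, y, ir, br, degree)
          gain <- lf$rss - (left$rss + right$rss) - penalty_weight * m
          if (gain > 0 && (is.null(best) || gain > best$gain)) {
            best <- list(leaf = li, axis = axis, value = s, gain = gain,
                         left = left, right = right)
          }
        }
      }
    }
    if (is.null(best)) break
    leaves[[best$leaf]] <- best$left
    leaves[[length(leaves) + 1L]] <- best$right
    criterion <- criterion - best$gain
    trace <- c(trace, criterion)
  }
  structure(list(leaves = leaves, degree = degree, box = box,
                 penalty_weight = penalty_weight,
                 n_parameters = length(leaves) * m,
                 rss = sum(vapply(leaves, `[[`, 0, "rss")),
                 criterion_trace = trace),
            class = "scfsol_ppr")
}

# route clipped points to leaves: a point belongs to the leaf with
# lo <= x < hi on every axis; points on a split boundary go to the
# right/upper child (whose box starts at the split), and the global upper
# face is closed
route_to_leaf <- function(model, xi) {
  for (li in seq_along(model$leaves)) {
    b <- model$leaves[[li]]$box
    ok <- TRUE
    for (j in 1:2) {
      hi_closed <- b$hi[j] >= model$box$hi[j]
      if (xi[j] < b$lo[j] || (if (hi_closed) xi[j] > b$hi[j] else xi[j] >= b$hi[j])) {
        ok <- FALSE; break
      }
    }
    if (ok) return(li)
  }
  stop("internal error: point not routed to any segment")
}

#' Predict from a piecewise polynomial model
#'
#' Each query is clipped into the training box (so out-of-range points use
#' the nearest boundary segment), routed to exactly one segment, and the
#' segment's polynomial is evaluated.
#'
#' @param object A `scfsol_ppr` model.
#' @param x Matrix of scaled features, columns (temperature, pressure).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict_ppr <- function(object, x, ...) {
  x <- as.matrix(x)
  xc <- pmin(pmax(t(x), object$box$lo), object$box$hi)  # 2 x n, clipped
  out <- numeric(ncol(xc))
  for (i in seq_len(ncol(xc))) {
    li <- route_to_leaf(object, xc[, i])
    X <- poly_design(matrix(xc[, i], nrow = 1), object$degree)
    out[i] <- drop(X %*% object$leaves[[li]]$coef)
  }
  out
}

#' @export
predict.scfsol_ppr <- function(object, x, ...) predict_ppr(object, x, ...)
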