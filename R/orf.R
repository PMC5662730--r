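#' Monotone normalized response function
#'
#' A mapping from offered quantity to normalized activity (units of the
#' maximum rate): values are monotone non-decreasing and bounded in [0, 1].
#'
#' @param grid Ordered quantity points.
#' @param values Normalized activity at each point.
#' @param good `"A"` or `"B"`.
#' @return An object of class `response_function`.
#' @export
response_function <- function(grid, values, good = "B") {
  stopifnot(length(grid) == length(values), !is.unsorted(grid),
            all(diff(values) >= -1e-9),
            min(values) >= -1e-9, max(values) <= 1 + 1e-9)
  structure(list(grid = grid, values = pmin(pmax(values, 0), 1), good = good),
            class = "response_function")
}

#' @export
print.response_function <- function(x, ...) {
  cat(sprintf("Response function (good %s): %d grid points on [%g, %g]\n",
              x$good, length(x$grid), min(x$grid), max(x$grid)))
  invisible(x)
}

#' Evaluate a response function at arbitrary quantities
#'
#' Linear interpolation between grid points; constant beyond the grid ends.
#'
#' @param rf A `response_function`.
#' @param q Quantities.
#' @return Normalized activity values.
#' @export
eval_response_function <- function(rf, q) {
  stats::approx(rf$grid, rf$values, xout = q, rule = 2, ties = "ordered")$y
}

#' Quantity at which a response function crosses a given activity level
#'
#' Linear interpolation between the bracketing grid points; for a step
#' function with the tie point at 0.5 this returns the step location.
#'
#' @param rf A `response_function`.
#' @param level Activity level (default 0.5).
#' @return The crossing quantity, or `NA` if the level is never reached.
#' @export
step_location <- function(rf, level = 0.5) {
  v <- rf$values; x <- rf$grid
  if (v[1] >= level) return(x[1])
  i <- which(v >= level)[1]
  if (is.na(i)) return(NA_real_)
  if (v[i] == level) return(x[i])
  x[i - 1] + (x[i] - x[i - 1]) * (level - v[i - 1]) / (v[i] - v[i - 1])
}

#' Joint offer distribution for response-function optimization
#'
#' @param offers Data frame with columns `q_A`, `q_B` and optional `weight`.
#' @param rho Relative value (payoff accounting in juice-B units).
#' @return An object of class `offer_distribution`.
#' @export
offer_distribution <- function(offers, rho) {
  stopifnot(all(c("q_A", "q_B") %in% names(offers)), rho > 0)
  if (is.null(offers$weight)) offers$weight <- 1
  offers$weight <- offers$weight / sum(offers$weight)
  structure(list(offers = offers, rho = rho), class = "offer_distribution")
}

#' Symmetric uniform joint offer distribution
#'
#' Quantities of both goods uniform and independent, with equal value
#' ranges (the good-B range equals `rho` times the good-A range), discretized
#' on a regular grid.
#'
#' @param rho Relative value.
#' @param Q_A Range of good A (good B spans `rho * Q_A`).
#' @param n Grid points per axis.
#' @return An `offer_distribution`.
#' @export
uniform_offer_distribution <- function(rho = 1, Q_A = 1, n = 21) {
  offers <- expand.grid(q_A = seq(0, Q_A, length.out = n),
                        q_B = seq(0, rho * Q_A, length.out = n))
  offers <- offers[!(offers$q_A == 0 & offers$q_B == 0), ]
  offer_distribution(offers, rho)
}

# Expected payoff of a pair of response functions under the generalized
# noise model: the linear drive q_g t_g of the decision model is replaced by
# nu_bar * f_g(q_g), keeping the Poisson-like variance proportional to the
# mean activity: z = sqrt(nu_bar) (f_A - f_B) / sqrt(chi (f_A + f_B)).
orf_payoff <- function(va, vb, ia, ib, w, value_a, value_b, chi, nu_bar) {
  fa <- va[ia]; fb <- vb[ib]
  s <- fa + fb
  if (chi <= 0) {
    p <- ifelse(fa > fb, 1, ifelse(fa < fb, 0, 0.5))
  } else {
    z <- ifelse(s > 0, sqrt(nu_bar) * (fa - fb) / sqrt(chi * pmax(s, 1e-300)), 0)
    p <- stats::pnorm(z)
  }
  sum(w * (p * value_a + (1 - p) * value_b))
}

#' Numerically optimized payoff-maximizing response functions
#'
#' Maximizes the expected payoff over monotone normalized response functions
#' for the two goods, given a joint offer distribution and the decision
#' noise level. The response functions replace the linear drive of the
#' decision model (`q_g t_g -> nu_bar f_g(q_g)`; variance proportional to
#' mean activity, reducing to the linear model when `f` is linear). The
#' optimizer is projected coordinate ascent on the grid values under the
#' monotonicity bounds, with multiple deterministic and seeded random
#' starts (linear ramps, candidate steps at every grid point) to avoid
#' local optima. After convergence, grid points whose value is
#' payoff-indifferent -- offered only in exact value ties, or never offered
#' -- are set to the midpoint of their feasible interval, which places the
#' conventional 0.5 at the tie point of a step solution.
#'
#' @param dist An [offer_distribution()].
#' @param chi Decision noise coefficient (default `0.01 / 4`).
#' @param grid_resolution Minimum grid points per good; the offered
#'   quantity levels are always included.
#' @param nu_bar Maximum activity (sets the noise scale via
#'   `sqrt(nu_bar / chi)`).
#' @param n_random_starts Extra random monotone starts.
#' @param max_sweeps Maximum coordinate sweeps per start.
#' @param tol Convergence threshold on the payoff improvement per sweep.
#' @param seed Seed for the random starts.
#'
#' @return List with `f_A`, `f_B` (class `response_function`), `payoff`,
#'   and `converged`.
#' @export
optimize_response_functions <- function(dist, chi = 0.0025,
                                        grid_resolution = 21, nu_bar = 1,
                                        n_random_starts = 3,
                                        max_sweeps = 200, tol = 1e-9,
                                        seed = 1) {
  stopifnot(inherits(dist, "offer_distribution"), grid_resolution >= 2)
  offers <- dist$offers
  ga <- sort(unique(offers$q_A))
  gb <- sort(unique(offers$q_B))
  ia <- match(offers$q_A, ga)
  ib <- match(offers$q_B, gb)
  w <- offers$weight
  value_a <- dist$rho * offers$q_A
  value_b <- offers$q_B
  na <- length(ga); nb <- length(gb)

  payoff_of <- function(va, vb) {
    orf_payoff(va, vb, ia, ib, w, value_a, value_b, chi, nu_bar)
  }

  ascend <- function(va, vb) {
    best <- payoff_of(va, vb)
    for (sweep in seq_len(max_sweeps)) {
      prev <- best
      for (j in seq_len(na)) {
        lo <- if (j > 1) va[j - 1] else 0
        hi <- if (j < na) va[j + 1] else 1
        if (hi - lo > 1e-12) {
          o <- stats::optimize(function(v) {
            va[j] <- v; payoff_of(va, vb)
          }, interval = c(lo, hi), maximum = TRUE, tol = 1e-7)
          # also test the interval ends (step solutions live on the boundary)
          cand_v <- c(o$maximum, lo, hi)
          cand_p <- c(o$objective,
                      {va[j] <- lo; payoff_of(va, vb)},
                      {va[j] <- hi; payoff_of(va, vb)})
          k <- which.max(cand_p)
          va[j] <- cand_v[k]; best <- cand_p[k]
        }
      }
      for (j in seq_len(nb)) {
        lo <- if (j > 1) vb[j - 1] else 0
        hi <- if (j < nb) vb[j + 1] else 1
        if (hi - lo > 1e-12) {
          o <- stats::optimize(function(v) {
            vb[j] <- v; payoff_of(va, vb)
          }, interval = c(lo, hi), maximum = TRUE, tol = 1e-7)
          cand_v <- c(o$maximum, lo, hi)
          cand_p <- c(o$objective,
                      {vb[j] <- lo; payoff_of(va, vb)},
                      {vb[j] <- hi; payoff_of(va, vb)})
          k <- which.max(cand_p)
          vb[j] <- cand_v[k]; best <- cand_p[k]
        }
      }
      if (best - prev < tol * (1 + abs(best))) break
    }
    list(va = va, vb = vb, payoff = best,
         converged = best - prev < tol * (1 + abs(best)))
  }

  linear <- function(n) if (n == 1) 0.5 else seq(0, 1, length.out = n)
  step_at <- function(g, x) ifelse(g < x, 0, ifelse(g > x, 1, 0.5))
  starts <- list(list(va = linear(na), vb = linear(nb)))
  for (x in gb) {
    starts[[length(starts) + 1L]] <- list(va = linear(na), vb = step_at(gb, x))
  }
  for (x in ga) {
    starts[[length(starts) + 1L]] <- list(va = step_at(ga, x), vb = linear(nb))
  }
  best <- with_seed(seed, {
    for (k in seq_len(n_random_starts)) {
      starts[[length(starts) + 1L]] <- list(va = sort(stats::runif(na)),
                                            vb = sort(stats::runif(nb)))
    }
    # full ascent is run only from the most promising starts (by initial
    # payoff); the linear ramp is always ascended
    p0 <- vapply(starts, function(s) payoff_of(s$va, s$vb), numeric(1))
    keep <- unique(c(1L, order(p0, decreasing = TRUE)[seq_len(min(4L,
                                                                  length(starts)))]))
    best <- NULL
    for (s in starts[keep]) {
      res <- ascend(s$va, s$vb)
      if (is.null(best) || res$payoff > best$payoff) best <- res
    }
    best
  })

  # payoff-indifferent grid points: only exact value ties (or never offered)
  settle_ties <- function(v, g, idx, own_value, other_value) {
    for (j in seq_along(g)) {
      at <- idx == j & w > 0
      if (!any(at) || all(abs(own_value[at] - other_value[at]) < 1e-9)) {
        lo <- if (j > 1) v[j - 1] else 0
        hi <- if (j < length(g)) v[j + 1] else 1
        v[j] <- min(max(0.5, lo), hi)
      }
    }
    v
  }
  va <- settle_ties(best$va, ga, ia, value_a, value_b)
  vb <- settle_ties(best$vb, gb, ib, value_b, value_a)

  list(f_A = response_function(ga, va, "A"),
       f_B = response_function(gb, vb, "B"),
       payoff = payoff_of(va, vb),
       converged = best$converged)
}

#' Analytic step-function optimum for degenerate session designs
#'
#' For the idealized session designs in which every binary offer type
#' includes at least one good offered in quantity 1, the payoff-maximizing
#' response functions are step functions: for good B, 0 below the relative
#' value `rho`, 0.5 at the tie point `rho`, 1 above; for good A, 0 at a zero
#' offer, 0.5 at quantity 1, 1 above.
#'
#' @param trials Trial table (or data frame of offer types with `q_A`,
#'   `q_B`) used to check the degeneracy pattern and read off the quantity
#'   levels.
#' @param rho Relative value.
#' @param good `"A"` or `"B"`.
#' @return A `response_function` on the session's quantity levels.
#' @export
session_step_orf <- function(trials, rho, good = c("B", "A")) {
  good <- match.arg(good)
  bin <- trials[trials$q_A > 0 & trials$q_B > 0, c("q_A", "q_B")]
  if (nrow(bin) > 0 && !all(bin$q_A == 1 | bin$q_B == 1)) {
    stop(paste("session design is not degenerate (binary offers without a",
               "quantity-1 offer); use optimize_response_functions()"))
  }
  if (good == "B") {
    g <- sort(unique(trials$q_B))
    v <- ifelse(g < rho, 0, ifelse(g > rho, 1, 0.5))
  } else {
    g <- sort(unique(trials$q_A))
    v <- ifelse(g < 1, 0, ifelse(g > 1, 1, 0.5))
  }
  response_function(g, v, good)
}

#' Mean optimal response function across sessions
#'
#' Each session's optimal offer-value-B response is a step at `rho / Q_B`
#' on the normalized quantity axis; the mean across sessions is therefore
#' the empirical cumulative distribution function of `rho / Q_B`, evaluated
#' on a normalized grid in [0, 1]. If `rho / Q_B` were uniform on [0, 1],
#' the mean optimal response would be linear.
#'
#' @param rho_over_Q Per-session values of `rho / Q_B`, in (0, 1].
#' @param grid Normalized quantity grid.
#' @return A `response_function` in normalized units (good B).
#' @export
mean_orf <- function(rho_over_Q, grid = seq(0, 1, length.out = 101)) {
  if (length(rho_over_Q) < 1) stop("need at least one session")
  stopifnot(all(rho_over_Q > 0), all(rho_over_Q <= 1))
  response_function(grid, stats::ecdf(rho_over_Q)(grid), "B")
}

#' Optimal response functions for the symmetric uniform offer distribution
#'
#' Runs the monotone response-function optimizer on a symmetric uniform
#' joint distribution (equal value ranges, normalized units). The result is
#' quasi-linear and slightly convex -- the shape against which recorded
#' offer-value responses are benchmarked, and one of the 20 encoding
#' variables of the variable-selection analysis.
#'
#' @param chi Decision noise coefficient (default `0.01 / 4`).
#' @param grid_resolution Grid points per good.
#' @param rho Relative value of the symmetric design.
#' @param ... Passed to [optimize_response_functions()].
#' @return List with `f_A`, `f_B`, `payoff`, `converged`.
#' @export
orf_uniform <- function(chi = 0.0025, grid_resolution = 21, rho = 1, ...) {
  dist <- uniform_offer_distribution(rho = rho, n = grid_resolution)
  optimize_response_functions(dist, chi = chi,
                              grid_resolution = grid_resolution, ...)
}
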