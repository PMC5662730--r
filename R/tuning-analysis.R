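#' Cumulative distribution of trial counts over quantity levels
#'
#' The infomax benchmark shape for a neuron's tuning: the cumulative
#' fraction of trials at each offered quantity level. Optionally normalized
#' with the same linear-regression transform applied to firing rates, so
#' that its best straight-line fit is the identity.
#'
#' @param levels Strictly increasing quantity levels.
#' @param counts Trials per level (>= 1 each).
#' @param normalize Apply the linear-fit normalization.
#' @return Data frame with `level`, `x` (level / max level), `cdf_raw`, and
#'   (when normalized) `cdf_norm`.
#' @export
ntrials_cdf <- function(levels, counts, normalize = TRUE) {
  if (length(levels) < 2) stop("need at least 2 quantity levels")
  stopifnot(length(counts) == length(levels), all(counts >= 1),
            !is.unsorted(levels, strictly = TRUE))
  cdf <- cumsum(counts) / sum(counts)
  x <- levels / max(levels)
  out <- data.frame(level = levels, x = x, cdf_raw = cdf)
  if (normalize) {
    b <- stats::coef(stats::lm(cdf ~ x))
    out$cdf_norm <- (cdf - b[1]) / b[2]
  }
  out
}

#' Normalize a neuronal response for curvature analysis
#'
#' Quantity levels are divided by the maximum level in the session; firing
#' rates are regressed on the normalized levels (`y = a0 + a1 x`) and
#' transformed to `(y - a0) / a1`, so a perfectly linear response lies on
#' the identity line and the transform is invariant to affine changes of
#' gain and offset. Flat (non-encoding) responses cannot be normalized.
#'
#' @param levels Offered quantity levels (strictly increasing, >= 3).
#' @param rates Mean firing rate at each level (spikes/s).
#' @return An object of class `normalized_response`: list with `x`, `y`,
#'   `a0`, `a1`.
#' @export
normalize_response <- function(levels, rates) {
  stopifnot(length(levels) == length(rates))
  if (length(levels) < 3) stop("need at least 3 quantity levels")
  if (is.unsorted(levels, strictly = TRUE)) stop("levels must be increasing")
  x <- levels / max(levels)
  co <- stats::coef(stats::lm(rates ~ x))
  if (abs(co[2]) < 1e-8 * (1 + stats::sd(rates))) {
    stop("non-encoding response: regression slope is ~0")
  }
  structure(list(x = x, y = (rates - co[1]) / co[2],
                 a0 = unname(co[1]), a1 = unname(co[2])),
            class = "normalized_response")
}

#' Curvature coefficients of a normalized response
#'
#' Quantifies departure from linearity: `beta2` is the quadratic coefficient
#' from a degree-2 polynomial fit of the normalized points, and `beta3` the
#' cubic coefficient from a separate degree-3 fit (the fits are not
#' nested). Exactly linear responses give `beta2 = beta3 = 0`; both
#' coefficients are invariant to affine transforms of the raw rates.
#'
#' @param norm A `normalized_response` (or any list with `x`, `y`).
#' @return List with `beta2` and `beta3` (`beta3 = NA` with fewer than 4
#'   points).
#' @export
curvature_fit <- function(norm) {
  x <- norm$x; y <- norm$y
  if (length(x) < 3) stop("need at least 3 points for the quadratic fit")
  beta2 <- unname(stats::coef(stats::lm(y ~ x + I(x^2)))[3])
  beta3 <- if (length(x) >= 4) {
    unname(stats::coef(stats::lm(y ~ x + I(x^2) + I(x^3)))[4])
  } else NA_real_
  list(beta2 = beta2, beta3 = beta3)
}

#' Tuning slope versus value range across contexts
#'
#' Range adaptation predicts that a neuron's tuning slope is inversely
#' proportional to the range of values offered in the current context, with
#' proportionality constant equal to the activity range: `slope * range`
#' constant (`~ nu_bar`) under complete adaptation. Regresses the per-context
#' slopes on the reciprocal range and summarizes the product.
#'
#' @param slopes Per-context tuning slopes.
#' @param ranges Per-context value ranges (same length, >= 2 distinct).
#' @return List with `proportionality` (regression coefficient on
#'   `1/range`), `intercept`, `r_squared`, `slope_range_product` (mean of
#'   `slope * range`), and `product_cv` (coefficient of variation of the
#'   product; ~0 under complete adaptation).
#' @export
range_adaptation_check <- function(slopes, ranges) {
  stopifnot(length(slopes) == length(ranges))
  if (length(unique(ranges)) < 2) {
    stop("need at least 2 distinct ranges")
  }
  inv <- 1 / ranges
  fit <- stats::lm(slopes ~ inv)
  prod <- slopes * ranges
  list(proportionality = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared,
       slope_range_product = mean(prod),
       product_cv = stats::sd(prod) / mean(prod))
}
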