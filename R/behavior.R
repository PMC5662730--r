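#' Fit the choice sigmoid of one session
#'
#' Probit regression of the probability of choosing juice B on the log
#' quantity ratio, `X = a0 + a1 * log(q_B / q_A)`. Forced choices (either
#' offer zero) are excluded because the log ratio is undefined there. From
#' the coefficients, the relative value is `rho = exp(-a0/a1)` and the
#' sigmoid steepness is `eta = a1` (the inverse measure of choice
#' variability). Sessions in which the choices are fully ordered by the log
#' ratio ("perfect separation") are flagged; their `rho`/`eta` are returned
#' but unreliable.
#'
#' @param trials Trial table with columns `q_A`, `q_B`, `choice`.
#'
#' @return An object of class `sigmoid_fit`: list with `a0`, `a1`, `se_a0`,
#'   `se_a1`, `rho`, `eta`, `perfect_separation`, `n_binary_trials`,
#'   `n_offer_types`.
#' @export
fit_choice_sigmoid <- function(trials) {
  bin <- trials[trials$q_A > 0 & trials$q_B > 0, ]
  types <- unique(bin[, c("q_A", "q_B")])
  if (nrow(types) < 2) {
    stop("need at least 2 distinct binary offer types to fit a sigmoid")
  }
  lr <- log(bin$q_B / bin$q_A)
  y <- bin$choice == "B"
  # perfect separation: no overlap between the A-chosen and B-chosen ranges
  hi_a <- if (any(!y)) max(lr[!y]) else -Inf
  lo_b <- if (any(y)) min(lr[y]) else Inf
  sep <- hi_a < lo_b || all(y) || all(!y)
  fit <- suppressWarnings(
    stats::glm(y ~ lr, family = stats::binomial(link = "probit")))
  co <- summary(fit)$coefficients
  a0 <- unname(co[1, 1]); a1 <- unname(co[2, 1])
  structure(
    list(a0 = a0, a1 = a1,
         se_a0 = unname(co[1, 2]), se_a1 = unname(co[2, 2]),
         rho = exp(-a0 / a1), eta = a1,
         perfect_separation = sep,
         n_binary_trials = nrow(bin), n_offer_types = nrow(types),
         scaled = FALSE),
    class = "sigmoid_fit"
  )
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf("Probit choice fit: rho=%.3f eta=%.3f (a0=%.3f, a1=%.3f)%s\n",
              x$rho, x$eta, x$a0, x$a1,
              if (x$perfect_separation) " [perfect separation]" else ""))
  invisible(x)
}

#' Rescale the steepness of a fitted sigmoid, keeping the relative value
#'
#' Applies `a1 -> a1 * factor` and `a0 -> a0 * factor`, so that `a0/a1` and
#' hence `rho` are unchanged while `eta` scales by `factor`. Standard errors
#' are invalidated. Used to emulate flatter sigmoids (larger hypothetical
#' value ranges without adaptation).
#'
#' @param fit A `sigmoid_fit`.
#' @param factor Positive scale factor.
#' @return A `sigmoid_fit` with scaled coefficients.
#' @export
scale_steepness <- function(fit, factor) {
  stopifnot(inherits(fit, "sigmoid_fit"), factor > 0)
  fit$a0 <- fit$a0 * factor
  fit$a1 <- fit$a1 * factor
  fit$eta <- fit$a1
  fit$rho <- exp(-fit$a0 / fit$a1)
  if (factor != 1) {
    fit$se_a0 <- NA_real_
    fit$se_a1 <- NA_real_
    fit$scaled <- TRUE
  }
  fit
}

payoff_values <- function(trials, rho) {
  bin <- trials[trials$q_A > 0 & trials$q_B > 0, ]
  if (nrow(bin) < 1) stop("need at least one strictly binary trial")
  v_a <- rho * bin$q_A
  v_b <- bin$q_B
  list(bin = bin, v_a = v_a, v_b = v_b,
       v_max = pmax(v_a, v_b), v_chance = (v_a + v_b) / 2)
}

#' Fractional lost value and percent error of a session
#'
#' On strictly binary trials (forced choices excluded), each offer is valued
#' in units of juice B: `value_A = rho * q_A`, `value_B = q_B`. The
#' fractional lost value is
#' `FLV = <max value - chosen value> / <max value - chance value>`, where
#' `<.>` averages across trials before taking the ratio and the chance value
#' is the midpoint of the two offer values. FLV is 0 for a subject that
#' always takes the higher value and 1 for random choosing; it quantifies
#' the fraction of available value lost to choice variability. The percent
#' error is the percentage of binary trials in which the lower value was
#' chosen, excluding exact value ties (where no lower value exists; ties
#' still enter FLV with zero loss).
#'
#' @param trials Trial table.
#' @param rho Relative value used to place both juices on a common scale.
#'
#' @return An object of class `payoff_summary` with `flv`, `percent_error`,
#'   `mean_chosen_value`, `mean_max_value`, `mean_chance_value`,
#'   `n_trials_used`.
#' @export
compute_payoff_metrics <- function(trials, rho) {
  stopifnot(rho > 0)
  pv <- payoff_values(trials, rho)
  chosen <- ifelse(pv$bin$choice == "A", pv$v_a, pv$v_b)
  denom <- mean(pv$v_max - pv$v_chance)
  if (denom <= 0) {
    stop("FLV undefined: all offers lie on the indifference line")
  }
  tie <- pv$v_a == pv$v_b
  structure(
    list(flv = mean(pv$v_max - chosen) / denom,
         percent_error = 100 * mean(chosen[!tie] < pv$v_max[!tie]),
         mean_chosen_value = mean(chosen),
         mean_max_value = mean(pv$v_max),
         mean_chance_value = mean(pv$v_chance),
         n_trials_used = nrow(pv$bin)),
    class = "payoff_summary"
  )
}

#' Expected fractional lost value of a session under a fitted sigmoid
#'
#' Replaces the realized chosen value with its expectation under the fitted
#' choice probabilities: on each binary trial,
#' `E(chosen value) = P_A * value_A + P_B * value_B` with `P_B` from the
#' probit sigmoid evaluated at the trial's log quantity ratio. The EFLV is
#' the FLV with this expectation substituted for the chosen value. Values
#' are computed with the fit's own relative value.
#'
#' @param trials Trial table.
#' @param fit A `sigmoid_fit`; must not be flagged for perfect separation.
#'
#' @return A `payoff_summary` whose `flv` field holds the EFLV.
#' @export
compute_eflv <- function(trials, fit) {
  stopifnot(inherits(fit, "sigmoid_fit"))
  if (isTRUE(fit$perfect_separation)) {
    stop("EFLV unreliable under perfect separation")
  }
  pv <- payoff_values(trials, fit$rho)
  p_b <- stats::pnorm(fit$a0 + fit$a1 * log(pv$bin$q_B / pv$bin$q_A))
  e_chosen <- (1 - p_b) * pv$v_a + p_b * pv$v_b
  denom <- mean(pv$v_max - pv$v_chance)
  if (denom <= 0) {
    stop("FLV undefined: all offers lie on the indifference line")
  }
  structure(
    list(flv = mean(pv$v_max - e_chosen) / denom,
         percent_error = NA_real_,
         mean_chosen_value = mean(e_chosen),
         mean_max_value = mean(pv$v_max),
         mean_chance_value = mean(pv$v_chance),
         n_trials_used = nrow(pv$bin)),
    class = "payoff_summary"
  )
}

#' Errors-in-variables (Deming) straight-line fit
#'
#' Closed-form Deming regression of `y` on `x` when both variables carry
#' measurement error, governed by `lambda`, the ratio of the y-error
#' variance to the x-error variance. `lambda = 1` gives orthogonal (total
#' least squares) regression; `lambda -> Inf` recovers ordinary least
#' squares of y on x.
#'
#' @param x,y Numeric vectors (>= 3 points).
#' @param lambda Positive error-variance ratio var(y errors)/var(x errors).
#'
#' @return List with `slope`, `intercept`, `lambda`, and `degenerate`
#'   (`TRUE` when the covariance is zero and the solution is a vertical
#'   line, reported with `slope = Inf`).
#' @export
deming_regression <- function(x, y, lambda = 1) {
  stopifnot(length(x) == length(y), length(x) >= 3, lambda > 0)
  sxx <- stats::var(x); syy <- stats::var(y); sxy <- stats::cov(x, y)
  if (sxy == 0) {
    if (syy > lambda * sxx) {
      return(list(slope = Inf, intercept = NA_real_, lambda = lambda,
                  degenerate = TRUE))
    }
    return(list(slope = 0, intercept = mean(y), lambda = lambda,
                degenerate = syy == lambda * sxx))
  }
  b <- (syy - lambda * sxx +
          sqrt((syy - lambda * sxx)^2 + 4 * lambda * sxy^2)) / (2 * sxy)
  list(slope = b, intercept = mean(y) - b * mean(x), lambda = lambda,
       degenerate = FALSE)
}

#' Error-variance ratio for the steepness-vs-range regression
#'
#' Propagates the probit-fit standard errors into the variance ratio
#' `lambda = var(eta) / var(Delta)` needed by the Deming regression of the
#' sigmoid steepness `eta` on the geometric mean value range
#' `Delta = (rho * Q_A * Q_B)^(1/2)`:
#' `lambda = 4 a1^4 (se_a1)^2 / (rho Q_A Q_B (a0 se_a1 - a1 se_a0)^2)`,
#' with `rho` taken from the same fit.
#'
#' @param fit A `sigmoid_fit` with valid standard errors.
#' @param Q_A,Q_B Session quantity ranges (> 0).
#' @return The scalar variance ratio `lambda`.
#' @export
variance_ratio <- function(fit, Q_A, Q_B) {
  stopifnot(inherits(fit, "sigmoid_fit"), Q_A > 0, Q_B > 0)
  if (!is.finite(fit$se_a0) || !is.finite(fit$se_a1)) {
    stop("fit has no valid standard errors")
  }
  den <- fit$rho * Q_A * Q_B * (fit$a0 * fit$se_a1 - fit$a1 * fit$se_a0)^2
  if (den == 0) stop("lambda undefined (zero denominator)")
  4 * fit$a1^4 * fit$se_a1^2 / den
}

delta_value_range <- function(rho, Q_A, Q_B,
                              variant = c("geometric", "mean",
                                          "log_geometric")) {
  variant <- match.arg(variant)
  switch(variant,
         geometric = sqrt(rho * Q_A * Q_B),
         mean = (rho * Q_A + Q_B) / 2,
         log_geometric = log(rho * Q_A * Q_B) / 2)
}

#' Relation between sigmoid steepness and value range across sessions
#'
#' Tests the optimal-coding prediction that choice variability grows with
#' the range of values in play: across sessions, the steepness `eta` should
#' decrease with the geometric mean value range
#' `Delta = (rho Q_A Q_B)^(1/2)`. Reports the Pearson correlation with its
#' test, a Deming regression of `eta` on `Delta` (using the median of the
#' per-session error-variance ratios when supplied), and, for each session
#' set with at least `min_set_size` sessions, the stepwise coefficient
#' `beta_eta` obtained by regressing `eta` on `rho` and then the residuals
#' on `Delta` (the range effect not explained by fluctuations of `rho`).
#'
#' @param records Data frame with columns `rho`, `eta`, `Q_A`, `Q_B`, and
#'   optionally `lambda` (per-session variance ratios) and `set` (session
#'   set label, e.g. animal x juice pair).
#' @param delta_variant Definition of the value-range scale: geometric mean
#'   (default), simple mean `(rho Q_A + Q_B)/2`, or log geometric mean
#'   `log(rho Q_A Q_B)/2`.
#' @param min_set_size Minimum sessions per set for the per-set analysis.
#'
#' @return List with `delta`, `correlation`, `cor_p`, `deming`, `per_set`
#'   (data frame of `beta_eta` per set), `delta_variant`.
#' @export
steepness_range_analysis <- function(records,
                                     delta_variant = c("geometric", "mean",
                                                       "log_geometric"),
                                     min_set_size = 5) {
  delta_variant <- match.arg(delta_variant)
  stopifnot(all(c("rho", "eta", "Q_A", "Q_B") %in% names(records)))
  delta <- delta_value_range(records$rho, records$Q_A, records$Q_B,
                             delta_variant)
  ct <- stats::cor.test(delta, records$eta)
  lam <- if ("lambda" %in% names(records)) {
    stats::median(records$lambda[is.finite(records$lambda)])
  } else 1
  dem <- deming_regression(delta, records$eta, lambda = lam)
  sets <- if ("set" %in% names(records)) records$set else rep("all", nrow(records))
  per_set <- do.call(rbind, lapply(split(seq_len(nrow(records)), sets), function(i) {
    if (length(i) < min_set_size) return(NULL)
    r1 <- stats::lm(records$eta[i] ~ records$rho[i])
    r2 <- stats::lm(stats::resid(r1) ~ delta[i])
    data.frame(set = sets[i[1]], n = length(i),
               beta_eta = unname(stats::coef(r2)[2]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(per_set) || nrow(per_set) == 0) {
    stop(sprintf("no session set has >= %d sessions", min_set_size))
  }
  list(delta = delta, correlation = unname(ct$estimate), cor_p = ct$p.value,
       deming = dem, per_set = per_set, delta_variant = delta_variant)
}

#' Mean EFLV of a session ensemble under rescaled sigmoid steepness
#'
#' For each session the fitted sigmoid's steepness is multiplied by each
#' factor (relative value fixed) and the expected fractional lost value is
#' recomputed; the mean across sessions traces how the expected payoff
#' degrades as choice variability grows (the simulated cost of losing range
#' adaptation).
#'
#' @param sessions List of lists with elements `trials` and `fit`.
#' @param factors Steepness scale factors to evaluate.
#' @return Data frame with columns `factor` and `mean_eflv`.
#' @export
steepness_reduction <- function(sessions, factors = c(1, 0.5, 0.1)) {
  stopifnot(length(sessions) >= 1)
  mean_eflv <- vapply(factors, function(f) {
    mean(vapply(sessions, function(s) {
      compute_eflv(s$trials, scale_steepness(s$fit, f))$flv
    }, numeric(1)))
  }, numeric(1))
  data.frame(factor = factors, mean_eflv = mean_eflv)
}

#' Calibrate a global steepness scale to a target baseline mean EFLV
#'
#' Finds the common factor `s` such that scaling every session's fitted
#' steepness by `s` yields the requested ensemble mean EFLV. Used to anchor
#' a synthetic ensemble to an empirically observed baseline before
#' steepness-reduction simulations.
#'
#' @param sessions List of lists with elements `trials` and `fit`.
#' @param target Target baseline mean EFLV.
#' @param interval Search interval for the scale factor.
#' @return The scale factor `s`.
#' @export
calibrate_steepness_scale <- function(sessions, target = 0.054,
                                      interval = c(0.02, 50)) {
  f <- function(s) steepness_reduction(sessions, s)$mean_eflv - target
  stats::uniroot(f, interval = interval, tol = 1e-6)$root
}
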