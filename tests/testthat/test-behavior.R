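test_that("probit fit returns the exact (rho, eta) identities and flags separation", {
  tr <- fixture_session(rho = 1, eta = 2, Q_A = 5, Q_B = 5, seed = 21)
  fit <- fit_choice_sigmoid(tr)
  expect_equal(fit$rho, exp(-fit$a0 / fit$a1))
  expect_identical(fit$eta, fit$a1)
  expect_lt(abs(fit$rho - 1), 0.2)

  # deterministic choices at every offered ratio: perfect separation
  tr2 <- manual_trials(q_A = rep(c(1, 1, 2, 1), 10),
                       q_B = rep(c(8, 9, 1, 10), 10),
                       choice = rep(c("B", "B", "A", "B"), 10))
  expect_true(fit_choice_sigmoid(tr2)$perfect_separation)

  expect_error(fit_choice_sigmoid(manual_trials(1, 2, "B")), "offer types")
})

test_that("FLV matches hand-enumerated values and its limits", {
  toy <- manual_trials(q_A = c(1, 1, 1), q_B = c(1, 3, 6),
                       choice = c("B", "B", "A"))
  pm <- compute_payoff_metrics(toy, rho = 2)
  # values A: 2,2,2; B: 1,3,6; max 2,3,6; chosen 1,3,2; chance 1.5,2.5,4
  expect_equal(pm$flv, ((2 - 1) + 0 + (6 - 2)) / 3 /
                 (((2 - 1.5) + (3 - 2.5) + (6 - 4)) / 3))
  expect_equal(pm$percent_error, 100 * 2 / 3)

  # always choosing the higher value: FLV = 0
  best <- manual_trials(q_A = c(1, 1, 2), q_B = c(1, 5, 1),
                        choice = c("A", "B", "A"))
  expect_equal(compute_payoff_metrics(best, rho = 2)$flv, 0)

  # random choices at large n: FLV -> 1
  set.seed(1)
  n <- 20000
  qa <- sample(1:3, n, TRUE); qb <- sample(1:8, n, TRUE)
  rnd <- manual_trials(qa, qb, sample(c("A", "B"), n, TRUE))
  expect_lt(abs(compute_payoff_metrics(rnd, rho = 2)$flv - 1), 0.05)

  # invariance to rescaling all values by a positive constant
  expect_equal(compute_payoff_metrics(toy, rho = 2)$flv,
               {
                 toy2 <- toy; toy2$q_B <- toy$q_B * 3
                 compute_payoff_metrics(toy2, rho = 6)$flv
               })

  # all offers on the indifference line: undefined
  tie <- manual_trials(c(1, 2), c(2, 4), c("A", "B"))
  expect_error(compute_payoff_metrics(tie, rho = 2), "undefined")
})

test_that("EFLV limits and convergence to FLV", {
  tr <- fixture_session(rho = 2.5, eta = 3, n_trials = 20000, seed = 31)
  fit <- fit_choice_sigmoid(tr)
  flv <- compute_payoff_metrics(tr, fit$rho)$flv
  eflv <- compute_eflv(tr, fit)$flv
  expect_lt(abs(eflv - flv), 0.25 * max(flv, 0.02))

  # eta -> infinity: EFLV -> 0 ; eta -> 0: EFLV -> 1
  expect_lt(compute_eflv(tr, scale_steepness(fit, 50))$flv, 0.01)
  expect_lt(abs(compute_eflv(tr, scale_steepness(fit, 1e-4))$flv - 1), 0.01)

  sep <- fit; sep$perfect_separation <- TRUE
  expect_error(compute_eflv(tr, sep), "separation")
})

test_that("steepness rescaling keeps rho and is monotone in EFLV", {
  tr <- fixture_session(seed = 41)
  fit <- fit_choice_sigmoid(tr)
  expect_equal(scale_steepness(fit, 1), fit)
  half <- scale_steepness(fit, 0.5)
  expect_equal(half$rho, fit$rho)
  expect_equal(half$eta, fit$eta / 2)
  expect_true(is.na(half$se_a1))

  fs <- seq(0.1, 1, by = 0.1)
  eflv <- vapply(fs, function(f) {
    compute_eflv(tr, scale_steepness(fit, f))$flv
  }, numeric(1))
  expect_true(all(diff(eflv) <= 1e-12))
})

test_that("Deming regression: exact line, TLS oracle at lambda 1, OLS and swap limits", {
  x <- c(0, 1, 2, 3.5, 5)
  y <- 2 * x + 1
  for (lam in c(0.25, 1, 4)) {
    d <- deming_regression(x, y, lam)
    expect_equal(d$slope, 2, tolerance = 1e-10)
    expect_equal(d$intercept, 1, tolerance = 1e-10)
  }

  set.seed(2)
  xn <- x + rnorm(5, 0, 0.3); yn <- y + rnorm(5, 0, 0.3)
  d1 <- deming_regression(xn, yn, 1)
  # orthogonal-regression oracle via eigen-decomposition of the covariance
  ev <- eigen(stats::cov(cbind(xn, yn)))$vectors[, 1]
  expect_equal(d1$slope, ev[2] / ev[1], tolerance = 1e-8)

  # lambda -> Inf recovers OLS of y on x
  dInf <- deming_regression(xn, yn, 1e10)
  expect_equal(dInf$slope, unname(coef(lm(yn ~ xn))[2]), tolerance = 1e-5)

  # swapping axes with lambda -> 1/lambda inverts the line
  d <- deming_regression(xn, yn, 0.5)
  dsw <- deming_regression(yn, xn, 2)
  expect_equal(dsw$slope, 1 / d$slope, tolerance = 1e-8)
  expect_equal(dsw$intercept, -d$intercept / d$slope, tolerance = 1e-6)
})

test_that("error-propagation variance ratio matches direct substitution and Monte Carlo", {
  fit <- structure(list(a0 = -2, a1 = 1, se_a0 = 0, se_a1 = 0.1,
                        rho = exp(2), eta = 1, perfect_separation = FALSE),
                   class = "sigmoid_fit")
  # 4 a1^4 se1^2 / (rho QA QB (a0 se1 - a1 se0)^2) = 1 / (8 e^2)
  expect_equal(variance_ratio(fit, 2, 4), 1 / (8 * exp(2)))

  fit0 <- fit; fit0$se_a0 <- NA_real_
  expect_error(variance_ratio(fit0, 2, 4), "standard errors")
  fitz <- fit; fitz$se_a1 <- 0
  expect_error(variance_ratio(fitz, 2, 4), "zero denominator")

  # first-order error-propagation oracle: the ratio propagates the total
  # differential of (a0, a1), i.e. a common perturbation of both
  # coefficients with their respective standard errors
  set.seed(3)
  a0 <- -2; a1 <- 3; s0 <- 0.01; s1 <- 0.015; Q_A <- 3; Q_B <- 8
  z <- rnorm(40000)
  draws0 <- a0 + s0 * z; draws1 <- a1 + s1 * z
  eta_mc <- draws1
  delta_mc <- sqrt(exp(-draws0 / draws1) * Q_A * Q_B)
  lam_mc <- var(eta_mc) / var(delta_mc)
  fit2 <- structure(list(a0 = a0, a1 = a1, se_a0 = s0, se_a1 = s1,
                         rho = exp(-a0 / a1), eta = a1,
                         perfect_separation = FALSE),
                    class = "sigmoid_fit")
  expect_equal(variance_ratio(fit2, Q_A, Q_B), lam_mc, tolerance = 0.05)
})

test_that("steepness-range analysis finds the model-implied negative relation", {
  set.seed(4)
  # sessions generated under optimal coding: eta from the decision model at
  # the finite-pool noise level
  chi_b <- chi_effective(200, 0.01, duration = 0.5)
  recs <- do.call(rbind, lapply(1:24, function(i) {
    rho <- exp(runif(1, log(1.5), log(3.5)))
    Q_A <- sample(2:4, 1)
    Q_B <- min(10, max(2, round(rho * Q_A) + sample(-1:1, 1)))
    data.frame(rho = rho, Q_A = Q_A, Q_B = Q_B,
               eta = optimal_session_eta(rho, Q_A, Q_B, chi = chi_b) *
                 exp(rnorm(1, 0, 0.05)),
               set = paste0("set", (i - 1) %% 2 + 1))
  }))
  res <- steepness_range_analysis(recs)
  expect_lt(res$correlation, 0)
  expect_lt(res$cor_p, 0.05)
  expect_lt(res$deming$slope, 0)

  # all delta variants agree in sign
  for (v in c("mean", "log_geometric")) {
    expect_lt(steepness_range_analysis(recs, delta_variant = v)$correlation, 0)
  }

  # null control: eta independent of delta gives no systematic relation
  recs0 <- recs
  set.seed(8)
  recs0$eta <- rlnorm(nrow(recs0), log(3), 0.2)
  res0 <- steepness_range_analysis(recs0)
  expect_lt(abs(res0$correlation), 2.5 / sqrt(nrow(recs0) - 3))

  expect_error(steepness_range_analysis(recs[1:3, ]), ">= 5")
})
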