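test_that("analytic choice probability: frozen value, symmetry, limits, invariances", {
  m <- decision_model(t_A = 1, t_B = 1, chi = 0.0025)
  # z = -0.5 / sqrt(0.0025 * 10.5) = -3.086
  expect_equal(choice_probability(5, 5.5, m), pnorm(-0.5 / sqrt(0.02625)),
               tolerance = 1e-12)
  expect_equal(choice_probability(5, 5.5, m), 0.001014116, tolerance = 1e-6)

  # equal drives: P = 0.5; origin convention
  expect_equal(choice_probability(2, 2, m), 0.5)
  expect_equal(choice_probability(0, 0, m), 0.5)

  # P(A) + P(B) = 1 and invariance under common K scaling
  qa <- c(0, 1, 2, 3); qb <- c(2, 1, 0, 3)
  p <- choice_probability(qa, qb, m)
  expect_equal(p + (1 - p), rep(1, 4))
  m2 <- m; m2$K_A <- 7 * m$K_A; m2$K_B <- 7 * m$K_B
  expect_equal(choice_probability(qa, qb, m2), p)

  # deterministic limit
  m0 <- decision_model(t_A = 1, t_B = 1, chi = 0)
  expect_equal(choice_probability(3, 2, m0), 1)
  expect_equal(choice_probability(2, 3, m0), 0)

  # monotonicity in each offer at small chi
  grid <- seq(0.5, 5, by = 0.5)
  for (chi in c(0.0025, 0.001)) {
    mc <- decision_model(t_A = 1, t_B = 1, chi = chi)
    expect_true(all(diff(choice_probability(grid, 2, mc)) >= 0))
    expect_true(all(diff(choice_probability(2, grid, mc)) <= 0))
  }
})

test_that("Monte-Carlo pooled-Poisson decision matches the analytic probit", {
  nu <- 5
  mdl <- decision_model(t_A = nu / 5, t_B = nu / 10, K_A = 1, K_B = 1,
                        n = 100, xi = 0.01, nu_bar = nu)
  ma <- mdl; ma$chi <- chi_effective(100, 0.01, duration = 2)
  for (q in list(c(2, 4), c(2, 4.4), c(1, 2.2), c(3, 5.5))) {
    pe <- monte_carlo_decision(q[1], q[2], mdl, reps = 10000, duration = 2,
                               seed = 17)
    pa <- choice_probability(q[1], q[2], ma)
    se <- sqrt(max(pa * (1 - pa), 1e-6) / 10000)
    expect_lt(abs(pe - pa), 3.5 * se + 0.002)
  }
  # forced choice
  expect_gt(monte_carlo_decision(2, 0, mdl, reps = 1000, seed = 1), 0.999)
})

test_that("expected payoff respects the chance and maximum bounds", {
  g <- offer_grid(5, 10, 2, n_steps = 11)
  chance <- sum(g$weight * (2 * g$q_A + g$q_B) / 2)
  maxv <- sum(g$weight * pmax(2 * g$q_A, g$q_B))
  m <- decision_model(t_A = 1 / 5, t_B = 1 / 10, chi = 0.0025)
  pay <- expected_payoff(g, m)
  expect_gt(pay, chance)
  expect_lte(pay, maxv + 1e-12)

  # deterministic limit attains the maximum
  m0 <- decision_model(t_A = 1 / 5, t_B = 1 / 10, chi = 0)
  expect_equal(expected_payoff(g, m0), maxv, tolerance = 1e-12)

  # zero tuning: both drives zero, P = 0.5 everywhere -> chance value
  mr <- decision_model(t_A = 0, t_B = 0, chi = 0.0025)
  expect_equal(expected_payoff(g, mr), chance, tolerance = 1e-12)
})

test_that("optimal tuning slopes sit on the complete-adaptation boundary", {
  cases <- list(c(rho = 2, Q_A = 5, Q_B = 10, chi = 0.0025),
                c(rho = 3, Q_A = 3, Q_B = 9, chi = 0.0025),
                c(rho = 1.5, Q_A = 4, Q_B = 6, chi = 0.01 / 4),
                c(rho = 2, Q_A = 5, Q_B = 10, chi = 0.01))
  for (cs in cases) {
    g <- offer_grid(cs[["Q_A"]], cs[["Q_B"]], cs[["rho"]], n_steps = 11)
    m <- decision_model(t_A = 1, t_B = 1, chi = cs[["chi"]], nu_bar = 1)
    opt <- optimize_tuning(g, m, n_search = 11)
    expect_gt(opt$f_A, 0.99)
    expect_gt(opt$f_B, 0.99)
  }

  # payoff non-decreasing along a common scaling of the slopes
  g <- offer_grid(5, 10, 2, n_steps = 11)
  m <- decision_model(t_A = 1, t_B = 1, chi = 0.0025)
  pays <- vapply(seq(0.1, 1, by = 0.1), function(f) {
    mf <- m; mf$t_A <- f / 5; mf$t_B <- f / 10
    expected_payoff(g, mf)
  }, numeric(1))
  expect_true(all(diff(pays) >= -1e-12))
})

test_that("adaptation scenarios rank complete > partial > none", {
  g <- offer_grid(5, 10, 2, n_steps = 11)
  m <- decision_model(t_A = 1, t_B = 1, chi = 0.0025, nu_bar = 1)
  sc <- adaptation_scenario_payoffs(g, m, Q_wide = 40)
  pay <- setNames(sc$payoff, sc$scenario)
  expect_gt(pay[["complete"]], pay[["partial"]])
  expect_gt(pay[["partial"]], pay[["none"]])
})

test_that("efficacy optimization: symmetric optimum, asymmetric bias, chi scaling", {
  # symmetric case rho Q_A = Q_B: ratio 1, indifference at rho
  g <- offer_grid(5, 10, 2, n_steps = 11)
  m <- decision_model(t_A = 1 / 5, t_B = 1 / 10, chi = 0.0025)
  opt <- optimize_efficacies(g, m)
  expect_lt(abs(opt$ratio - 1), 0.01)
  expect_lt(abs(opt$indifference - 2), 0.05)

  # asymmetric case: ratio ~ rho Q_A / Q_B, bias favors the larger range
  g2 <- offer_grid(3, 4, 3, n_steps = 21)   # value ranges 9 vs 4: A larger
  m2 <- decision_model(t_A = 1 / 3, t_B = 1 / 4, chi = 0.0025)
  o2 <- optimize_efficacies(g2, m2)
  expect_lt(abs(o2$ratio / (3 * 3 / 4) - 1), 0.1)
  expect_gt(o2$bias, 0)

  g3 <- offer_grid(8, 4, 0.75, n_steps = 21) # value ranges 6 vs 4: A larger
  m3 <- decision_model(t_A = 1 / 8, t_B = 1 / 4, chi = 0.0025)
  expect_gt(optimize_efficacies(g3, m3)$bias, 0)

  # bias magnitude decreases as chi -> 0
  bias <- vapply(c(0.01, 0.001, 1e-4) / 4, function(chi) {
    mc <- decision_model(t_A = 1 / 3, t_B = 1 / 4, chi = chi)
    abs(optimize_efficacies(g2, mc)$bias)
  }, numeric(1))
  expect_true(all(diff(bias) < 0))
})

test_that("model-implied sigmoid steepness falls with the value range", {
  # doubling both ranges at fixed rho lowers eta
  e1 <- optimal_session_eta(2, 3, 6)
  e2 <- optimal_session_eta(2, 6, 12)
  expect_lt(e2, e1)

  # monotone decrease along a sweep of Delta = sqrt(rho Q_A Q_B)
  etas <- vapply(1:5, function(k) optimal_session_eta(2, 2 * k, 4 * k),
                 numeric(1))
  expect_true(all(diff(etas) < 0))

  # uncorrected adaptation: doubling the B range doubles the indifference
  # point (the bias that synaptic rescaling must prevent)
  m_b5 <- decision_model(t_A = 1 / 2, t_B = 1 / 5, chi = 0.0025)
  m_b10 <- decision_model(t_A = 1 / 2, t_B = 1 / 10, chi = 0.0025)
  ind <- function(m) m$K_A * m$t_A / (m$K_B * m$t_B)
  expect_equal(ind(m_b5), 2.5)
  expect_equal(ind(m_b10), 5)

  expect_error(
    model_sigmoid_steepness(m_b5, offer_grid(2, 5, 2.5, offers = data.frame(
      q_A = c(1, 2), q_B = c(2, 4)))),
    "degenerate")
})
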