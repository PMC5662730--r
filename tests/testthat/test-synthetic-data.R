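test_that("session generation is deterministic and covers the design", {
  cfg <- session_config(Q_A = 3, Q_B = 10, rho = 4.1, eta = 2,
                        n_trials = 250, seed = 1)
  tr <- generate_exp1_session(cfg)
  expect_equal(nrow(tr), 250)
  expect_identical(tr, generate_exp1_session(cfg))

  # forced choices present for both juices, and always taken
  expect_gt(sum(tr$q_B == 0), 0)
  expect_gt(sum(tr$q_A == 0), 0)
  expect_true(all(tr$choice[tr$q_B == 0] == "A"))
  expect_true(all(tr$choice[tr$q_A == 0] == "B"))
  expect_false(any(tr$q_A == 0 & tr$q_B == 0))

  # most binary offer types contain a quantity-1 offer
  types <- unique(tr[tr$q_A > 0 & tr$q_B > 0, c("q_A", "q_B")])
  expect_gte(mean(types$q_A == 1 | types$q_B == 1), 0.9)

  # low quantity levels over-represented relative to high ones
  expect_gt(sum(tr$q_B == 1), sum(tr$q_B == max(tr$q_B)))
})

test_that("generated choices follow the requested probit parameters", {
  cfg <- session_config(Q_A = 3, Q_B = 10, rho = 4.1, eta = 2,
                        n_trials = 250, seed = 1)
  fit <- fit_choice_sigmoid(generate_exp1_session(cfg))
  expect_lt(abs(fit$rho - 4.1), 2 * 4.1 * (abs(fit$se_a0 / fit$a1) +
                                             abs(fit$a0 * fit$se_a1 / fit$a1^2)))
  # near-deterministic steepness: every binary choice picks the higher value
  cfg2 <- session_config(Q_A = 3, Q_B = 10, rho = 2, eta = 50,
                         n_trials = 400, seed = 3)
  tr2 <- generate_exp1_session(cfg2)
  bin <- tr2[tr2$q_A > 0 & tr2$q_B > 0 & 2 * tr2$q_A != tr2$q_B, ]
  expect_true(all(ifelse(bin$q_B > 2 * bin$q_A, "B", "A") == bin$choice))
})

test_that("refitting recovers (rho, eta) with shrinking bias as n grows", {
  err <- vapply(c(250, 2500, 25000), function(n) {
    fits <- lapply(1:4, function(s) {
      cfg <- session_config(Q_A = 3, Q_B = 8, rho = 2.5, eta = 2,
                            n_trials = n, seed = 100 + s)
      fit_choice_sigmoid(generate_exp1_session(cfg))
    })
    mean(abs(vapply(fits, `[[`, numeric(1), "rho") - 2.5))
  }, numeric(1))
  expect_lt(err[3], err[1])
  expect_lt(err[3], 0.1)
})

test_that("range-manipulation sessions change one range by exactly two and stay balanced", {
  cfg <- session_config(Q_A = 4, Q_B = 8, rho = 2.2, eta = 3,
                        n_trials = 180, seed = 5)
  tr <- generate_exp2_session(cfg, "B_doubled")
  rng <- attr(tr, "ranges")
  expect_equal(rng$block2[["B"]] / rng$block1[["B"]], 2)
  expect_equal(rng$block2[["A"]], rng$block1[["A"]])
  b1 <- tr[tr$block == 1, ]; b2 <- tr[tr$block == 2, ]
  expect_true(nrow(b2) >= 110 && nrow(b2) <= 260)
  r1 <- sum(b1$choice == "A") / sum(b1$choice == "B")
  r2 <- sum(b2$choice == "A") / sum(b2$choice == "B")
  expect_lt(abs(r2 / r1 - 1), 0.05)
  d1 <- sum(b1$q_A[b1$choice == "A"]) / sum(b1$q_B[b1$choice == "B"])
  d2 <- sum(b2$q_A[b2$choice == "A"]) / sum(b2$q_B[b2$choice == "B"])
  expect_lt(abs(d2 / d1 - 1), 0.05)

  expect_error(
    generate_exp2_session(session_config(Q_A = 1, Q_B = 4, n_trials = 120,
                                         seed = 1), "A_halved"),
    "halved")
})

test_that("spike counts have the requested means and noise correlations", {
  tr <- fixture_session(n_trials = 600, seed = 8)
  # slope 0: i.i.d. Poisson at baseline
  sp0 <- neuron_spec("B", baseline = 10, slope = 0)
  ct0 <- generate_neuron_counts(tr, sp0, xi = 0, duration = 0.5, seed = 2)
  expect_lt(abs(mean(ct0$count) - 10 * 0.5), 3 * sqrt(5 / nrow(ct0)))

  # pairwise correlations match xi within Monte-Carlo error
  specs <- replicate(40, neuron_spec("B", baseline = 8, slope = 2),
                     simplify = FALSE)
  for (xi in c(0, 0.05)) {
    ct <- generate_neuron_counts(tr, specs, xi = xi, duration = 0.5,
                                 seed = 3)
    m <- matrix(ct$count, nrow = nrow(tr))
    # remove the signal component (common tuning) by residualizing on q_B
    r <- apply(m, 2, function(col) stats::resid(stats::lm(col ~ tr$q_B)))
    cc <- stats::cor(r)
    mean_off <- mean(cc[upper.tri(cc)])
    if (xi == 0) {
      expect_lt(abs(mean_off), 0.01)
    } else {
      expect_gt(mean_off, xi - 0.01)
      expect_lt(mean_off, xi + 0.01)
    }
  }

  expect_error(
    generate_neuron_counts(tr, neuron_spec("B", baseline = 0, slope = -2),
                           seed = 1),
    "negative")
})

test_that("mixed populations carry recoverable labels and degenerate inputs work", {
  tr <- fixture_session(seed = 9)
  pop <- generate_mixed_population(
    tr, c("offer A" = 3, "chosen juice" = 3), rho = 2.5,
    noise_sd = 0.2, seed = 4)
  expect_equal(nrow(pop$labels), 6)
  expect_setequal(unique(pop$labels$variable), c("offer A", "chosen juice"))
  expect_true(all(pop$counts$count >= 0))

  empty <- generate_mixed_population(tr, integer(0), rho = 2.5)
  expect_equal(nrow(empty$counts), 0)

  expect_error(
    generate_mixed_population(tr, c("not a variable" = 2), rho = 2.5),
    "unknown")
})

test_that("the session ensemble returns usable fitted sessions", {
  ens <- exp1_session_ensemble(25, seed = 7)
  expect_gt(length(ens), 15)
  expect_true(all(vapply(ens, function(s) !s$fit$perfect_separation,
                         logical(1))))
  expect_true(all(vapply(ens, function(s) s$fit$a1 > 0, logical(1))))
})
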