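make_bundle <- function(trials, rho) {
  orf_bundle(trials, rho, uniform = fixture_orf_uniform())
}

test_that("the variable table has exactly 20 well-defined columns", {
  tr <- fixture_session(rho = 2, seed = 51)
  vars <- build_variables(tr, rho = 2, orf_bundle = make_bundle(tr, 2))
  expect_identical(setdiff(names(vars),
                           c("q_A", "q_B", "choice", "n_trials")),
                   encoding_variable_names())

  # hand-checked arithmetic for trial type (1, 3, B) at rho = 2
  row <- vars[vars$q_A == 1 & vars$q_B == 3 & vars$choice == "B", ]
  expect_equal(row[["offer A"]], 2)
  expect_equal(row[["offer B"]], 3)
  expect_equal(row[["chosen value"]], 3)
  expect_equal(row[["other value"]], 2)
  expect_equal(row[["total value"]], 5)
  expect_equal(row[["value difference"]], -1)
  expect_equal(row[["value ratio"]], 1.5)
  expect_equal(row[["chosen juice"]], 1)

  # forced choice: offer A variable is zero, value ratio undefined
  fb <- vars[vars$q_A == 0, ][1, ]
  expect_equal(fb[["offer A"]], 0)
  expect_true(is.na(fb[["value ratio"]]))

  expect_error(build_variables(tr, 2, orf_bundle = NULL), "orf_bundle")
})

test_that("the ANOVA screen keeps offer-type-tuned neurons and drops spatial ones", {
  tr <- fixture_session(rho = 2, seed = 52, n_trials = 400)
  # one offer-value neuron, one position-tuned neuron, one noise neuron
  sp <- list(neuron_spec("B", baseline = 2, slope = 6),
             neuron_spec("B", baseline = 10, slope = 0),
             neuron_spec("B", baseline = 10, slope = 0))
  ct <- generate_neuron_counts(tr, sp, xi = 0, duration = 0.5, seed = 5)
  # make neuron 2 position-tuned instead
  pos <- ct$neuron_id == 2
  ct$count[pos] <- rpois(sum(pos),
                         ifelse(tr$position_A[ct$trial_id[pos]] == "left",
                                12, 3) * 0.5)
  scr <- anova_screen(ct, tr, alpha = 0.001)
  expect_true(scr$task_related[scr$neuron_id == 1])
  expect_false(scr$task_related[scr$neuron_id == 2])
  expect_false(scr$task_related[scr$neuron_id == 3])
})

test_that("ANOVA screen type-I rate on pure-noise neurons is near alpha", {
  tr <- fixture_session(rho = 2, seed = 53, n_trials = 250)
  sp <- replicate(300, neuron_spec("B", baseline = 10, slope = 0),
                  simplify = FALSE)
  ct <- generate_neuron_counts(tr, sp, xi = 0, duration = 0.5, seed = 6)
  scr <- anova_screen(ct, tr, alpha = 0.05)
  rate <- mean(scr$task_related)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 300) + 0.01)
})

test_that("regressions identify the generating variable and calibrate on noise", {
  tr <- fixture_session(rho = 2, seed = 54, n_trials = 400)
  bundle <- make_bundle(tr, 2)
  vars <- build_variables(tr, 2, bundle)
  pop <- generate_mixed_population(tr, c("offer A" = 4), rho = 2,
                                   orf_bundle = bundle, noise_sd = 0.3,
                                   gain = 30, seed = 7)
  rm <- response_means(pop$counts, tr)
  res <- suppressWarnings(regress_all(rm, vars))
  best <- res[res$best_fit, ]
  expect_true(all(best$variable == "offer A"))

  # determinism under re-run
  res2 <- suppressWarnings(regress_all(rm, vars))
  expect_identical(res, res2)

  # noise-only responses: about 5% of variables explain by chance
  noise <- generate_mixed_population(tr, c("offer A" = 40), rho = 2,
                                     orf_bundle = bundle, gain = 0,
                                     noise_sd = 0, baseline = 10, seed = 8)
  rn <- response_means(noise$counts, tr)
  resn <- suppressWarnings(regress_all(rn, vars))
  expect_lt(mean(resn$explains), 0.12)
})

test_that("stepwise and best-subset recover the generating variable set", {
  # a compact session keeps the explain threshold above the intrinsic
  # correlation between chosen value and the offers, so the removal rule
  # does not sweep other encoders from the pool
  tr <- generate_exp1_session(session_config(
    2, 4, rho = 1.8, eta = 0.7, n_trials = 400, low_value_bias = 4,
    force_unit_offer_frac = 1, seed = 55))
  bundle <- make_bundle(tr, 1.8)
  vars <- build_variables(tr, 1.8, bundle)
  comp <- c("offer A" = 20, "offer B" = 20, "chosen value" = 20,
            "chosen juice" = 20)
  pop <- generate_mixed_population(tr, comp, rho = 1.8, orf_bundle = bundle,
                                   noise_sd = 2, gain = 20, baseline = 15,
                                   duration = 1, seed = 9)
  rm <- response_means(pop$counts, tr)
  res <- suppressWarnings(regress_all(rm, vars))

  st <- stepwise_select(res)
  expect_setequal(st$selected, names(comp))
  expect_true(all(diff(st$iterations$pct_explained) >= 0))

  bs <- best_subset_select(res, n_max = 4)
  expect_setequal(bs$selected, names(comp))
  bs_n <- best_subset_select(res, n_max = 4, criterion = "n_explained")
  expect_setequal(bs_n$selected, names(comp))

  # single-variable population: one iteration, one selection
  pop1 <- generate_mixed_population(tr, c("chosen juice" = 6), rho = 1.8,
                                    orf_bundle = bundle, noise_sd = 0.2,
                                    gain = 25, seed = 10)
  res1 <- suppressWarnings(regress_all(response_means(pop1$counts, tr), vars))
  st1 <- stepwise_select(res1)
  expect_equal(st1$selected, "chosen juice")
  bs1 <- best_subset_select(res1, n_max = 1)
  expect_equal(bs1$selected, "chosen juice")

  expect_error(best_subset_select(res, n_max = 10), "stepwise")
})

test_that("post-hoc binomial comparison behaves at both extremes", {
  tr <- fixture_session(rho = 2, seed = 56, n_trials = 400)
  bundle <- make_bundle(tr, 2)
  vars <- build_variables(tr, 2, bundle)
  pop <- generate_mixed_population(tr, c("offer B" = 30), rho = 2,
                                   orf_bundle = bundle, noise_sd = 0.3,
                                   gain = 30, seed = 11)
  res <- suppressWarnings(regress_all(response_means(pop$counts, tr), vars))

  ph <- posthoc_binomial(res, "offer B", "total value")
  expect_lt(ph$p_value, 0.001)
  expect_equal(ph$direction, 1)

  # swapping the arguments reverses the direction, same p
  ph2 <- posthoc_binomial(res, "total value", "offer B")
  expect_equal(ph2$p_value, ph$p_value)
  expect_equal(ph2$direction, -1)

  # a variable against itself: no information, p = 1
  ph3 <- posthoc_binomial(res, "offer B", "offer B")
  expect_equal(ph3$p_value, 1)
  expect_equal(ph3$direction, 0)
})
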