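#' Linear decision model over pools of offer-value neurons
#'
#' The decision variable is `D = X_A - X_B` with
#' `X_g = K_g * sum_i(w_i * r_i)`, where each pool holds `n` Poisson neurons
#' whose mean rate is `q_g * t_g` (tuning slope `t_g`, offered quantity
#' `q_g`), `K_g` is the synaptic efficacy of the pool onto the downstream
#' comparison, and same-pool neurons share a rate-independent noise
#' correlation `xi`. `D > 0` and `D < 0` map to choices of A and B. Under a
#' normal approximation the probability of choosing A is
#' `P = Phi((K_A q_A t_A - K_B q_B t_B) /
#'          sqrt(chi * (K_A^2 q_A t_A + K_B^2 q_B t_B)))`,
#' with `chi = xi / 4` in the many-neuron regime studied analytically (see
#' [chi_effective()] for the finite-pool value).
#'
#' @param t_A,t_B Tuning slopes (rate per drop, > 0 unless representing a
#'   non-encoding pool).
#' @param K_A,K_B Synaptic efficacies (> 0); only their ratio matters.
#' @param n Neurons per pool.
#' @param nu_bar Maximum firing rate; with complete range adaptation
#'   `t_g = nu_bar / Q_g`.
#' @param xi Within-pool noise correlation.
#' @param chi Variance coefficient of the normal approximation; defaults to
#'   `xi / 4`.
#' @param w Decision weight applied to every neuron (the model never needs
#'   unequal weights; a common weight cancels from the choice probability).
#'
#' @return An object of class `decision_model`.
#' @export
decision_model <- function(t_A, t_B, K_A = 1, K_B = 1, n = 200, nu_bar = 1,
                           xi = 0.01, chi = xi / 4, w = 1) {
  stopifnot(K_A > 0, K_B > 0, n >= 2, nu_bar > 0, xi >= 0, chi >= 0, w > 0)
  structure(
    list(t_A = t_A, t_B = t_B, K_A = K_A, K_B = K_B, n = as.integer(n),
         nu_bar = nu_bar, xi = xi, chi = chi, w = w),
    class = "decision_model"
  )
}

#' @export
print.decision_model <- function(x, ...) {
  cat(sprintf(
    "Decision model: t=(%.4g, %.4g) K=(%.4g, %.4g) n=%d xi=%.3g chi=%.4g\n",
    x$t_A, x$t_B, x$K_A, x$K_B, x$n, x$xi, x$chi))
  invisible(x)
}

#' Effective variance coefficient of a finite Poisson pool
#'
#' Normal approximation of the decision variable for `n` neurons per pool
#' with within-pool count correlation `xi`, counting spikes over `duration`
#' seconds: the choice probability is the analytic probit with
#' `chi = (1 + (n - 1) * xi) / (n * duration)`. As `n` grows this tends to
#' `xi / duration`; the `xi / 4` regime corresponds to pooling activity over
#' about four seconds of trial time in the many-neuron limit.
#'
#' @param n Neurons per pool.
#' @param xi Within-pool noise correlation.
#' @param duration Spike-count window (s).
#' @return The scalar `chi`.
#' @export
chi_effective <- function(n, xi, duration = 4) {
  (1 + (n - 1) * xi) / (n * duration)
}

#' Analytic choice probability of the linear decision model
#'
#' @param q_A,q_B Offered quantities (vectors are recycled together).
#' @param model A [decision_model()].
#' @return `P(choice = A)` for each offer pair. The degenerate offer
#'   `(0, 0)` returns 0.5 by convention; `chi = 0` gives the deterministic
#'   limit (ties split 0.5).
#' @export
choice_probability <- function(q_A, q_B, model) {
  stopifnot(inherits(model, "decision_model"))
  mu_a <- model$K_A * q_A * model$t_A
  mu_b <- model$K_B * q_B * model$t_B
  num <- mu_a - mu_b
  if (model$chi <= 0) {
    return(ifelse(num > 0, 1, ifelse(num < 0, 0, 0.5)))
  }
  v <- model$chi * (model$K_A^2 * q_A * model$t_A +
                      model$K_B^2 * q_B * model$t_B)
  p <- ifelse(v > 0, stats::pnorm(num / sqrt(pmax(v, 0))), 0.5)
  # v == 0 can only occur at q = (0, 0) (or a zero-slope pool): define 0.5
  ifelse(v == 0 & num != 0, ifelse(num > 0, 1, 0), p)
}

#' Monte-Carlo simulation of the pooled-Poisson decision
#'
#' Independent oracle for [choice_probability()]: simulates the two pools of
#' correlated Poisson neurons explicitly, forms `D = X_A - X_B`, and returns
#' the fraction of repetitions with `D > 0` (ties broken by a fair coin).
#' The matching analytic probability is the probit evaluated at
#' `chi = chi_effective(n, xi, duration)`.
#'
#' @param q_A,q_B A single offer pair.
#' @param model A [decision_model()].
#' @param reps Number of simulated trials (>= 1000).
#' @param duration Spike-count window (s).
#' @param seed Optional RNG seed.
#' @return Empirical `P(choice = A)`.
#' @export
monte_carlo_decision <- function(q_A, q_B, model, reps = 10000, duration = 4,
                                 seed = NULL) {
  stopifnot(inherits(model, "decision_model"), reps >= 1000,
            length(q_A) == 1, length(q_B) == 1)
  with_seed(seed, {
    m_a <- q_A * model$t_A * duration
    m_b <- q_B * model$t_B * duration
    if (m_a < 0 || m_b < 0) stop("negative firing rate")
    x_a <- model$K_A * model$w *
      rowSums(rpois_equicorr(reps, model$n, m_a, model$xi))
    x_b <- model$K_B * model$w *
      rowSums(rpois_equicorr(reps, model$n, m_b, model$xi))
    d <- x_a - x_b
    mean(d > 0) + 0.5 * mean(d == 0)
  })
}

#' Offer grid with sampling weights
#'
#' The set of offers over which expected payoffs are averaged. By default a
#' uniform grid over `{0..Q_A} x {0..Q_B}` minus the never-presented `(0,0)`
#' with equal weights.
#'
#' @param Q_A,Q_B Quantity ranges.
#' @param rho Relative value used for payoff accounting.
#' @param n_steps Points per axis (integers 0..Q by default when `NULL`).
#' @param offers Optional data frame (`q_A`, `q_B`, optional `weight`)
#'   overriding the uniform grid.
#' @return An object of class `offer_grid`: data frame `q_A`, `q_B`,
#'   `weight` with attributes `rho`, `Q_A`, `Q_B`.
#' @export
offer_grid <- function(Q_A, Q_B, rho, n_steps = NULL, offers = NULL) {
  stopifnot(Q_A > 0, Q_B > 0, rho > 0)
  if (is.null(offers)) {
    qa <- if (is.null(n_steps)) 0:Q_A else seq(0, Q_A, length.out = n_steps)
    qb <- if (is.null(n_steps)) 0:Q_B else seq(0, Q_B, length.out = n_steps)
    offers <- expand.grid(q_A = qa, q_B = qb)
    offers <- offers[!(offers$q_A == 0 & offers$q_B == 0), ]
  }
  if (is.null(offers$weight)) offers$weight <- 1
  stopifnot(all(offers$q_A >= 0), all(offers$q_A <= Q_A),
            all(offers$q_B >= 0), all(offers$q_B <= Q_B),
            all(offers$weight >= 0))
  offers$weight <- offers$weight / sum(offers$weight)
  structure(offers, rho = rho, Q_A = Q_A, Q_B = Q_B,
            class = c("offer_grid", "data.frame"))
}

#' Expected payoff of a decision model over an offer grid
#'
#' Weighted mean over offers of
#' `P_A * rho * q_A + (1 - P_A) * q_B` (juice-B units), with `P_A` from the
#' analytic choice probability.
#'
#' @param grid An [offer_grid()].
#' @param model A [decision_model()].
#' @return Scalar expected payoff in drops of juice B.
#' @export
expected_payoff <- function(grid, model) {
  stopifnot(inherits(grid, "offer_grid"))
  rho <- attr(grid, "rho")
  p <- choice_probability(grid$q_A, grid$q_B, model)
  sum(grid$weight * (p * rho * grid$q_A + (1 - p) * grid$q_B))
}

#' Payoff-maximizing tuning slopes under a firing-rate bound
#'
#' Searches tuning slopes `(t_A, t_B)` under the bounded-rate constraint
#' `t_g * Q_g <= nu_bar` for the pair maximizing the expected payoff. The
#' optimum sits on the boundary `t_g = nu_bar / Q_g` -- complete range
#' adaptation: each pool spends its full activity range on the range of
#' values actually offered.
#'
#' @param grid An [offer_grid()].
#' @param model A [decision_model()] providing `K`, `chi`, `nu_bar` (the
#'   slopes in `model` are ignored).
#' @param n_search Grid points per axis on the fraction-of-bound scale.
#' @return List with `t_A`, `t_B`, `payoff`, and the search `surface`
#'   (data frame `t_A`, `t_B`, `payoff`).
#' @export
optimize_tuning <- function(grid, model, n_search = 21) {
  stopifnot(inherits(grid, "offer_grid"))
  Q_A <- attr(grid, "Q_A"); Q_B <- attr(grid, "Q_B")
  fr <- seq(1 / n_search, 1, length.out = n_search)
  surface <- expand.grid(f_A = fr, f_B = fr)
  surface$t_A <- surface$f_A * model$nu_bar / Q_A
  surface$t_B <- surface$f_B * model$nu_bar / Q_B
  surface$payoff <- vapply(seq_len(nrow(surface)), function(i) {
    m <- model; m$t_A <- surface$t_A[i]; m$t_B <- surface$t_B[i]
    expected_payoff(grid, m)
  }, numeric(1))
  best <- surface[which.max(surface$payoff), ]
  # local refinement within the bound
  opt <- stats::optim(
    c(best$f_A, best$f_B),
    function(f) {
      m <- model
      m$t_A <- f[1] * model$nu_bar / Q_A
      m$t_B <- f[2] * model$nu_bar / Q_B
      -expected_payoff(grid, m)
    },
    method = "L-BFGS-B", lower = c(1e-4, 1e-4), upper = c(1, 1))
  list(t_A = opt$par[1] * model$nu_bar / Q_A,
       t_B = opt$par[2] * model$nu_bar / Q_B,
       f_A = opt$par[1], f_B = opt$par[2],
       payoff = -opt$value,
       surface = surface[, c("t_A", "t_B", "payoff")])
}

#' Payoff-maximizing ratio of synaptic efficacies
#'
#' With tuning slopes fixed (typically at complete adaptation,
#' `t_g = nu_bar / Q_g`), maximizes the expected payoff over the efficacy
#' ratio `K_A / K_B` (the choice probability is invariant under a common
#' rescaling of the efficacies). Also reports the induced indifference
#' point, `q_B/q_A` at `P = 0.5`, which equals `K_A t_A / (K_B t_B)`, and
#' the choice bias `log(indifference / rho)`. In the symmetric case
#' `rho * Q_A = Q_B` the optimum is `K_A/K_B = 1` with no bias; in
#' asymmetric cases the optimal ratio is close to `rho * Q_A / Q_B` with a
#' small bias favoring the larger value range, vanishing as `chi -> 0`.
#'
#' @param grid An [offer_grid()].
#' @param model A [decision_model()] with the slopes to use.
#' @param interval Search interval for `log(K_A / K_B)`.
#' @return List with `ratio`, `indifference`, `bias`, `payoff`.
#' @export
optimize_efficacies <- function(grid, model, interval = log(c(0.05, 20))) {
  stopifnot(inherits(grid, "offer_grid"))
  rho <- attr(grid, "rho")
  obj <- function(lk) {
    m <- model; m$K_A <- exp(lk); m$K_B <- 1
    -expected_payoff(grid, m)
  }
  opt <- stats::optimize(obj, interval = interval, tol = 1e-8)
  ratio <- exp(opt$minimum)
  indiff <- ratio * model$t_A / model$t_B
  list(ratio = ratio, indifference = indiff, bias = log(indiff / rho),
       payoff = -opt$objective)
}

#' Sigmoid steepness implied by a decision model
#'
#' Evaluates the model's choice pattern `P(choice = B)` against the log
#' quantity ratio on the binary offers of the grid and fits the behavioral
#' probit sigmoid to it (weighted by the offer frequencies), returning the
#' model-implied steepness `eta`. Under optimal coding this steepness falls
#' as the value ranges grow.
#'
#' @param model A [decision_model()].
#' @param grid An [offer_grid()].
#' @return List with `eta`, `a0`, `rho` (model-implied indifference).
#' @export
model_sigmoid_steepness <- function(model, grid) {
  stopifnot(inherits(grid, "offer_grid"))
  bin <- grid[grid$q_A > 0 & grid$q_B > 0, ]
  lr <- log(bin$q_B / bin$q_A)
  if (length(unique(lr)) < 2) {
    stop("degenerate grid: need at least 2 distinct log quantity ratios")
  }
  p_b <- 1 - choice_probability(bin$q_A, bin$q_B, model)
  w <- bin$weight / sum(bin$weight)
  fit <- suppressWarnings(stats::glm(
    p_b ~ lr, weights = w * 1000,
    family = stats::quasibinomial(link = "probit")))
  co <- stats::coef(fit)
  list(eta = unname(co[2]), a0 = unname(co[1]),
       rho = exp(-unname(co[1]) / unname(co[2])))
}

#' Model-implied steepness of an optimally coded session
#'
#' Convenience wrapper: builds the complete-adaptation decision model for a
#' session's `(rho, Q_A, Q_B)` (slopes `nu_bar / Q_g`, efficacy ratio
#' `rho * Q_A / Q_B`) and returns its sigmoid steepness on the session's
#' uniform offer grid.
#'
#' @param rho Relative value.
#' @param Q_A,Q_B Quantity ranges.
#' @param chi Variance coefficient (default `0.01 / 4`).
#' @param nu_bar Maximum firing rate.
#' @return Scalar model-implied `eta`.
#' @export
optimal_session_eta <- function(rho, Q_A, Q_B, chi = 0.0025, nu_bar = 1) {
  grid <- offer_grid(Q_A, Q_B, rho)
  model <- decision_model(t_A = nu_bar / Q_A, t_B = nu_bar / Q_B,
                          K_A = rho * Q_A / Q_B, K_B = 1,
                          nu_bar = nu_bar, chi = chi)
  model_sigmoid_steepness(model, grid)$eta
}

#' Expected payoff under different range-adaptation scenarios
#'
#' Compares complete adaptation (`t_g = nu_bar / Q_g`), partial adaptation,
#' and no adaptation (slopes set for a larger hypothetical range
#' `Q_wide`, so the activity range is only partly used) on the same offer
#' grid, with the efficacy ratio re-optimized in each scenario so that no
#' scenario is handicapped by a choice bias.
#'
#' @param grid An [offer_grid()].
#' @param model A [decision_model()] providing `chi` and `nu_bar`.
#' @param Q_wide Hypothetical larger range for the no-adaptation scenario.
#' @param partial Fraction of the way from no to complete adaptation for
#'   the intermediate scenario.
#' @return Data frame `scenario`, `t_A`, `t_B`, `payoff`.
#' @export
adaptation_scenario_payoffs <- function(grid, model, Q_wide, partial = 0.5) {
  Q_A <- attr(grid, "Q_A"); Q_B <- attr(grid, "Q_B")
  stopifnot(Q_wide > max(Q_A, Q_B))
  slope_for <- function(mix) {
    # mix = 0: adapted to Q_wide (none); mix = 1: adapted to own range
    c(t_A = model$nu_bar / (mix * Q_A + (1 - mix) * Q_wide),
      t_B = model$nu_bar / (mix * Q_B + (1 - mix) * Q_wide))
  }
  rows <- lapply(c(none = 0, partial = partial, complete = 1), function(mix) {
    t <- slope_for(mix)
    m <- model; m$t_A <- t[["t_A"]]; m$t_B <- t[["t_B"]]
    opt <- optimize_efficacies(grid, m)
    data.frame(t_A = t[["t_A"]], t_B = t[["t_B"]], payoff = opt$payoff)
  })
  out <- do.call(rbind, rows)
  out$scenario <- names(rows)
  out[, c("scenario", "t_A", "t_B", "payoff")]
}
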