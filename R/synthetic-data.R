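#' Configuration for a synthetic two-juice choice session
#'
#' Describes one session of a binary juice-choice task. On every trial the
#' subject chooses between `q_A` drops of juice A and `q_B` drops of juice B,
#' with quantities drawn from the ranges `[0, Q_A]` and `[0, Q_B]`. A zero
#' offer is a forced choice for the other juice. Choices follow a probit
#' sigmoid in the log quantity ratio, parameterized by the relative value
#' `rho` (drops of B equivalent to one drop of A) and the steepness `eta`.
#'
#' @param Q_A,Q_B Maximum quantities of juices A and B (integer drops, >= 1).
#' @param rho True relative value (> 0).
#' @param eta True sigmoid steepness (> 0); the probit slope on
#'   `log(q_B / q_A)`.
#' @param n_trials Total number of trials in the session.
#' @param low_value_bias Weighting knob (>= 1) over-representing low quantity
#'   levels: offer type `(q_A, q_B)` receives weight
#'   `low_value_bias^-(q_A/Q_A + q_B/Q_B)`.
#' @param force_unit_offer_frac Target fraction of binary offer types that
#'   include a quantity-1 offer (the task's characteristic design).
#' @param seed Optional RNG seed; the caller's RNG state is untouched.
#'
#' @return An object of class `session_config`.
#' @export
session_config <- function(Q_A, Q_B, rho = 2, eta = 2, n_trials = 250,
                           low_value_bias = 2, force_unit_offer_frac = 0.96,
                           seed = NULL) {
  stopifnot(
    Q_A >= 1, Q_B >= 1, Q_A == round(Q_A), Q_B == round(Q_B),
    rho > 0, eta > 0, n_trials >= 1,
    low_value_bias >= 1,
    force_unit_offer_frac >= 0, force_unit_offer_frac <= 1
  )
  structure(
    list(Q_A = as.integer(Q_A), Q_B = as.integer(Q_B), rho = rho, eta = eta,
         n_trials = as.integer(n_trials), low_value_bias = low_value_bias,
         force_unit_offer_frac = force_unit_offer_frac, seed = seed),
    class = "session_config"
  )
}

#' @export
print.session_config <- function(x, ...) {
  cat(sprintf(
    "Session config: Q_A=%d Q_B=%d rho=%.3g eta=%.3g n_trials=%d\n",
    x$Q_A, x$Q_B, x$rho, x$eta, x$n_trials))
  invisible(x)
}

# Probit coefficients implied by (rho, eta): X = a0 + a1 log(q_B/q_A),
# indifference at q_B/q_A = rho, slope eta.
probit_coef <- function(rho, eta) c(a0 = -eta * log(rho), a1 = eta)

# Offer-type schedule for one block: forced choices for both juices, all
# binary types containing a quantity-1 offer, plus enough other binary types
# to bring the unit-offer fraction down to the configured target.
build_offer_types <- function(Q_A, Q_B, force_unit_offer_frac) {
  forced <- rbind(
    data.frame(q_A = seq_len(Q_A), q_B = 0L),
    data.frame(q_A = 0L, q_B = seq_len(Q_B))
  )
  unit <- unique(rbind(
    data.frame(q_A = 1L, q_B = seq_len(Q_B)),
    data.frame(q_A = seq_len(Q_A), q_B = 1L)
  ))
  other_pool <- expand.grid(q_A = seq_len(Q_A), q_B = seq_len(Q_B))
  other_pool <- other_pool[other_pool$q_A > 1 & other_pool$q_B > 1, ]
  f <- force_unit_offer_frac
  n_other <- if (f >= 1) 0L else min(
    nrow(other_pool), floor(nrow(unit) * (1 - f) / f))
  other <- if (n_other > 0) {
    # deterministic pick: lowest-quantity non-unit types first
    ord <- order(other_pool$q_A / Q_A + other_pool$q_B / Q_B)
    other_pool[ord[seq_len(n_other)], ]
  } else other_pool[0, ]
  rbind(forced, unit, other)
}

# Trial counts per offer type: low quantities over-represented, every type
# presented at least once.
allocate_trials <- function(types, n_trials, Q_A, Q_B, low_value_bias) {
  n_types <- nrow(types)
  if (n_trials < n_types) {
    stop(sprintf("n_trials (%d) smaller than the number of offer types (%d)",
                 n_trials, n_types))
  }
  w <- low_value_bias^(-(types$q_A / Q_A + types$q_B / Q_B))
  w <- w / sum(w)
  extra <- n_trials - n_types
  counts <- rep(1L, n_types)
  if (extra > 0) {
    counts <- counts + as.integer(stats::rmultinom(1, extra, w))
  }
  counts
}

# Find forced-choice trials to append to block 2 so that the A:B
# choice-count ratio matches rC and the drunk-amount (drops) ratio matches
# rD, given realized block-2 tallies (A2 choices / B2 choices, DA2 / DB2
# drops drunk). Forced-A trials add one choice and 1..Q_A drops each (and
# likewise for B), so for any pair of forced-trial counts the achievable
# drop totals form an interval; the smallest feasible pair is returned with
# the drop quantities distributed over trials.
balance_extras <- function(A2, B2, DA2, DB2, rC, rD, Q_A, Q_B, headroom,
                           tol) {
  spread_drops <- function(total, n_trials, Q) {
    if (n_trials == 0) return(integer(0))
    base <- total %/% n_trials
    rem <- total - base * n_trials
    q <- c(rep(base + 1L, rem), rep(base, n_trials - rem))
    if (any(q < 1) || any(q > Q)) return(NULL)
    as.integer(q)
  }
  if (abs((A2 / B2) / rC - 1) <= tol && abs((DA2 / DB2) / rD - 1) <= tol) {
    return(list(qA_extra = integer(0), qB_extra = integer(0),
                mismatch = max(abs((A2 / B2) / rC - 1),
                               abs((DA2 / DB2) / rD - 1))))
  }
  for (xB in 0:headroom) {
    xA <- as.integer(round(rC * (B2 + xB) - A2))
    if (xA < 0) next
    if (xA + xB > headroom) break
    m_choice <- abs(((A2 + xA) / (B2 + xB)) / rC - 1)
    if (m_choice > tol) next
    # need (DA2 + SA) / (DB2 + SB) = rD with SA in [xA, Q_A xA], SB likewise
    g <- rD * DB2 - DA2
    if (xB == 0) {
      SB <- 0L
    } else {
      sb_lo <- max(xB, ceiling((xA - g) / rD))
      sb_hi <- min(Q_B * xB, floor((Q_A * xA - g) / rD))
      if (sb_lo > sb_hi) next
      SB <- as.integer(round((sb_lo + sb_hi) / 2))
    }
    SA <- as.integer(round(g + rD * SB))
    SA <- min(max(SA, xA), Q_A * xA)
    m_drink <- abs(((DA2 + SA) / (DB2 + SB)) / rD - 1)
    if (m_drink > tol) next
    qA_extra <- spread_drops(SA, xA, Q_A)
    qB_extra <- spread_drops(SB, xB, Q_B)
    if ((xA > 0 && is.null(qA_extra)) || (xB > 0 && is.null(qB_extra))) next
    return(list(qA_extra = qA_extra %||% integer(0),
                qB_extra = qB_extra %||% integer(0),
                mismatch = max(m_choice, m_drink)))
  }
  NULL
}

sample_choices <- function(q_A, q_B, a0, a1) {
  choice <- character(length(q_A))
  forced_a <- q_B == 0
  forced_b <- q_A == 0
  choice[forced_a] <- "A"
  choice[forced_b] <- "B"
  bin <- !forced_a & !forced_b
  if (any(bin)) {
    p_b <- stats::pnorm(a0 + a1 * log(q_B[bin] / q_A[bin]))
    choice[bin] <- ifelse(stats::runif(sum(bin)) < p_b, "B", "A")
  }
  choice
}

finish_trials <- function(q_A, q_B, choice, session_id, block) {
  position_A <- sample(c("left", "right"), length(q_A), replace = TRUE)
  # saccade direction: the side of the chosen offer (no generative effect on
  # choices or firing; present so spatial factors are exercisable downstream)
  direction <- ifelse(choice == "A", position_A,
                      ifelse(position_A == "left", "right", "left"))
  data.frame(
    session_id = session_id, block = as.integer(block), trial = seq_along(q_A),
    q_A = as.integer(q_A), q_B = as.integer(q_B),
    choice = choice, position_A = position_A, direction = direction,
    stringsAsFactors = FALSE
  )
}

#' Generate one fixed-range session
#'
#' Simulates a single-block session: offer types always include forced
#' choices for both juices, most binary offer types contain a quantity-1
#' offer, low quantity levels are over-represented, and binary choices are
#' sampled from the probit sigmoid implied by `(rho, eta)`.
#'
#' @param config A [session_config()].
#' @param session_id Identifier stored in the trial table.
#'
#' @return A data frame of trials with columns `session_id`, `block`,
#'   `trial`, `q_A`, `q_B`, `choice`, `position_A`, `direction`; the config
#'   is attached as attribute `"config"`.
#' @export
generate_exp1_session <- function(config, session_id = "S1") {
  stopifnot(inherits(config, "session_config"))
  with_seed(config$seed, {
    types <- build_offer_types(config$Q_A, config$Q_B,
                               config$force_unit_offer_frac)
    counts <- allocate_trials(types, config$n_trials, config$Q_A, config$Q_B,
                              config$low_value_bias)
    q_A <- rep(types$q_A, counts)
    q_B <- rep(types$q_B, counts)
    ord <- sample.int(length(q_A))
    q_A <- q_A[ord]; q_B <- q_B[ord]
    ab <- probit_coef(config$rho, config$eta)
    choice <- sample_choices(q_A, q_B, ab["a0"], ab["a1"])
    trials <- finish_trials(q_A, q_B, choice, session_id, 1L)
    attr(trials, "config") <- config
    trials
  })
}

#' Generate one two-block range-manipulation session
#'
#' Simulates a session in which the quantity range of one juice is halved or
#' doubled between two trial blocks while the other range is unchanged, so
#' the ratio `Q_A/Q_B` changes by exactly a factor of two. The generating
#' relative value and steepness are shared by the two blocks (range
#' adaptation corrected within the decision circuit). After sampling, forced
#' choices are appended to the second block until the A:B choice-count ratio
#' and the relative amounts of juice drunk match the first block within
#' `balance_tol` (emulating the online correction used at the rig).
#'
#' @param config A [session_config()]; `Q_A`/`Q_B` are the first-block ranges
#'   and `n_trials` the per-block base trial count (blocks must end up with
#'   110--260 trials).
#' @param manipulation One of `"A_doubled"`, `"A_halved"`, `"B_doubled"`,
#'   `"B_halved"`.
#' @param balance_tol Maximum tolerated relative mismatch of the two balance
#'   ratios across blocks.
#' @param session_id Identifier stored in the trial table.
#'
#' @return A data frame of trials spanning both blocks, with the per-block
#'   ranges in attribute `"ranges"`.
#' @export
generate_exp2_session <- function(config, manipulation = c("A_doubled",
                                  "A_halved", "B_doubled", "B_halved"),
                                  balance_tol = 0.05, session_id = "S1") {
  stopifnot(inherits(config, "session_config"))
  manipulation <- match.arg(manipulation)
  good <- substr(manipulation, 1, 1)
  fac <- if (grepl("doubled", manipulation)) 2 else 0.5
  Q1 <- c(A = config$Q_A, B = config$Q_B)
  Q2 <- Q1
  new_q <- Q1[[good]] * fac
  if (new_q < 1 || new_q != round(new_q)) {
    stop(sprintf("range of juice %s (%d drops) cannot be %s", good, Q1[[good]],
                 if (fac < 1) "halved" else "doubled"))
  }
  Q2[[good]] <- as.integer(new_q)
  if (config$n_trials < 110 || config$n_trials > 260) {
    stop("per-block trial count must lie in [110, 260]")
  }

  with_seed(config$seed, {
    ab <- probit_coef(config$rho, config$eta)
    make_block <- function(Q, block, n) {
      types <- build_offer_types(Q[["A"]], Q[["B"]],
                                 config$force_unit_offer_frac)
      counts <- allocate_trials(types, n, Q[["A"]], Q[["B"]],
                                config$low_value_bias)
      q_A <- rep(types$q_A, counts); q_B <- rep(types$q_B, counts)
      ord <- sample.int(length(q_A))
      q_A <- q_A[ord]; q_B <- q_B[ord]
      choice <- sample_choices(q_A, q_B, ab["a0"], ab["a1"])
      list(q_A = q_A, q_B = q_B, choice = choice)
    }
    b1 <- make_block(Q1, 1L, config$n_trials)
    # leave generous headroom in block 2 for balancing forced choices
    base2 <- 110L
    b2 <- make_block(Q2, 2L, base2)

    n_choices <- function(b) c(A = sum(b$choice == "A"), B = sum(b$choice == "B"))
    drunk <- function(b) c(A = sum(b$q_A[b$choice == "A"]),
                           B = sum(b$q_B[b$choice == "B"]))
    c1 <- n_choices(b1); d1 <- drunk(b1)
    rC <- c1[["A"]] / c1[["B"]]; rD <- d1[["A"]] / d1[["B"]]
    # When the range manipulation shifts the balance so far that appended
    # forced choices cannot compensate within the block-size budget, swap
    # individual binary trials for forced choices of the under-represented
    # juice first (the rig equivalently re-tuned offer frequencies online).
    mismatch <- function(b) {
      c2 <- n_choices(b); d2 <- drunk(b)
      max(abs(log((c2[["A"]] / c2[["B"]]) / rC)),
          abs(log((d2[["A"]] / d2[["B"]]) / rD)))
    }
    apply_swap <- function(b, i, good, q) {
      if (good == "A") {
        b$q_A[i] <- q; b$q_B[i] <- 0L; b$choice[i] <- "A"
      } else {
        b$q_B[i] <- q; b$q_A[i] <- 0L; b$choice[i] <- "B"
      }
      b
    }
    best <- NULL
    for (swap in 0:base2) {
      c2 <- n_choices(b2); d2 <- drunk(b2)
      best <- balance_extras(c2[["A"]], c2[["B"]], d2[["A"]], d2[["B"]],
                             rC = rC, rD = rD,
                             Q_A = Q2[["A"]], Q_B = Q2[["B"]],
                             headroom = 260L - base2, tol = balance_tol)
      if (!is.null(best)) break
      # greedily swap one binary trial for a forced choice, choosing the
      # swap that most reduces the joint (choice, drink) ratio mismatch
      cur <- mismatch(b2)
      cand <- NULL
      for (ch in c("A", "B")) {
        src <- which(b2$choice == ch & b2$q_A > 0 & b2$q_B > 0)
        if (length(src) == 0) next
        qsrc <- if (ch == "A") b2$q_A[src] else b2$q_B[src]
        for (i in src[c(which.max(qsrc), which.min(qsrc))]) {
          for (good in c("A", "B")) {
            for (q in seq_len(Q2[[good]])) {
              m <- mismatch(apply_swap(b2, i, good, q))
              if (m < cur - 1e-12 &&
                  (is.null(cand) || m < cand$m)) {
                cand <- list(i = i, good = good, q = q, m = m)
              }
            }
          }
        }
      }
      if (is.null(cand)) break
      b2 <- apply_swap(b2, cand$i, cand$good, cand$q)
    }
    if (is.null(best)) {
      stop(sprintf(paste0("cannot balance block 2 within tolerance %.3g ",
                          "(constraint: choice-count and drunk-amount ",
                          "ratios matched across blocks within the block-",
                          "size budget)"), balance_tol))
    }
    extra_qA <- c(best$qA_extra, rep(0L, length(best$qB_extra)))
    extra_qB <- c(rep(0L, length(best$qA_extra)), best$qB_extra)
    q_A2 <- c(b2$q_A, extra_qA); q_B2 <- c(b2$q_B, extra_qB)
    choice2 <- c(b2$choice, rep("A", length(best$qA_extra)),
                 rep("B", length(best$qB_extra)))
    ord <- sample.int(length(q_A2))
    t1 <- finish_trials(b1$q_A, b1$q_B, b1$choice, session_id, 1L)
    t2 <- finish_trials(q_A2[ord], q_B2[ord], choice2[ord], session_id, 2L)
    t2$trial <- t2$trial + nrow(t1)
    trials <- rbind(t1, t2)
    attr(trials, "config") <- config
    attr(trials, "ranges") <- list(block1 = Q1, block2 = Q2)
    attr(trials, "balance") <- best
    trials
  })
}

#' Generate an ensemble of fixed-range sessions with fitted sigmoids
#'
#' Draws session parameters the way the fixed-range experiment varied them
#' -- relative values log-uniform, juice-A ranges of a few drops, juice-B
#' ranges set so the two value ranges are roughly matched
#' (`Q_B ~ rho * Q_A`, capped at 10 drops), steepness log-normal across
#' sessions -- generates each session, and fits its choice sigmoid.
#' Sessions with perfectly separated choices (no split decisions) are
#' dropped, as they carry no steepness information.
#'
#' @param n_sessions Number of sessions to draw.
#' @param eta0 Median generating steepness.
#' @param eta_sdlog Log-scale SD of the steepness across sessions.
#' @param rho_range Range of the log-uniform relative value.
#' @param Q_A_choices Candidate juice-A ranges (drops).
#' @param n_trials Trials per session.
#' @param seed Optional RNG seed.
#'
#' @return List of sessions, each a list with `trials`, `fit`
#'   (`sigmoid_fit`), and `config`.
#' @export
exp1_session_ensemble <- function(n_sessions = 150, eta0 = 3,
                                  eta_sdlog = 0.6, rho_range = c(1.2, 4),
                                  Q_A_choices = 2:4, n_trials = 250,
                                  seed = NULL) {
  with_seed(seed, {
    sessions <- vector("list", 0L)
    for (i in seq_len(n_sessions)) {
      rho <- exp(stats::runif(1, log(rho_range[1]), log(rho_range[2])))
      Q_A <- sample(Q_A_choices, 1)
      Q_B <- min(10L, max(2L, as.integer(round(rho * Q_A))))
      eta <- stats::rlnorm(1, log(eta0), eta_sdlog)
      cfg <- session_config(Q_A, Q_B, rho = rho, eta = eta,
                            n_trials = n_trials,
                            seed = sample.int(.Machine$integer.max, 1))
      tr <- generate_exp1_session(cfg, session_id = sprintf("S%03d", i))
      fit <- tryCatch(fit_choice_sigmoid(tr), error = function(e) NULL)
      if (is.null(fit) || fit$perfect_separation || fit$a1 <= 0) next
      sessions[[length(sessions) + 1L]] <- list(trials = tr, fit = fit,
                                                config = cfg)
    }
    sessions
  })
}

#' Specification of one simulated offer-value neuron
#'
#' @param good `"A"` or `"B"`: the juice whose offered quantity the neuron
#'   encodes.
#' @param baseline Baseline firing rate (spikes/s, >= 0) at a zero offer.
#' @param slope Tuning slope (spikes/s per drop).
#' @param max_rate Maximum firing rate `nu_bar` (spikes/s); with complete
#'   range adaptation `baseline + slope * Q_good <= max_rate`.
#' @param encoded_variable Label of the encoded variable (used by the
#'   variable-selection fixtures).
#' @param window_count Number of analysis time windows to simulate.
#'
#' @return An object of class `neuron_spec`.
#' @export
neuron_spec <- function(good = c("A", "B"), baseline = 2, slope = 5,
                        max_rate = 50, encoded_variable = NULL,
                        window_count = 1L) {
  good <- match.arg(good)
  stopifnot(baseline >= 0, max_rate > 0, window_count >= 1)
  structure(
    list(good = good, baseline = baseline, slope = slope, max_rate = max_rate,
         encoded_variable = encoded_variable %||%
           paste("offer", good),
         window_count = as.integer(window_count)),
    class = "neuron_spec"
  )
}

#' Simulate correlated Poisson spike counts for a population
#'
#' Each neuron's count on each trial is Poisson with mean
#' `(baseline + slope * q_good) * duration`. Counts of neurons encoding the
#' same good share a trial-by-trial noise correlation `xi` (Gaussian copula
#' with a common within-good factor, calibrated so the Pearson correlation of
#' the counts matches `xi`); neurons encoding different goods are
#' uncorrelated. The correlation does not depend on the firing rates.
#'
#' @param trials Trial table from [generate_exp1_session()] or similar.
#' @param specs A single [neuron_spec()] or a list of them.
#' @param xi Within-good noise correlation, in `[0, 0.2]`.
#' @param duration Time-window duration in seconds.
#' @param seed Optional RNG seed.
#'
#' @return A data frame (`neuron_id`, `trial_id`, `window`, `count`,
#'   `duration`).
#' @export
generate_neuron_counts <- function(trials, specs, xi = 0.01, duration = 0.5,
                                   seed = NULL) {
  if (inherits(specs, "neuron_spec")) specs <- list(specs)
  stopifnot(all(vapply(specs, inherits, logical(1), "neuron_spec")),
            xi >= 0, xi <= 0.2, duration > 0)
  n_tr <- nrow(trials)
  with_seed(seed, {
    out <- vector("list", length(specs))
    goods <- vapply(specs, `[[`, character(1), "good")
    n_win <- max(vapply(specs, `[[`, integer(1), "window_count"))
    for (w in seq_len(n_win)) {
      # one common within-good latent factor per trial, per window
      z0 <- list(A = stats::rnorm(n_tr), B = stats::rnorm(n_tr))
      for (k in seq_along(specs)) {
        sp <- specs[[k]]
        if (w > sp$window_count) next
        q <- if (sp$good == "A") trials$q_A else trials$q_B
        rate <- sp$baseline + sp$slope * q
        if (any(rate < 0)) stop("neuron spec implies a negative firing rate")
        m <- rate * duration
        if (xi > 0) {
          att <- poisson_copula_attenuation(mean(m[m > 0]))
          r <- min(xi / att, 0.99)
          z <- sqrt(r) * z0[[sp$good]] + sqrt(1 - r) * stats::rnorm(n_tr)
          count <- stats::qpois(stats::pnorm(z), m)
        } else {
          count <- stats::rpois(n_tr, m)
        }
        out[[length(out) + 1L]] <- data.frame(
          neuron_id = k, trial_id = seq_len(n_tr), window = paste0("w", w),
          count = as.integer(count), duration = duration)
      }
    }
    do.call(rbind, out[!vapply(out, is.null, logical(1))])
  })
}

#' Simulate a mixed population of variable-encoding neurons
#'
#' Fixture generator for the variable-selection pipeline: each neuron's
#' trial-by-trial firing rate is an affine function of one assigned encoding
#' variable (rescaled to `[0, 1]`) plus Gaussian rate noise, and spike counts
#' are Poisson. Ground-truth labels are returned for recovery scoring.
#'
#' @param trials Trial table.
#' @param composition Named integer vector: how many neurons encode each
#'   variable; names must come from [encoding_variable_names()].
#' @param rho Relative value used to construct the value variables.
#' @param orf_bundle Optional bundle of response functions (see
#'   [build_variables()]); required only when the composition includes
#'   response-function variables.
#' @param noise_sd SD of the Gaussian rate noise (spikes/s).
#' @param baseline,gain Affine map from the unit-scaled variable to the mean
#'   firing rate (spikes/s).
#' @param duration Count-window duration (s).
#' @param window_count Number of identical analysis windows to emit.
#' @param seed Optional RNG seed.
#'
#' @return A list with elements `counts` (spike table) and `labels`
#'   (data frame `neuron_id`, `variable`).
#' @export
generate_mixed_population <- function(trials, composition, rho,
                                      orf_bundle = NULL, noise_sd = 1,
                                      baseline = 2, gain = 20, duration = 0.5,
                                      window_count = 1L, seed = NULL) {
  if (length(composition) == 0) {
    return(list(
      counts = data.frame(neuron_id = integer(), trial_id = integer(),
                          window = character(), count = integer(),
                          duration = numeric()),
      labels = data.frame(neuron_id = integer(), variable = character())))
  }
  vars <- names(composition)
  unknown <- setdiff(vars, encoding_variable_names())
  if (length(unknown) > 0) {
    stop("unknown encoding variable(s): ", paste(unknown, collapse = ", "))
  }
  design <- build_variables(trials, rho, orf_bundle = orf_bundle,
                            require_orf = any(grepl("ORF", vars)))
  key <- paste(trials$q_A, trials$q_B, trials$choice)
  dkey <- paste(design$q_A, design$q_B, design$choice)
  idx <- match(key, dkey)
  with_seed(seed, {
    labels <- data.frame(
      neuron_id = seq_len(sum(composition)),
      variable = rep(vars, composition), stringsAsFactors = FALSE)
    out <- vector("list", 0L)
    for (k in seq_len(nrow(labels))) {
      v <- design[[labels$variable[k]]][idx]
      v[!is.finite(v)] <- NA
      rng <- range(v, na.rm = TRUE)
      v01 <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else rep(0.5, length(v))
      v01[is.na(v01)] <- 0.5
      for (w in seq_len(window_count)) {
        rate <- pmax(baseline + gain * v01 +
                       stats::rnorm(length(v01), 0, noise_sd), 0)
        out[[length(out) + 1L]] <- data.frame(
          neuron_id = k, trial_id = seq_len(nrow(trials)),
          window = paste0("w", w),
          count = stats::rpois(length(rate), rate * duration),
          duration = duration)
      }
    }
    list(counts = do.call(rbind, out), labels = labels)
  })
}
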