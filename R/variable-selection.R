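#' Names of the 20 candidate encoding variables
#'
#' The variable set regressed against every neuronal response: linear offer
#' values, cumulative trial-count distributions (plus variance-equalized
#' versions fit on square-root rates), session-optimal step response
#' functions, their mean across sessions, optimal response functions under
#' the symmetric uniform distribution, and the chosen-value / choice
#' variables.
#'
#' @return Character vector of length 20 (fixed order, used for
#'   deterministic tie-breaking).
#' @export
encoding_variable_names <- function() {
  c("offer A", "offer B",
    "offer A ntrials_CDF", "offer B ntrials_CDF",
    "offer A ntrials_CDF VE", "offer B ntrials_CDF VE",
    "offer A ORF", "offer B ORF",
    "offer A mean(ORF)", "offer B mean(ORF)",
    "offer A ORF_uniform", "offer B ORF_uniform",
    "chosen value", "chosen value ntrials_CDF", "chosen value ntrials_CDF VE",
    "other value", "value difference", "value ratio", "total value",
    "chosen juice")
}

ve_variable_names <- function() {
  c("offer A ntrials_CDF VE", "offer B ntrials_CDF VE",
    "chosen value ntrials_CDF VE")
}

#' Response-function bundle for variable construction
#'
#' Collects the response-function regressors needed by [build_variables()]:
#' the session's analytic step response functions, the mean response
#' functions across an ensemble of sessions (empirical CDFs of the
#' normalized step locations), and the optimal response functions for the
#' symmetric uniform offer distribution.
#'
#' @param trials Trial table of the session.
#' @param rho Session relative value.
#' @param step_norm_A,step_norm_B Normalized step locations across sessions
#'   (defaults: this session's own `1 / Q_A` and `rho / Q_B`).
#' @param chi Noise coefficient for the uniform-distribution optimum.
#' @param grid_resolution Grid for the uniform-distribution optimum.
#' @param uniform Optional precomputed result of [orf_uniform()] (it is
#'   session independent, so one optimization can serve many sessions).
#' @return List of `response_function`s: `orf_A`, `orf_B`, `mean_orf_A`,
#'   `mean_orf_B`, `orf_uniform_A`, `orf_uniform_B`.
#' @export
orf_bundle <- function(trials, rho, step_norm_A = NULL, step_norm_B = NULL,
                       chi = 0.0025, grid_resolution = 21, uniform = NULL) {
  Q_A <- max(trials$q_A); Q_B <- max(trials$q_B)
  u <- uniform %||% orf_uniform(chi = chi, grid_resolution = grid_resolution)
  step_rf <- function(grid, loc, good) {
    response_function(grid, ifelse(grid < loc, 0,
                                   ifelse(grid > loc, 1, 0.5)), good)
  }
  list(orf_A = step_rf(sort(unique(trials$q_A)), 1, "A"),
       orf_B = step_rf(sort(unique(trials$q_B)), rho, "B"),
       mean_orf_A = mean_orf(pmin(step_norm_A %||% (1 / Q_A), 1)),
       mean_orf_B = mean_orf(pmin(step_norm_B %||% (rho / Q_B), 1)),
       orf_uniform_A = u$f_A, orf_uniform_B = u$f_B)
}

#' Per-trial-type values of the 20 encoding variables
#'
#' One row per trial type (offer type x choice) of the session, one numeric
#' column per candidate variable. Value variables are expressed in
#' juice-B-drop units (`value_A = rho * q_A`); the trial-count CDFs are
#' computed from the session's own trial frequencies; response-function
#' variables are evaluated through the supplied bundle. The value ratio is
#' undefined on forced choices (one value is zero) and is returned as `NA`
#' there.
#'
#' @param trials Trial table.
#' @param rho Relative value.
#' @param orf_bundle A bundle from [orf_bundle()]; may be `NULL` when
#'   `require_orf = FALSE`, in which case the six response-function columns
#'   are `NA`.
#' @param require_orf Error when the bundle is missing.
#' @return Data frame with `q_A`, `q_B`, `choice`, `n_trials` and the 20
#'   variable columns; attribute `"ve_variables"` lists the columns to be
#'   regressed on square-root rates.
#' @export
build_variables <- function(trials, rho, orf_bundle = NULL,
                            require_orf = TRUE) {
  stopifnot(rho > 0)
  if (is.null(orf_bundle) && require_orf) {
    stop("missing orf_bundle: response-function variables cannot be built")
  }
  tt <- stats::aggregate(list(n_trials = trials$q_A),
                         by = list(q_A = trials$q_A, q_B = trials$q_B,
                                   choice = trials$choice), FUN = length)
  tt <- tt[order(tt$q_A, tt$q_B, tt$choice), ]
  v_a <- rho * tt$q_A
  v_b <- tt$q_B
  chosen <- ifelse(tt$choice == "A", v_a, v_b)
  other <- ifelse(tt$choice == "A", v_b, v_a)

  # empirical CDF of trial counts over quantity / value levels
  count_cdf <- function(all_values, at) {
    f <- stats::ecdf(all_values)
    f(at)
  }
  chosen_all <- ifelse(trials$choice == "A", rho * trials$q_A, trials$q_B)
  Q_A <- max(trials$q_A); Q_B <- max(trials$q_B)

  ev <- function(rf, q) if (is.null(orf_bundle)) NA_real_ else
    eval_response_function(rf, q)
  vars <- data.frame(check.names = FALSE,
    q_A = tt$q_A, q_B = tt$q_B, choice = tt$choice, n_trials = tt$n_trials,
    "offer A" = v_a,
    "offer B" = v_b,
    "offer A ntrials_CDF" = count_cdf(trials$q_A, tt$q_A),
    "offer B ntrials_CDF" = count_cdf(trials$q_B, tt$q_B),
    "offer A ntrials_CDF VE" = count_cdf(trials$q_A, tt$q_A),
    "offer B ntrials_CDF VE" = count_cdf(trials$q_B, tt$q_B),
    "offer A ORF" = ev(orf_bundle$orf_A, tt$q_A),
    "offer B ORF" = ev(orf_bundle$orf_B, tt$q_B),
    "offer A mean(ORF)" = ev(orf_bundle$mean_orf_A, tt$q_A / Q_A),
    "offer B mean(ORF)" = ev(orf_bundle$mean_orf_B, tt$q_B / Q_B),
    "offer A ORF_uniform" = ev(orf_bundle$orf_uniform_A, tt$q_A / Q_A),
    "offer B ORF_uniform" = ev(orf_bundle$orf_uniform_B, tt$q_B / Q_B),
    "chosen value" = chosen,
    "chosen value ntrials_CDF" = count_cdf(chosen_all, chosen),
    "chosen value ntrials_CDF VE" = count_cdf(chosen_all, chosen),
    "value difference" = v_a - v_b,
    "value ratio" = ifelse(pmin(v_a, v_b) > 0, pmax(v_a, v_b) / pmin(v_a, v_b),
                           NA_real_),
    "total value" = v_a + v_b,
    "chosen juice" = as.numeric(tt$choice == "B"))
  vars[["other value"]] <- other
  vars <- vars[, c("q_A", "q_B", "choice", "n_trials",
                   encoding_variable_names())]
  attr(vars, "ve_variables") <- ve_variable_names()
  vars
}

#' Mean firing rate per trial type
#'
#' Collapses a spike table to neuronal responses: the mean firing rate of
#' each neuron in each time window for each trial type.
#'
#' @param counts Spike table (`neuron_id`, `trial_id`, `window`, `count`,
#'   `duration`).
#' @param trials Trial table (row order defines `trial_id`).
#' @return Data frame `neuron_id`, `window`, `q_A`, `q_B`, `choice`,
#'   `rate`, `n_trials`.
#' @export
response_means <- function(counts, trials) {
  tr <- trials[counts$trial_id, c("q_A", "q_B", "choice")]
  d <- cbind(counts, tr)
  d$rate <- d$count / d$duration
  agg <- stats::aggregate(
    list(rate = d$rate),
    by = list(neuron_id = d$neuron_id, window = d$window,
              q_A = d$q_A, q_B = d$q_B, choice = d$choice), FUN = mean)
  n <- stats::aggregate(
    list(n_trials = d$rate),
    by = list(neuron_id = d$neuron_id, window = d$window,
              q_A = d$q_A, q_B = d$q_B, choice = d$choice), FUN = length)
  agg$n_trials <- n$n_trials
  agg[order(agg$neuron_id, agg$window, agg$q_A, agg$q_B, agg$choice), ]
}

#' Screen responses for task relatedness (3-way ANOVA)
#'
#' Each neuronal response (one neuron, one window) is submitted to a 3-way
#' ANOVA with main effects of stimulus position, saccade direction, and
#' offer type on the trial-by-trial firing rates. Responses whose
#' offer-type factor is significant at `alpha` are task related. Factors
#' with a single level are dropped with a warning.
#'
#' @param counts Spike table.
#' @param trials Trial table.
#' @param alpha Significance threshold for the offer-type factor.
#' @return Data frame `neuron_id`, `window`, `p_offer_type`,
#'   `task_related`.
#' @export
anova_screen <- function(counts, trials, alpha = 0.001) {
  if (!all(c("position_A", "direction") %in% names(trials))) {
    stop("factors position_A and direction must be present in the trials")
  }
  tr <- trials[counts$trial_id, c("q_A", "q_B", "choice", "position_A",
                                  "direction")]
  d <- cbind(counts, tr)
  d$rate <- d$count / d$duration
  d$offer_type <- paste(d$q_A, d$q_B, sep = ":")
  groups <- split(d, list(d$neuron_id, d$window), drop = TRUE)
  out <- lapply(groups, function(g) {
    terms <- c("position_A", "direction", "offer_type")
    keep <- vapply(terms, function(t) length(unique(g[[t]])) > 1, logical(1))
    if (!all(keep)) {
      warning(sprintf("neuron %s window %s: dropping single-level factor(s) %s",
                      g$neuron_id[1], g$window[1],
                      paste(terms[!keep], collapse = ", ")), call. = FALSE)
    }
    terms <- terms[keep]
    if (!("offer_type" %in% terms)) {
      return(data.frame(neuron_id = g$neuron_id[1], window = g$window[1],
                        p_offer_type = NA_real_, task_related = FALSE))
    }
    fml <- stats::as.formula(paste("rate ~", paste(terms, collapse = " + ")))
    fit <- stats::lm(fml, data = g)
    dr <- stats::drop1(fit, test = "F")
    p <- dr["offer_type", "Pr(>F)"]
    data.frame(neuron_id = g$neuron_id[1], window = g$window[1],
               p_offer_type = p, task_related = is.finite(p) && p < alpha)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$neuron_id, res$window), ]
}

# closed-form simple OLS of y on x: slope, two-sided slope p, R^2
ols_stats <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  if (sxx == 0 || n < 3) return(NULL)
  slope <- sxy / sxx
  r2 <- if (syy > 0) sxy^2 / (sxx * syy) else 0
  rss <- syy - sxy^2 / sxx
  se <- sqrt(pmax(rss, 0) / ((n - 2) * sxx))
  p <- if (se > 0) 2 * stats::pt(-abs(slope / se), n - 2) else 0
  list(slope = slope, p_value = p, r_squared = r2)
}

#' Regress every neuronal response on every encoding variable
#'
#' Simple linear regression of each response's trial-type mean rates on
#' each variable column; variance-equalized variables are regressed on the
#' square root of the rates. A variable "explains" a response when its
#' slope differs from zero at `p < 0.05`; among the explaining variables,
#' the one with the highest R-squared is the best fit (ties broken by the
#' fixed variable order). Constant variable columns are skipped with a
#' warning.
#'
#' @param responses Data frame from [response_means()].
#' @param variables Data frame from [build_variables()].
#' @param alpha Significance threshold for "explains".
#' @return Data frame with one row per (response, variable): `neuron_id`,
#'   `window`, `variable`, `slope`, `p_value`, `r_squared`, `explains`,
#'   `best_fit`.
#' @export
regress_all <- function(responses, variables, alpha = 0.05) {
  var_names <- encoding_variable_names()
  ve <- attr(variables, "ve_variables") %||% ve_variable_names()
  key_r <- paste(responses$q_A, responses$q_B, responses$choice)
  key_v <- paste(variables$q_A, variables$q_B, variables$choice)
  idx <- match(key_r, key_v)
  groups <- split(seq_len(nrow(responses)),
                  list(responses$neuron_id, responses$window), drop = TRUE)
  skipped <- character(0)
  out <- lapply(groups, function(i) {
    if (length(i) < 3) {
      stop("need at least 3 trial types per response")
    }
    rate <- responses$rate[i]
    rows <- lapply(var_names, function(vn) {
      v <- variables[[vn]][idx[i]]
      ok <- is.finite(v)
      y <- if (vn %in% ve) sqrt(pmax(rate, 0)) else rate
      if (sum(ok) < 3 || length(unique(v[ok])) < 2) {
        skipped <<- union(skipped, vn)
        return(NULL)
      }
      st <- ols_stats(v[ok], y[ok])
      if (is.null(st)) return(NULL)
      data.frame(neuron_id = responses$neuron_id[i[1]],
                 window = responses$window[i[1]], variable = vn,
                 slope = st$slope, p_value = st$p_value,
                 r_squared = st$r_squared, stringsAsFactors = FALSE)
    })
    g <- do.call(rbind, rows)
    g$explains <- g$p_value < alpha
    g$best_fit <- FALSE
    cand <- which(g$explains)
    if (length(cand) > 0) {
      # ties (to within numerical noise) broken by the fixed variable order
      # (rows are already in that order)
      top <- max(g$r_squared[cand])
      g$best_fit[cand[g$r_squared[cand] >= top - 1e-9][1]] <- TRUE
    }
    g
  })
  if (length(skipped) > 0) {
    warning("skipped constant/degenerate variable column(s): ",
            paste(skipped, collapse = ", "), call. = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

response_ids <- function(results) paste(results$neuron_id, results$window)

#' Stepwise variable selection
#'
#' Iteratively selects the variable (scored in its best time window) that
#' provides the highest number of best fits among the responses not yet
#' explained, then removes every response that variable explains. The
#' procedure stops when the marginal explanatory power of the next variable
#' falls below `stop_frac` of the task-related responses (that variable is
#' reported as eliminated).
#'
#' @param results Data frame from [regress_all()].
#' @param stop_frac Marginal-explanatory-power stopping fraction.
#' @return An object of class `selection_report`: list with `selected`
#'   (character), `iterations` (data frame per iteration: variable, window,
#'   best-fit tally, responses newly explained, cumulative percent
#'   explained, eliminated flag), `n_responses`.
#' @export
stepwise_select <- function(results, stop_frac = 0.05) {
  stopifnot(nrow(results) > 0)
  ids <- response_ids(results)
  all_ids <- unique(ids)
  pool <- all_ids
  iterations <- NULL
  selected <- character(0)
  explained_total <- character(0)
  repeat {
    live <- results[ids %in% pool & results$best_fit, ]
    if (nrow(live) == 0) break
    tal <- stats::aggregate(list(n_best = live$variable),
                            by = list(variable = live$variable,
                                      window = live$window), FUN = length)
    tal <- tal[order(-tal$n_best,
                     match(tal$variable, encoding_variable_names())), ]
    v <- tal$variable[1]
    expl_ids <- unique(ids[results$variable == v & results$explains])
    marginal <- intersect(expl_ids, pool)
    eliminated <- length(marginal) / length(all_ids) < stop_frac
    if (!eliminated) {
      selected <- c(selected, v)
      pool <- setdiff(pool, expl_ids)
      explained_total <- union(explained_total, expl_ids)
    }
    iterations <- rbind(iterations, data.frame(
      variable = v, window = tal$window[1], n_best = tal$n_best[1],
      n_new_explained = length(marginal),
      pct_explained = 100 * length(explained_total) / length(all_ids),
      eliminated = eliminated, stringsAsFactors = FALSE))
    if (eliminated) break
  }
  structure(list(selected = selected, iterations = iterations,
                 n_responses = length(all_ids)),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("Variable selection:", paste(x$selected, collapse = ", "), "\n")
  if (!is.null(x$iterations)) print(x$iterations)
  invisible(x)
}

#' Best-subset variable selection (exhaustive)
#'
#' For each subset size `n = 1..n_max`, enumerates all subsets of the 20
#' variables and scores each by the total R-squared (each response
#' contributes its best R-squared among the subset members that explain it)
#' or by the number of responses explained. Exhaustive, hence optimal, but
#' limited to small `n`.
#'
#' @param results Data frame from [regress_all()].
#' @param n_max Largest subset size.
#' @param criterion `"total_R2"` (default, the more robust score) or
#'   `"n_explained"`.
#' @return A `selection_report` whose `selected` is the best subset of size
#'   `n_max`; `per_size` holds the best subset and score for each size.
#' @export
best_subset_select <- function(results, n_max = 4,
                               criterion = c("total_R2", "n_explained")) {
  criterion <- match.arg(criterion)
  vars <- encoding_variable_names()
  n_comb <- sum(choose(length(vars), seq_len(n_max)))
  if (n_max > 6 || n_comb > 2e5) {
    stop("subset enumeration too large; use stepwise_select()")
  }
  ids <- response_ids(results)
  all_ids <- unique(ids)
  # response x variable matrix of explaining R^2 (0 when not explaining)
  R <- matrix(0, length(all_ids), length(vars),
              dimnames = list(all_ids, vars))
  ok <- results$explains
  R[cbind(match(ids[ok], all_ids), match(results$variable[ok], vars))] <-
    results$r_squared[ok]
  per_size <- NULL
  best_subset <- NULL
  for (n in seq_len(n_max)) {
    combs <- utils::combn(length(vars), n)
    scores <- vapply(seq_len(ncol(combs)), function(j) {
      sub <- R[, combs[, j], drop = FALSE]
      rmax <- do.call(pmax, as.data.frame(sub))
      if (criterion == "total_R2") sum(rmax) else sum(rmax > 0)
    }, numeric(1))
    jbest <- which.max(scores)
    sel <- vars[combs[, jbest]]
    if (n == n_max) best_subset <- sel
    per_size <- rbind(per_size, data.frame(
      n = n, score = scores[jbest],
      subset = paste(sel, collapse = " | "), stringsAsFactors = FALSE))
  }
  structure(list(selected = best_subset, per_size = per_size,
                 criterion = criterion, n_responses = length(all_ids)),
            class = "selection_report")
}

#' Post-hoc binomial comparison of two variables' explanatory power
#'
#' Sign test on the per-response contest between two variables: among
#' responses scored on both, counts how often each provides the higher
#' R-squared and tests the split against 0.5.
#'
#' @param results Data frame from [regress_all()].
#' @param var1,var2 Variable names.
#' @return List with `p_value`, `direction` (+1 when `var1` wins more
#'   often), `wins1`, `wins2`, `n`.
#' @export
posthoc_binomial <- function(results, var1, var2) {
  ids <- response_ids(results)
  r1 <- results[results$variable == var1, ]
  r2 <- results[results$variable == var2, ]
  common <- intersect(response_ids(r1), response_ids(r2))
  if (length(common) == 0) {
    stop("test undefined: no responses scored on both variables")
  }
  x1 <- r1$r_squared[match(common, response_ids(r1))]
  x2 <- r2$r_squared[match(common, response_ids(r2))]
  wins1 <- sum(x1 > x2); wins2 <- sum(x2 > x1)
  if (wins1 + wins2 == 0) {
    return(list(p_value = 1, direction = 0, wins1 = 0, wins2 = 0,
                n = length(common)))
  }
  bt <- stats::binom.test(wins1, wins1 + wins2, 0.5)
  list(p_value = bt$p.value, direction = sign(wins1 - wins2),
       wins1 = wins1, wins2 = wins2, n = length(common))
}
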