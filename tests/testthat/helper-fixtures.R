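# Shared fixtures, built in code.

# A small deterministic session used across tests.
fixture_session <- function(rho = 2.5, eta = 3, Q_A = 3, Q_B = 8,
                            n_trials = 300, seed = 42) {
  generate_exp1_session(session_config(Q_A, Q_B, rho = rho, eta = eta,
                                       n_trials = n_trials, seed = seed))
}

# The uniform-distribution optimal response functions are expensive;
# compute once per test run.
fixture_orf_uniform <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- orf_uniform(chi = 0.0025,
                                              grid_resolution = 21, seed = 1)
    cache
  }
})

# Trial table built directly from explicit offers/choices.
manual_trials <- function(q_A, q_B, choice) {
  data.frame(session_id = "T", block = 1L, trial = seq_along(q_A),
             q_A = q_A, q_B = q_B, choice = choice,
             position_A = rep(c("left", "right"), length.out = length(q_A)),
             direction = rep(c("left", "right"), length.out = length(q_A)),
             stringsAsFactors = FALSE)
}
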