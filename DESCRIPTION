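Package: valuecoding
Title: Payoff-Optimal Coding of Economic Value in Choice Behavior
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to study how the neural representation of offer values
    shapes economic choice. Implements probit fitting of two-alternative
    choice patterns (relative value and sigmoid steepness), payoff metrics
    (fractional lost value and its expectation), a linear decision model over
    pools of correlated Poisson neurons with analytic choice probabilities,
    numerical optimization of payoff-maximizing tuning slopes, synaptic
    efficacies and monotone response functions, neuronal tuning-curvature and
    range-adaptation analyses, and stepwise/best-subset variable selection
    over a 20-variable encoding set. A synthetic-data generator emulates
    two-juice choice sessions and offer-value neuron populations with known
    ground truth so every stage of the pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
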