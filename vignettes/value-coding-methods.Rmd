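---
title: "Payoff-optimal value coding: models, simulations and analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Payoff-optimal value coding: models, simulations and analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(valuecoding)
```

## The scientific problem

In two-alternative economic choice, a subject repeatedly picks between
quantities $q_A$ and $q_B$ of two goods. Neurons that encode the value of a
single offered good are linear in that value, but their tuning slope
rescales with the range of values in play ("range adaptation"). This
package implements a framework in which that observation can be
interrogated quantitatively: it asks what tuning — slope, synaptic gain,
and functional form — maximizes the *expected payoff* of the resulting
decisions, simulates behavioral sessions and neuronal populations with
known ground truth, and provides the statistical analyses that connect the
theory to (synthetic or user-supplied) data.

## Choice behavior: the probit sigmoid

A session's choice pattern is summarized by a probit regression of the
probability of choosing good B on the log quantity ratio,

$$P(ch = B) = \Phi\!\big(a_0 + a_1 \log(q_B/q_A)\big),$$

with two derived quantities: the **relative value** $\rho = e^{-a_0/a_1}$
(drops of B worth one drop of A; the indifference point) and the
**steepness** $\eta = a_1$, the inverse measure of choice variability.
Forced choices ($q_A = 0$ or $q_B = 0$) are excluded from the fit because
the log ratio is undefined there. Sessions in which choices are perfectly
ordered by the log ratio ("perfect separation") make the slope
unidentifiable; `fit_choice_sigmoid()` flags them and all steepness
analyses drop them.

Two payoff metrics quantify what choice variability costs, on strictly
binary trials with values $v_A = \rho q_A$, $v_B = q_B$:

* **FLV** (fractional lost value)
  $= \langle \max v - v_{chosen}\rangle / \langle \max v - \bar v\rangle$,
  where $\bar v$ is the midpoint of the two offer values and $\langle\cdot\rangle$
  averages over trials *before* the ratio is taken. 0 means the higher
  value is always taken, 1 means chance.
* **EFLV** replaces the realized chosen value with its expectation under
  the fitted sigmoid; it is the payoff cost the sigmoid itself predicts.

Design choices worth making explicit: exact value ties are excluded from
the percent-error count (no lower value exists) but kept in FLV, where
they contribute zero loss; FLV is a ratio of trial averages rather than an
average of per-trial ratios; and both metrics are invariant to a common
rescaling of all values.

## The linear decision model

Decisions are modeled as a comparison of two pooled signals,
$D = X_A - X_B$ with $X_g = K_g \sum_i w_i r_i^g$: $n$ Poisson neurons per
pool with mean rate $q_g t_g$ (slope $t_g$), pool-specific synaptic
efficacy $K_g$, equal decision weights, and a rate-independent noise
correlation $\xi$ between same-pool neurons. A normal approximation gives
the choice probability

$$P(ch = A) = \Phi\!\left(\frac{K_A q_A t_A - K_B q_B t_B}
{\sqrt{\chi\,(K_A^2 q_A t_A + K_B^2 q_B t_B)}}\right).$$

The variance coefficient $\chi$ collects the pool parameters. For a finite
pool counting spikes over $T$ seconds,
$\chi = (1 + (n-1)\xi)/(nT)$ (`chi_effective()`); for many neurons this
tends to $\xi/T$, and the analysis default $\chi = \xi/4 = 0.0025$
corresponds to pooling roughly four seconds of trial activity in that
limit. The Monte-Carlo simulator `monte_carlo_decision()` is an
independent oracle: it simulates the correlated Poisson pools explicitly
(Gaussian copula with a common within-pool factor, latent correlation
calibrated through the first Hermite coefficient so that the *count*
correlation matches $\xi$) and agrees with the probit at the matching
finite-pool $\chi$ within binomial error. Behavioral realism in the
synthetic steepness analyses uses the finite-pool value
(`chi_effective(200, 0.01, 0.5)` $\approx 0.03$), which produces sigmoid
steepness in the empirically familiar range of 2–4; the many-neuron
default would imply nearly deterministic choices.

Three optimality results are verified numerically rather than symbolically:

* `optimize_tuning()`: under the bounded-rate constraint
  $t_g Q_g \le \bar\nu$ the expected payoff is maximized on the boundary
  $t_g = \bar\nu/Q_g$ — complete range adaptation.
* `optimize_efficacies()`: with slopes at the bound, the payoff-maximizing
  efficacy ratio is $K_A/K_B = 1$ when $\rho Q_A = Q_B$ (no choice bias;
  the indifference point equals $\rho$), and
  $K_A/K_B \approx \rho Q_A/Q_B$ otherwise, with a small bias favoring
  the larger value range that shrinks as $\chi \to 0$.
* `model_sigmoid_steepness()`: the model-implied $\eta$ decreases as the
  value ranges grow, which is the behavioral signature tested by
  `steepness_range_analysis()`.

A practical numerical point: expected payoff over a *discrete* offer grid
is piecewise constant in the efficacy ratio wherever no offer sits near
the indifference line, so coarse integer grids can park the optimizer
anywhere on a plateau. The efficacy and bias analyses therefore use grids
with matched value resolution on the two axes (`offer_grid(n_steps = )`);
with 11–21 steps per axis the symmetric optimum is recovered to $10^{-6}$
and the bias-versus-$\chi$ curve is monotone.

## Optimal response functions

Relaxing linearity, a response function $f_g$ maps offered quantity to
normalized activity in $[0, 1]$ and replaces the linear drive:
$q_g t_g \to \bar\nu f_g(q_g)$, keeping variance proportional to mean
activity (the Poisson property). This generalization reduces exactly to
the linear model when $f$ is linear; it is the package's central modeling
assumption for non-linear tuning, and it is validated against the analytic
cases rather than derived. `optimize_response_functions()` maximizes
expected payoff over monotone $f_A, f_B$ by projected coordinate ascent
with deterministic multi-starts (linear ramps and candidate steps at every
grid point, the most promising starts ascended to convergence at a payoff
tolerance of $10^{-9}$).

Analytic anchors: when good A is always offered in quantity 1 and
$\rho = 2$ (or 3), the optimal offer-value-B function is a step at 2 (or
3) with value $\tfrac12$ at the tie point. The optimizer reproduces these
within one grid cell, with the tie pinned exactly: after convergence, grid
points whose activity is payoff-indifferent — quantities offered only in
exact value ties, or never offered — are set to the midpoint of their
feasible interval, which is the conventional $\tfrac12$ split. Two
degenerate regimes deserve a warning: at very small $\chi$ the payoff
difference between orderings falls below machine precision and the
objective becomes numerically flat (use $\chi \gtrsim 10^{-3}$), and at
$\chi = 0$ exactly the optimizer is meaningless.

`mean_orf()` implements the ensemble average of per-session steps as the
empirical CDF of the normalized step locations ($\rho/Q_B$ for good B; the
step of the good-A function sits at one drop, so $1/Q_A$ plays that role
for good A — an extension chosen for symmetry, since no analytic result
pins the good-A average). `orf_uniform()` optimizes under a symmetric
uniform joint offer distribution; the result is monotone and convex
(fitted quadratic coefficient $\approx +0.95$ at $\chi = 0.0025$). How
*strongly* convex the optimum is depends on the noise model and on
$\chi$; the qualitative shape — quasi-linear with upward curvature,
unlike the sharp per-session steps — is the property the package's tests
pin down.

## Neuronal tuning analyses

`ntrials_cdf()` builds the infomax benchmark (cumulative trial counts over
quantity levels); `normalize_response()` divides levels by their maximum
and applies the linear-regression transform $fr \to (fr - a_0)/a_1$, making
the analysis invariant to gain and offset and idempotent;
`curvature_fit()` extracts $\beta_2$ (quadratic, from a degree-2 fit) and
$\beta_3$ (cubic, from a separate degree-3 fit — deliberately not nested).
Polynomial fits are unweighted least squares on the normalized points;
weighting by trial counts would be a defensible alternative, but the
unweighted convention keeps the curvature of sparsely sampled high
quantities visible. `range_adaptation_check()` regresses tuning slopes on
the reciprocal value range: under complete adaptation the product
slope × range is constant at the activity range $\bar\nu$.

## Variable selection

`build_variables()` constructs the 20 candidate encoding variables per
trial type (linear offer values, trial-count CDFs and variance-equalized
versions fit on square-root rates, session step response functions, their
ensemble means, the uniform-distribution optima, chosen value and its CDF
forms, other value, value difference, value ratio, total value, chosen
juice). The value ratio is undefined on forced choices and is carried as
`NA`; regressions drop those trial types for that variable only.
`anova_screen()` keeps responses whose offer-type factor is significant at
$p < 0.001$ in a main-effects three-way ANOVA (position × direction ×
offer type; interactions are not modeled). `regress_all()` marks a
variable as *explaining* a response at $p < 0.05$ and assigns each
response a *best fit* (highest $R^2$ among explaining variables; ties
within numerical noise resolved by the fixed variable order).
`stepwise_select()` repeatedly takes the variable/window with most best
fits and removes every response that variable explains, stopping when the
marginal gain drops below 5% of the task-related pool;
`best_subset_select()` enumerates subsets exhaustively (feasible through
$n = 5$ of 20) and scores them by total $R^2$ (default) or responses
explained. Variable families are collapsed across time windows: a family
is one candidate, each response scored in its own window.

The label-recovery fixture (`generate_mixed_population()`) deserves a
note, because the stepwise removal rule makes exact recovery a property of
the *design*, not just the noise level. Any response cleanly tuned to
chosen value is also weakly correlated with the offers (the chosen value
*is* one of the offer values), so in information-rich sessions the offer
variables "explain" chosen-value responses and sweep them from the pool
before chosen value can be selected. Recovery of the exact generating set
therefore requires a compact session — few trial types, so the
significance threshold on $R^2$ sits above those intrinsic
cross-correlations — together with split decisions (a shallow sigmoid
decorrelates choice from the offers) and neurons whose baseline keeps the
square-root transform approximately affine (otherwise the
variance-equalized CDF surrogates tie with the linear variables). The
packaged fixture (ranges 2 × 4 drops, $\rho = 1.8$, $\eta = 0.7$, strong
low-quantity over-representation, baseline 15 spikes/s) recovers
{offer A, offer B, chosen value, chosen juice} by both procedures across
seeds; richer designs degrade gracefully toward the CDF surrogates, which
is itself informative about what the procedure can and cannot conclude.

## The synthetic-data generator

`generate_exp1_session()` emulates fixed-range sessions: offer types span
forced choices for both juices plus binary types of which a configurable
fraction (default 0.96) contains a quantity-1 offer; per-type frequencies
are weighted by `low_value_bias^-(q_A/Q_A + q_B/Q_B)` (default 2),
over-representing low quantities; choices are sampled from the probit
implied by the session's $(\rho, \eta)$. `generate_exp2_session()` builds
two blocks with one range halved or doubled, sharing one $(\rho, \eta)$
across blocks (range adaptation corrected downstream), and balances the
realized A:B choice-count and drops-drunk ratios across blocks by
appending forced choices — swapping individual binary trials for forced
ones when appending alone cannot reach the 5% tolerance. With one-drop
granularity some range combinations are genuinely infeasible to balance
(e.g. halving a 4-drop range against a 2-drop companion); the generator
reports the unmet constraint rather than silently delivering an
unbalanced session.

`exp1_session_ensemble()` draws the session parameters the way the
fixed-range experiment varied them: $\rho$ log-uniform on $[1.2, 4]$,
$Q_A \in \{2, 3, 4\}$ drops, $Q_B \approx \rho Q_A$ capped at 10 drops,
250 trials per session, and steepness log-normal across sessions (median
3, log-SD 0.6). The log-SD was chosen so that the *distribution* of
baseline FLV and percent error across sessions matches the published
behavioral spread (FLV mass near zero with a tail to ≈ 0.3, percent
errors of roughly 1–30%); the absolute steepness scale is never trusted —
the steepness-reduction analysis calibrates a single global factor so the
baseline mean EFLV equals 0.054 before halving or dividing steepness by
ten. What the generator does not emulate: session-to-session drift of
$\rho$ within a day, choice hysteresis, lapses, and any spatial biases
(the position and direction factors are generated with zero effect so the
ANOVA screen is exercisable; a position-tuned control is built in the
tests by construction). Passing tests therefore certify the estimators
and the optimality machinery, not these omitted behavioral phenomena.

Correlated spike counts use a Gaussian copula with one common factor per
trial and pool. The copula attenuates correlations pushed through discrete
Poisson margins, so the latent correlation is inflated by the reciprocal
of the squared first Hermite coefficient of
$\mathrm{qpois}(\Phi(Z), m)$ — a quadrature calibration that holds the
realized count correlation at the requested $\xi$ across firing rates.

## Error-in-variables details

The steepness–range regression treats both $\eta$ and
$\Delta = (\rho Q_A Q_B)^{1/2}$ as measured with error, using Deming
regression with variance ratio
$\lambda = 4 a_1^4 (\delta a_1)^2 / (\rho Q_A Q_B (a_0\,\delta a_1 -
a_1\,\delta a_0)^2)$, propagated from the probit standard errors. The
numerator of the propagated $\delta\rho$ is the total differential
$\rho\,(a_0\,\delta a_1 - a_1\,\delta a_0)/a_1^2$ — a joint perturbation
of both coefficients, which the unit tests mirror with perfectly
correlated draws. One $\lambda$ per regression is required; when
per-session values are supplied the median is used. The convention is
$\lambda = \mathrm{var}(y\ \mathrm{errors})/\mathrm{var}(x\ \mathrm{errors})$:
$\lambda = 1$ is orthogonal regression and $\lambda \to \infty$ recovers
ordinary least squares of $y$ on $x$, both verified against independent
oracles.

## Problem sizes

The shipped analyses and tests run at desk scale: ensembles of 100–150
sessions of 250 trials for the payoff analyses; 60–80 sessions of 4,000
trials for the steepness–range regression (long sessions keep the refit
standard error of $\eta$ below the modest range effect); response-function
grids of 21 points per good; Monte-Carlo oracle checks with pools of
100–200 neurons and 10,000–50,000 repetitions per offer; selection
populations of 80 neurons over ~16 trial types. All stochastic steps take
explicit seeds and the generators restore the caller's RNG state.

## Known limitations

* The non-linear response-function objective is a reconstruction
  constrained to reduce to the linear model, not a derived result; only
  its analytic anchor cases are ground truth.
* The $\chi = \xi/4$ regime is adopted as stated; the package exposes the
  finite-pool mapping but does not attempt to re-derive the constant.
* Best-subset selection is exhaustive and hence limited to small subset
  sizes; stepwise selection inherits the order dependence of its removal
  rule, which the fixture section above makes concrete.
* The behavioral generator draws independent trials; sequential effects
  are out of scope.
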