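---
title: "Modelling the dynamic consumption of pain relief"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the dynamic consumption of pain relief}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The task and its state space

The task studied here is a finite-horizon consumption–savings problem over
pain relief.  An agent faces `T = 60` trials; on each trial a Poisson number
of mildly painful electric shocks is delivered, with mean 14 shocks when no
relief is used.  The agent holds a budget of 2400 mg of computerized relief;
every 1 mg spent on a trial lowers that trial's expected shock count by 0.1,
and at most 120 mg may be spent per trial (bringing the mean down to the
baseline of 2).  Spending is irreversible and there is no interest on
savings: capital evolves as `s[t+1] = s[t] - c[t]`, with no borrowing.

All modelling is done on the rounded grid the published analyses use:
consumption is rounded to the nearest 10 mg ("units"), giving 13 possible
actions per trial (0–12 units) and integer capital 0–240.  `reliefdyn`
keeps milligrams strictly at the data boundary (`round_and_correct()`
implements the rounding, with the budget constraint enforced *online*:
earlier trials keep their rounded value and later trials absorb any clip;
ties at `.5` round half away from zero by default, since the source of the
rounding rule is unstated, and the alternative banker's rule is available).
A quantity the agent sees on screen, and which several models build on, is
the mean relief remaining per trial, `rho[t] = s[t] / (T - (t - 1))` —
consuming exactly `rho[t]` forever after spreads the budget evenly.

## Valuation: utility and anticipation-discounting

Instantaneous utility is `U(c) = c^k` with `k` in `(0, 1]`.  With `k = 1`
and no discounting, every path that exhausts the budget has the same total
value; any concavity (`k < 1`) strictly favours even spreading.

Delay is weighted by an anticipation-discounting function

    Delta(d) = gamma_c^d + alpha * sum_{tau=0}^{d-1} gamma_c^(d-tau) gamma_a^tau

which combines conventional exponential discounting of the outcome itself
(rate `gamma_c`) with the discounted stream of anticipation (dread for
pains, savoring for reliefs) experienced while waiting, itself discounted
at rate `gamma_a` and weighted by `alpha >= 0`.  `Delta(0) = 1`: the current
period is never discounted.  When `alpha = 0` and `gamma_c < 1` the weight
decays with delay (discounting dominates); when `gamma_c = gamma_a = 1` and
`alpha > 0` it grows linearly (anticipation dominates, producing negative
time preference — the preference to defer relief).  Per-subject values of
`(alpha, gamma_c, gamma_a)` come from a companion binary intertemporal
choice experiment, mapping the pain discount factor to consumption
(`gamma_c = gamma_P`) and the dread discount factor to anticipation
(`gamma_a = gamma_D`); the relief frame is the default, being the frame of
the consumption task itself.

All formulas are evaluated term by term rather than with geometric closed
forms, so the undiscounted limit `gamma = 1` is exact — several published
simulations live exactly there.

## Planning under non-exponential discounting

The sophisticated planner values consuming `c` at `(s, t)` as

    Q(s, c, t) = U(c) + E_pi[ sum_d Delta(d) U(c[t+d]) ],

with the expectation over the agent's own future softmax policy
`pi(c | s, t) ∝ exp(beta Q)`.  Because `Delta` is not exponential this is
not a plain Bellman recursion.  `reliefdyn` uses the exact algebraic
decomposition `Delta(d) = gamma_c^d + alpha B(d)` with
`B(d) = gamma_c B(d-1) + gamma_c gamma_a^(d-1)`, which closes the recursion
with three coupled value tables: expected utility streams discounted at
`gamma_c` and at `gamma_a`, plus the anticipation stream.  One backward pass
costs `O(T S A)` instead of the naive `O(T^2)` delay-indexed sum.  The
decomposition is exact — the test-suite checks the Q tables against
brute-force enumeration of all future action sequences (an implementation
that uses `Delta(d)` directly, with no decomposition) to 1e-8 on random
small tasks.

The naive planner at trial `i` weights trial-`t` utility by `Delta(t - i)`
and assumes future selves will share those weights; it is re-solved at
every trial of a simulation, and only the current-trial action is executed.
With `alpha = 0` plans are dynamically consistent and naive and
sophisticated agents coincide (exactly so at `gamma_c = 1`; at finite
temperature and `gamma_c < 1` the naive agent's *imagined* far-future
policies are slightly softer because the perspective weights scale the
Q-values inside the softmax, a negligible effect at the high `beta` used
for optimal-path simulation).  With savoring the naive agent perpetually
defers: it consumes less than it planned; with dominant discounting it
consumes more.

No argmax is taken anywhere — "optimal" paths are softmax simulations at
`beta = 10000`, so exact value ties (e.g. linear utility with no
discounting) are split evenly and resolve to random choice.

## Heuristic choice models

Three action propensities formalise the observed behavioral motifs:
`M_spend = c`, `M_spread = -|rho - c|`, and `M_save = rho - c` while
`rho < 12` and 0 for every action once `rho` reaches the cap (the saving
drive switches off once the remaining budget suffices to hold the baseline
to the end; its component policy then becomes uniform and the other
heuristics take over).  Propensities use the real-valued `rho`.

**Direct Action** turns each propensity into its own softmax policy with a
separate inverse temperature (each bounded `[0, 10]`) and combines the
three policies by inverse-variance weighting: component `i` receives weight
proportional to `1 / Var(c)` under that component at the current state.
The variance is floored at `1e-10`; softmax policies over these propensities
never truly degenerate except at single-action states, where all components
coincide anyway.

**Income Maximization** replaces `M_save` with an action value: the
`gamma`-discounted expected stream of future `rho` under the model's own
mixture policy, computed by strict backward induction (the trial-`t`
mixture only references mixtures at later trials, so the apparent
circularity resolves).  `gamma` in `[0, 1]` is the probability of searching
one level deeper; at `gamma = 0` the component is uniform and the model
degenerates towards a two-heuristic mixture.  Income maximization *per se*
never wants to spend (spending always lowers future `rho`); spending is
produced by the other mixture components, and the characteristic
mid-experiment rise of saving emerges from the inverse-variance weighting
dynamics.

**Combined optimal-plus-heuristic** adds to the sophisticated planner's
Q-values three Gaussian biases toward spending salient quantities — zero,
`rho`, or the largest feasible amount — each a Gaussian density with sd 2
units centred on its quantity, weighted by `omega_min`, `omega_mean`,
`omega_max >= 0` (raw densities, not renormalised: any rescaling is
absorbed by the omegas, which are bounded `[0, 100]` for fitting since the
source states no bound).  The future policy inside the planner's
expectation is the biased policy itself.  With all omegas zero the model
reduces exactly to the pure anticipation-discounting policy, making the
pair a nested comparison.

## Maximum-likelihood fitting and model comparison

Each subject's likelihood conditions on their actual capital:
`-sum_t log p(c[t] | s[t], t)`, with probabilities floored at `1e-12`
against underflow.  Fitting uses Nelder–Mead simplex search with bound
constraints by a smooth sine transformation (the published procedure states
"bound constraints by transformation" without naming the bijection; any
smooth one is equivalent up to the optimizer's path), inside a random
multistart overlay: on each iteration, candidate starting points are drawn
uniformly within the bounds, the objective is evaluated at every candidate,
and the simplex runs from the best of them; the best point seen anywhere is
kept.  Running a separate simplex from *every* candidate is available
(`start_rule = "all"`) but is not the default — the overlay's purpose is to
choose a good basin, and the draw evaluations are three orders of magnitude
cheaper than simplex runs.  The published budget (10 iterations of 100
starts) is available by argument; the package default is the desk-scale
3 × 20.  All fits are deterministic under a fixed seed.

Group-level comparison is fixed-effects: log-likelihoods are summed across
subjects and `BIC = -2 L + k log(n)` with `k` = parameters per subject ×
subjects and `n` = total observations (subjects × 60).  The source does not
state its `k`/`n` accounting; both are overridable, and only BIC
*differences* between models fitted to the same subjects are interpreted.

Fit quality is summarised by the 10-trial block R²: per subject, observed
mean consumption in six 10-trial blocks against the same quantity from
10 000 paths simulated at the ML parameters, pooled across subjects, R²
from a least-squares regression of observed on predicted.

Two further descriptive surfaces: a robust (Tukey-bisquare IRLS) regression
of raw milligram consumption on trial index across all subject-trials, and
a per-subject behavioral classification — *spreading* if the mean absolute
deviation from `rho` is under 1 unit; otherwise *saving* if the mean of
`c - rho` is at or below −1, *early-spending* at or above +1, and *mixed*
otherwise (reported explicitly).  The signed deviation is defined as
`c - rho` so that savers score negative, which reproduces the published
group counts; note the source's own Eq. for `d` has the opposite sign to
the labelling used in its supplementary classification.

## The synthetic cohort

The original trial-level dataset (and the companion table of discounting
parameters) is not redistributable here, so the package generates a
deterministic synthetic stand-in with the reported structure: 33 subjects,
3 flagged as excluded pilots, and among the 30 included exactly 13
spreading / 15 saving / 2 early-spending.  Spreaders are spread-dominant
Direct Action agents; savers come in the two published shapes — 9 extreme
savers (save-heuristic-dominant Direct Action: conserve until `rho` reaches
the cap, then spend the cap) and 6 gradual savers (moderate Income
Maximization agents); early spenders are near-random agents with a weak
spend pull, matching the high trial-to-trial variability described for that
class.  Parameters are redrawn (seeded rejection sampling) until each
subject's realized path classifies as designed, so the composition is exact
by construction.  Consumption is emitted in milligrams so the full I/O and
rounding pipeline is exercised.

What the stand-in does and does not support: structure-level results
(classification counts, sign and magnitude of the consumption-trend slope,
which models win and lose, recovery behaviour) are meaningful; subject-level
point values reported for the real cohort (robust slope 0.47 mg/trial,
block R² of 0.56 / 0.80 / 0.07 / 0.83, BIC margins of 78 and 430) are
properties of real humans' choices and are *not* calibration targets — the
synthetic cohort was designed once from the qualitative descriptions and
never adjusted toward those numbers.  On the stand-in the robust slope
comes out at ≈ 0.5 mg/trial, and both heuristic models explain more block
variance than they do on real data (the data are generated by those very
model families, minus the unmodelled human variability).

The synthetic discounting table draws `alpha ~ U(0, 2)`,
`gamma_P ~ U(0.85, 1)`, `gamma_D ~ U(0.7, 1)` per frame for the first 23
included subjects — plausible for a cohort in which dread is common, but
deliberately *unrelated* to the agents' generating heuristics, mirroring
the published finding that one-off discounting parameters correspond only
weakly to dynamic consumption behaviour.

## Numerical choices and limitations

* **Exactness at `gamma = 1`** — no geometric closed forms anywhere.
* **Softmax stability** — max-subtraction throughout; the spread component's
  softmax is factorised around the integer part of `rho` with a shift by
  the smallest distance, which is overflow-safe for any `rho`.
* **Sensitivity of the Income Maximization recursion** — at extreme inverse
  temperatures and long horizons the coupled policy/value recursion
  amplifies floating-point rounding noise (near-deterministic components,
  value range of order hundreds): two algebraically identical
  implementations can diverge visibly at bimodal high-capital states.
  Cross-implementation equality is therefore asserted exactly on short
  horizons and only to ~5e-3 at full scale; likelihood-level effects are
  negligible.  Relatedly, the likelihood surface at high temperatures is
  rugged — the multistart overlay is not an optional luxury for this model.
* **Recovery regimes** — parameter recovery for Direct Action draws
  generating temperatures uniformly over the full bounds.  A structural
  caveat surfaces there: when one component's temperature is extreme, a
  single 60-trial near-deterministic path carries almost no information
  about the other components' temperatures — the likelihood has flat
  ridges, and the fitted optimum can be (slightly) better than the
  generating point while lying far from it.  Recovery correlations for the
  spread temperature accordingly sit near 0.6–0.7 in that regime, and this
  is a property of the data/model pair, not of the optimizer (enlarging the
  multistart budget does not move it).  Model recovery
  (Income Maximization vs Direct Action) is run in the engaged,
  stochastic-choice regime (`beta_maximize` in `[1, 3]`, `gamma` in
  `[0.8, 0.95]`, moderate spread/spend temperatures): outside it the income
  component is disengaged and the two models generate identical behaviour,
  so the comparison would measure only BIC's parsimony penalty; at extreme
  temperatures it would instead measure optimizer failure on the rugged
  surface.  Within the engaged regime the generating model wins by large
  margins (BIC differences in the hundreds to thousands).
* **Problem sizes** — the analyses in `analysis/` and the acceptance script
  run the full 60-trial, 241-state task; demonstration simulations use the
  reduced 10-trial / 400 mg task (the source also mentions a 100-unit
  variant, supported via `task_config(n_trials = 10, budget_mg = 1000)`).
  Desk-scale fitting defaults (3 × 20 multistart; 2 × 15 with a looser
  simplex tolerance for the 20-replicate recovery study) keep each analysis
  in the minutes range on one CPU.
* **Limitations** — heuristic mixture weights are constant over trials by
  construction (the source notes time-varying weights as an open
  extension); the binary-choice experiment that produces the discounting
  parameters is consumed, not modelled; hierarchical (random-effects) model
  comparison is out of scope, as are shock-delivery hardware and
  calibration procedures.
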