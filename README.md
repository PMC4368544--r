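# reliefdyn

Dynamic consumption of pain relief: planners, heuristics, and model fitting.

## The problem

People routinely allocate a limited resource across time. This package
models one laboratory version of that problem: over 60 trials an agent
holds a budget of 2400 mg of computerized pain relief; each trial delivers
a Poisson number of electric shocks with mean `14 − 0.1·c_mg`, at most
120 mg may be spent per trial, and spending is irreversible
(`s_{t+1} = s_t − c_t`, no borrowing, no interest). Consumption is analysed
on a rounded grid of 13 actions (0–12 units of 10 mg) against the on-screen
even-spreading benchmark `ρ_t = s_t / (T − (t − 1))`.

The scientific questions are (i) what consumption paths are *optimal* under
an anticipation-discounting (dread/savoring) account of time preference,

    Δ(d) = γ_C^d + α · Σ_{τ=0}^{d−1} γ_C^{d−τ} γ_A^τ ,   U(c) = c^k ,

for naive and sophisticated agents; (ii) whether simple *heuristics* —
spend-now (`M_spend = c`), spread-spending (`M_spread = −|ρ_t − c|`), and
save-now-spend-later (`M_save = ρ_t − c` while `ρ_t < 12`) — describe
observed choices better; and (iii) how to decide between these accounts by
per-subject maximum likelihood and group fixed-effects BIC
(`−2L + k·ln n`).

The package is for computational/behavioral modellers: it provides the task
environment, exact backward-induction planners for the non-exponential
discount function (via an algebraic three-table decomposition, verified
against brute-force path enumeration), the three fitted choice models
(Direct Action, Income Maximization, combined optimal-plus-heuristic with
inverse-variance policy mixing and Gaussian spending biases), bounded
multistart Nelder–Mead fitting, behavioral classification, and a
synthetic-cohort generator so every analysis runs without the original
(non-redistributable) dataset. See the vignette
(`vignettes/relief-consumption-models.Rmd`) for the model details and design
choices.

## Worked example

Optimal behaviour on the reduced 10-trial / 400 mg demonstration task:

```r
library(reliefdyn)
cfg <- task_config(n_trials = 10, budget_mg = 400)

# no discounting, concave utility: spread evenly
dp0 <- discount_params(alpha = 0, gamma_c = 1, gamma_a = 1)
simulate_paths(sophisticated_policy(dp0, k = 0.75, beta = 10000, cfg),
               cfg, n = 1, seed = 1)
#>      [,1] [,2] [,3] [,4] [,5] [,6] [,7] [,8] [,9] [,10]
#> [1,]    4    4    4    4    4    4    4    4    4     4

# savoring dominates (alpha = 2, gamma = 1): save, then spend
dps <- discount_params(alpha = 2, gamma_c = 1, gamma_a = 1)
simulate_paths(sophisticated_policy(dps, 0.75, 10000, cfg), cfg, 1, seed = 1)
#>      [,1] [,2] [,3] [,4] [,5] [,6] [,7] [,8] [,9] [,10]
#> [1,]    0    0    0    0    0    0    4   12   12    12

# the naive agent's trial-1 plan reveals dynamic inconsistency: it intends
# to start consuming earlier than it ever will
round(naive_plan(dps, 0.75, 10000, cfg, i = 1), 1)
#>  [1]  0  0  0  1  1  2  4  8 12 12
```

The full cohort analysis lives in `analysis/` (numbered scripts, outputs
under `results/`):

```sh
Rscript analysis/01_simulate_planners.R   # utility/discounting regimes, naive vs sophisticated
Rscript analysis/02_build_cohorts.R       # synthetic study cohort + discounting table
Rscript analysis/03_fit_heuristic_models.R
Rscript analysis/04_fit_discounting_models.R
Rscript analysis/05_recovery.R
```

`02_build_cohorts.R` prints, for the 33-subject synthetic cohort (3
excluded pilots):

```
Behavioral classes among the 30 included subjects:
early-spending         saving      spreading
             2             15             13
Robust (bisquare IRLS) slope of consumption on trial: 0.514 mg/trial over 1980 choices
```

i.e. the designed 13/15/2 composition, and a rising consumption trend of
about half a milligram per trial — consumption is conserved early and spent
late. `03_fit_heuristic_models.R` then prints, for the same cohort:

```
Direct Action:        group BIC 2724.4, 10-trial R^2 0.89
Income Maximization:  group BIC 4198.1, 10-trial R^2 0.06
BIC improvement of Income Maximization: -1473.7
```

On this synthetic cohort the Direct Action model wins decisively — 24 of
the 30 included agents are generated from its components, and the extreme
save-then-spend shape is structurally hard for the Income Maximization
mixture — whereas on the original human data the ordering was reversed;
the vignette discusses why the stand-in carries structure-level but not
subject-level conclusions. The fitted Income Maximization mixture weights
put little weight on spending throughout (≈ 0.05) and shift weight from
spreading toward the income-maximizing (saving) component from the
mid-experiment onward (0.32 → 0.40). `04_fit_discounting_models.R` shows
the pure anticipation-discounting model explains almost none of the block
variance (R² ≈ 0.07 — the discounting parameters are deliberately
unrelated to the generating heuristics, mirroring the weak one-off/dynamic
correspondence in real subjects), while adding the Gaussian spending
biases recovers most of it and improves the group BIC over Income
Maximization by several hundred points.

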