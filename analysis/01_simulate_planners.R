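#!/usr/bin/env Rscript
# Optimal consumption under different utility and anticipation-discounting
# assumptions, on the reduced 10-trial / 400 mg demonstration task.
#
# Shows (i) that linear utility with no discounting leaves every
# budget-exhausting path equally valued (simulated consumption is random),
# while concave utility motivates even spreading; and (ii) the four
# qualitative regimes of the anticipation-discounting function, with naive
# and sophisticated planners diverging whenever anticipation is active.

library(reliefdyn)

dir.create("results", showWarnings = FALSE)
seed <- 1L

cfg <- task_config(n_trials = 10, budget_mg = 400)

rows <- list()
add <- function(label, agent, path) {
  rows[[length(rows) + 1]] <<- data.frame(
    scenario = label, agent = agent, trial = seq_along(path),
    consumption_units = as.integer(path))
}

## Utility-function effects (no discounting, no anticipation) ---------------
dp0 <- discount_params(alpha = 0, gamma_c = 1, gamma_a = 1)
lin <- simulate_paths(sophisticated_policy(dp0, k = 1, beta = 10000, cfg),
                      cfg, n = 2, seed = seed)
con <- simulate_paths(sophisticated_policy(dp0, k = 0.75, beta = 10000, cfg),
                      cfg, n = 2, seed = seed)
add("linear_utility", "sophisticated", lin[1, ])
add("linear_utility_rep2", "sophisticated", lin[2, ])
add("concave_utility", "sophisticated", con[1, ])
cat("Linear utility, no discounting: two sample optimal paths\n")
print(rbind(lin[1, ], lin[2, ]))
cat("Concave utility (k = 0.75): consumption spreads evenly at",
    con[1, 1], "units/trial\n\n")

## Four anticipation-discounting regimes ------------------------------------
regimes <- list(
  discounting_dominates = discount_params(0.1, 0.7, 1),
  no_discounting        = discount_params(0, 1, 1),
  savoring_dominates    = discount_params(2, 1, 1),
  discounted_savoring   = discount_params(2, 1, 0.7)
)
for (nm in names(regimes)) {
  dp <- regimes[[nm]]
  soph <- simulate_paths(sophisticated_policy(dp, 0.75, 10000, cfg), cfg,
                         n = 1, seed = seed)
  naiv <- simulate_naive_paths(dp, 0.75, 10000, cfg, n = 1, seed = seed)
  add(nm, "sophisticated", soph[1, ])
  add(nm, "naive", naiv[1, ])
  cat(sprintf("%-22s sophisticated: %s\n", nm,
              paste(soph[1, ], collapse = " ")))
  cat(sprintf("%-22s naive:         %s\n", nm,
              paste(naiv[1, ], collapse = " ")))
  # plans made in the first three periods reveal the dynamic inconsistency
  if (dp$alpha > 0) {
    plan1 <- naive_plan(dp, 0.75, 10000, cfg, i = 1)
    cat(sprintf("%-22s plan made at t=1: %s\n", "",
                paste(round(plan1, 1), collapse = " ")))
  }
}

paths_tab <- do.call(rbind, rows)
write.csv(paths_tab, "results/demo_consumption_paths.csv", row.names = FALSE)
cat("\nWrote", nrow(paths_tab), "rows to results/demo_consumption_paths.csv\n")
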