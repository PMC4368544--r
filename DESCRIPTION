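Package: reliefdyn
Title: Dynamic Consumption of Pain Relief: Planners, Heuristics and Model
    Fitting
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Models trial-by-trial consumption of a limited budget of pain
    relief over a finite horizon.  Implements the task environment (60 trials,
    2400 mg budget, 13-level action grid), optimal planning under
    anticipation-discounting (dread/savoring) for both naive and sophisticated
    agents via exact backward induction, heuristic choice models (Direct
    Action, Income Maximization, and an optimal-plus-heuristic mixture),
    per-subject maximum-likelihood fitting with bounded multistart
    Nelder-Mead, group-level BIC comparison, behavioral classification, and a
    synthetic-cohort generator for parameter- and model-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    MASS,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
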