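#' Task configuration for the relief-consumption experiment
#'
#' Defines the fixed environment of the dynamic pain-relief consumption task:
#' a finite horizon of trials, a total budget of relief in milligrams, a
#' per-trial cap, and the mapping from relief consumed to the expected number
#' of electric shocks on a trial.  Defaults are the published task constants:
#' 60 trials, 2400 mg budget, 10 mg units (so 240 units of capital), a cap of
#' 12 units (120 mg) per trial, a default shock mean of 14 shocks/trial
#' reduced by 0.1 shocks per mg of relief down to a baseline of 2.
#'
#' Internally all model code works on the rounded integer grid: capital
#' `s = 0..budget_units`, consumption `c = 0..min(s, max_per_trial_units)`.
#' Milligrams appear only at the data boundary.
#'
#' @param n_trials Number of trials `T` (horizon).
#' @param budget_mg Total relief budget in milligrams; must be divisible by
#'   `unit_mg`.
#' @param unit_mg Size of one unit of relief in milligrams.
#' @param max_per_trial_units Maximum consumption per trial, in units.
#' @param default_shock_mean Expected shocks per trial with no relief.
#' @param relief_effect Reduction in expected shocks per mg of relief.
#' @param baseline_shock_mean Expected shocks per trial at the per-trial cap.
#' @return An object of class `task_config`.
#' @examples
#' cfg <- task_config()
#' cfg$budget_units # 240
#' demo <- task_config(n_trials = 10, budget_mg = 400) # reduced demo task
#' @export
task_config <- function(n_trials = 60L, budget_mg = 2400, unit_mg = 10,
                        max_per_trial_units = 12L,
                        default_shock_mean = 14, relief_effect = 0.1,
                        baseline_shock_mean = 2) {
  cfg <- list(
    n_trials = as.integer(n_trials),
    budget_mg = budget_mg,
    unit_mg = unit_mg,
    max_per_trial_units = as.integer(max_per_trial_units),
    default_shock_mean = default_shock_mean,
    relief_effect = relief_effect,
    baseline_shock_mean = baseline_shock_mean
  )
  if (any(vapply(cfg, function(x) !is.numeric(x) || length(x) != 1 || is.na(x),
                 logical(1)))) {
    stop("all task_config fields must be single non-missing numbers")
  }
  if (cfg$n_trials < 1L) stop("n_trials must be >= 1")
  if (any(unlist(cfg) <= 0)) stop("all task_config fields must be positive")
  if (cfg$budget_mg %% cfg$unit_mg != 0) {
    stop("budget_mg must be divisible by unit_mg")
  }
  shock_floor <- cfg$default_shock_mean -
    cfg$max_per_trial_units * cfg$unit_mg * cfg$relief_effect
  if (abs(shock_floor - cfg$baseline_shock_mean) > 1e-9) {
    stop("shock mapping inconsistent: default mean - cap * unit * effect ",
         "must equal the baseline shock mean")
  }
  cfg$budget_units <- as.integer(cfg$budget_mg / cfg$unit_mg)
  class(cfg) <- "task_config"
  cfg
}

#' @export
print.task_config <- function(x, ...) {
  cat(sprintf(
    "Relief-consumption task: %d trials, %g mg budget (%d units of %g mg),\n",
    x$n_trials, x$budget_mg, x$budget_units, x$unit_mg))
  cat(sprintf(
    "  cap %d units/trial; shocks/trial: %g default, %g baseline (-%g per mg)\n",
    x$max_per_trial_units, x$default_shock_mean, x$baseline_shock_mean,
    x$relief_effect))
  invisible(x)
}

#' Write or read a task configuration as a plain-text key = value file
#'
#' @param cfg A `task_config`.
#' @param path File path.
#' @return `read_task_config` returns a `task_config`;
#'   `write_task_config` returns `path` invisibly.
#' @export
write_task_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "task_config"))
  keys <- setdiff(names(cfg), "budget_units")
  writeLines(sprintf("%s = %s", keys,
                     vapply(cfg[keys], format, character(1))), path)
  invisible(path)
}

#' @rdname write_task_config
#' @export
read_task_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(kv) != 2)) stop("malformed config line in ", path)
  vals <- as.numeric(trimws(vapply(kv, `[`, character(1), 2)))
  names(vals) <- trimws(vapply(kv, `[`, character(1), 1))
  do.call(task_config, as.list(vals))
}

#' Deterministic capital transition
#'
#' Capital evolves as `s' = s - c`; borrowing is not allowed and consumption
#' is capped per trial, so `0 <= c <= min(s, cap)`.
#'
#' @param s Capital in units (vectorised).
#' @param c Consumption in units (vectorised).
#' @param cfg A [task_config()].
#' @return Next-trial capital `s - c`.
#' @export
transition <- function(s, c, cfg = task_config()) {
  if (any(c < 0) || any(c > pmin(s, cfg$max_per_trial_units))) {
    stop("infeasible action: need 0 <= c <= min(s, ",
         cfg$max_per_trial_units, ")")
  }
  s - c
}

#' Mean relief remaining per trial
#'
#' The even-spreading benchmark displayed to participants:
#' `rho_t = s_t / (T - (t - 1))`, real-valued.
#'
#' @param s Capital in units at the start of trial `t`.
#' @param t Trial index, 1-based.
#' @param cfg A [task_config()] (supplies the horizon `T`).
#' @return Mean relief remaining, units/trial.
#' @export
mean_relief_remaining <- function(s, t, cfg = task_config()) {
  if (any(t < 1) || any(t > cfg$n_trials)) {
    stop("trial index out of range 1..", cfg$n_trials)
  }
  if (any(s < 0)) stop("capital must be non-negative")
  s / (cfg$n_trials - (t - 1))
}

#' Deviation from even spreading
#'
#' `d_t = rho_t - c_t`.  Positive values mean consuming less than the mean
#' relief remaining per trial (conserving relief).
#'
#' @param rho Mean relief remaining (units/trial).
#' @param c Consumption (units).
#' @return `rho - c`.
#' @export
deviation <- function(rho, c) rho - c

#' Expected number of shocks given relief consumed
#'
#' Shock counts on a trial are Poisson with mean
#' `default_shock_mean - relief_effect * c_mg`: 14 with no relief, down to the
#' baseline of 2 at the 120 mg cap.
#'
#' @param c_mg Relief consumed on the trial, in milligrams.
#' @param cfg A [task_config()].
#' @return Expected shocks per trial.
#' @export
expected_shocks <- function(c_mg, cfg = task_config()) {
  cap_mg <- cfg$max_per_trial_units * cfg$unit_mg
  if (any(c_mg < 0) || any(c_mg > cap_mg)) {
    stop("relief per trial must be within [0, ", cap_mg, "] mg")
  }
  cfg$default_shock_mean - cfg$relief_effect * c_mg
}

#' Sample Poisson shock counts
#'
#' @param rate Expected shocks per trial (vectorised).
#' @param n Number of draws per rate (when `rate` has length 1).
#' @return Integer shock counts.
#' @export
sample_shock_counts <- function(rate, n = length(rate)) {
  if (any(rate < 0)) stop("shock rate must be non-negative")
  if (length(rate) == 1) rpois(n, rate) else rpois(length(rate), rate)
}

#' Construct a consumption path with its capital trajectory
#'
#' A `consumption_path` stores one subject's 60 rounded choices (units) plus
#' the derived capital trajectory `s_1 = budget, s_{t+1} = s_t - c_t`, and
#' validates feasibility (no borrowing, per-trial cap, budget conservation).
#'
#' @param units Integer vector of length `cfg$n_trials`, consumption in units.
#' @param cfg A [task_config()].
#' @param subject_id Label for the subject.
#' @return An object of class `consumption_path` with elements `subject_id`,
#'   `units`, `capital` (capital at the start of each trial) and `final`
#'   (capital left after the last trial).
#' @export
consumption_path <- function(units, cfg = task_config(), subject_id = "s1") {
  units <- as.integer(round(units))
  if (length(units) != cfg$n_trials) {
    stop("need exactly ", cfg$n_trials, " trials, got ", length(units))
  }
  if (any(units < 0) || any(units > cfg$max_per_trial_units)) {
    stop("consumption out of range 0..", cfg$max_per_trial_units)
  }
  capital <- cfg$budget_units - c(0L, cumsum(units)[-cfg$n_trials])
  if (any(units > capital)) {
    stop("infeasible path: consumption exceeds remaining capital at trial ",
         which(units > capital)[1])
  }
  structure(list(subject_id = subject_id, units = units, capital = capital,
                 final = cfg$budget_units - sum(units), n_trials = cfg$n_trials,
                 budget_units = cfg$budget_units),
            class = "consumption_path")
}

#' @export
print.consumption_path <- function(x, ...) {
  cat(sprintf("consumption_path '%s': %d trials, %d/%d units consumed\n",
              x$subject_id, x$n_trials, sum(x$units), x$budget_units))
  invisible(x)
}

#' Round raw milligram consumption to units and enforce the budget online
#'
#' Raw choices are rounded to the nearest unit (10 mg; ties round half away
#' from zero by default, configurable to banker's rounding) and then clipped
#' sequentially in trial order so that rounded consumption never exceeds the
#' remaining rounded capital.  Earlier trials keep their rounded value; later
#' trials absorb the correction, which can create small fictitious final-trial
#' observations exactly as in the published data processing.
#'
#' @param raw_mg Numeric vector of raw consumption in milligrams, one per
#'   trial, each within `[0, 120]`.
#' @param cfg A [task_config()].
#' @param subject_id Label carried to the resulting path.
#' @param ties Tie-breaking for `.5` boundaries: `"half-up"` (away from zero,
#'   default) or `"half-even"` (IEEE/banker's, R's `round()`).
#' @return A [consumption_path()].
#' @export
round_and_correct <- function(raw_mg, cfg = task_config(), subject_id = "s1",
                              ties = c("half-up", "half-even")) {
  ties <- match.arg(ties)
  cap_mg <- cfg$max_per_trial_units * cfg$unit_mg
  if (any(raw_mg < 0) || any(raw_mg > cap_mg)) {
    stop("raw consumption out of range [0, ", cap_mg, "] mg at trial ",
         which(raw_mg < 0 | raw_mg > cap_mg)[1])
  }
  x <- raw_mg / cfg$unit_mg
  units <- if (ties == "half-up") floor(x + 0.5) else round(x)
  s <- cfg$budget_units
  out <- integer(length(units))
  for (t in seq_along(units)) {
    ct <- min(units[t], s, cfg$max_per_trial_units)
    out[t] <- ct
    s <- s - ct
  }
  consumption_path(out, cfg, subject_id)
}
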