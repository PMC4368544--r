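#' Robust slope of consumption on trial number
#'
#' Iteratively reweighted least squares with Tukey's bisquare weighting
#' (via [MASS::rlm()]) of consumption (milligrams) on trial index, pooling
#' all supplied choices.  Captures the overall tendency to conserve relief:
#' a positive slope means consumption rises over the session.
#'
#' @param consumption_mg Consumption in milligrams (all subject-trials).
#' @param trial Trial index for each observation.
#' @return Slope in mg/trial.
#' @export
robust_slope <- function(consumption_mg, trial) {
  stopifnot(length(consumption_mg) == length(trial))
  if (length(unique(trial)) < 2) stop("need at least two distinct trials")
  fit <- MASS::rlm(consumption_mg ~ trial, psi = MASS::psi.bisquare,
                   maxit = 100)
  unname(coef(fit)["trial"])
}

#' @rdname robust_slope
#' @param mg_matrix Subjects x trials matrix of consumption in mg.
#' @export
cohort_robust_slope <- function(mg_matrix) {
  trial <- rep(seq_len(ncol(mg_matrix)), each = nrow(mg_matrix))
  robust_slope(as.numeric(mg_matrix), trial)
}

#' Behavioral classification of a consumption path
#'
#' Summary metrics of one subject's (rounded) path and the three-way
#' classification used at the cohort level:
#' * `spreading` if the mean absolute deviation from even consumption,
#'   `mean(|rho_t - c_t|)`, is below 1 unit;
#' * otherwise `saving` if the mean signed deviation `mean(c_t - rho_t)` is
#'   at or below -1 unit;
#' * otherwise `early-spending` if that mean is at or above +1 unit;
#' * otherwise `mixed` (reported explicitly, never silently dropped).
#'
#' The signed deviation is reported as consumption minus the even-spreading
#' benchmark, so saving subjects score negative.
#'
#' @param path A [consumption_path()].
#' @param cfg A [task_config()].
#' @return A list of class `behavioral_metrics`: `slope` and `abs_slope`
#'   (least-squares slope of units on trial), `mean_signed_deviation`,
#'   `mean_abs_deviation`, `class`.
#' @export
classify_behavior <- function(path, cfg = task_config()) {
  tt <- seq_len(path$n_trials)
  rho <- mean_relief_remaining(path$capital, tt, cfg)
  msd <- mean(path$units - rho)
  mad <- mean(abs(rho - path$units))
  slope <- unname(coef(lm(path$units ~ tt))[2])
  cls <- if (mad < 1) "spreading"
         else if (msd <= -1) "saving"
         else if (msd >= 1) "early-spending"
         else "mixed"
  structure(list(subject_id = path$subject_id, slope = slope,
                 abs_slope = abs(slope), mean_signed_deviation = msd,
                 mean_abs_deviation = mad, class = cls),
            class = "behavioral_metrics")
}

#' @rdname classify_behavior
#' @param paths A list of [consumption_path()]s.
#' @return `classify_cohort`: a data.frame with one row per subject.
#' @export
classify_cohort <- function(paths, cfg = task_config()) {
  rows <- lapply(paths, function(p) {
    m <- classify_behavior(p, cfg)
    data.frame(subject_id = m$subject_id, slope = m$slope,
               abs_slope = m$abs_slope,
               mean_signed_deviation = m$mean_signed_deviation,
               mean_abs_deviation = m$mean_abs_deviation, class = m$class)
  })
  do.call(rbind, rows)
}

#' Ten-trial block R-squared between observed and model-predicted consumption
#'
#' For each subject, mean observed consumption is computed in consecutive
#' 10-trial blocks; the model's prediction of the same quantity is the mean
#' over `n_sims` paths simulated from that subject's maximum-likelihood
#' policy.  The statistic is the least-squares R-squared of observed block
#' means regressed on predicted block means across all subject-blocks.
#'
#' @param policies List of per-subject `policy_table`s at ML parameters.
#' @param paths List of matching [consumption_path()]s.
#' @param cfg A [task_config()].
#' @param n_sims Simulated paths per subject (the published analysis uses
#'   10000).
#' @param seed Base seed; subject `i` simulates with `seed + i`.
#' @param block Trials per block.
#' @return A list with `r_squared` and the per-subject-block `observed` and
#'   `predicted` means (units).
#' @export
ten_trial_r2 <- function(policies, paths, cfg = task_config(), n_sims = 10000,
                         seed = 1, block = 10) {
  stopifnot(length(policies) == length(paths), n_sims >= 1)
  grp <- rep(seq_len(cfg$n_trials / block), each = block)
  obs <- pred <- NULL
  for (i in seq_along(paths)) {
    sims <- simulate_paths(policies[[i]], cfg, n = n_sims,
                           seed = (seed + i) %% .Machine$integer.max)
    obs <- c(obs, tapply(paths[[i]]$units, grp, mean))
    pred <- c(pred, tapply(colMeans(sims), grp, mean))
  }
  r2 <- summary(lm(obs ~ pred))$r.squared
  list(r_squared = r2, observed = obs, predicted = pred)
}
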