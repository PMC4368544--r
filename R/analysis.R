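#' Fit and compare the two heuristic models on a cohort
#'
#' Runs the full heuristic-model pipeline used at the group level: fits the
#' Direct Action and Income Maximization models to every path by bounded
#' multistart maximum likelihood, computes the group fixed-effects BIC for
#' each, and the 10-trial block R-squared between observed and simulated
#' consumption at the per-subject ML parameters.
#'
#' @param paths List of [consumption_path()]s (typically the 30 included
#'   subjects).
#' @param cfg A [task_config()].
#' @param n_sims Simulated paths per subject for the block R-squared.
#' @param seed Base seed for fitting and simulation.
#' @param ... Fitting settings passed to [fit_subject()].
#' @return A list with per-model `fits`, `bic`, `r2`, and `delta_bic`
#'   (Direct Action minus Income Maximization; positive favours Income
#'   Maximization).
#' @export
run_heuristic_comparison <- function(paths, cfg = task_config(),
                                     n_sims = 10000, seed = 1, ...) {
  fits_da <- fit_cohort("direct_action", paths, cfg, seed = seed, ...)
  fits_im <- fit_cohort("income_max", paths, cfg, seed = seed + 500L, ...)
  pol_da <- lapply(fits_da, function(f) build_policy("direct_action", f$par, cfg))
  pol_im <- lapply(fits_im, function(f) build_policy("income_max", f$par, cfg))
  bic_da <- group_bic(fits_da)
  bic_im <- group_bic(fits_im)
  list(fits = list(direct_action = fits_da, income_max = fits_im),
       bic = list(direct_action = bic_da, income_max = bic_im),
       r2 = list(
         direct_action = ten_trial_r2(pol_da, paths, cfg, n_sims, seed)$r_squared,
         income_max = ten_trial_r2(pol_im, paths, cfg, n_sims, seed)$r_squared),
       delta_bic = bic_da$bic - bic_im$bic)
}

#' Fit and compare the anticipation-discounting models on a cohort
#'
#' For subjects with discounting parameters carried over from one-off binary
#' choices: fits the pure anticipation-discounting ("optimal") model (free
#' softmax temperature and utility exponent, discount parameters held fixed
#' per subject) and the combined optimal-plus-heuristic model (additionally
#' free Gaussian bias weights), computes each group BIC and block R-squared,
#' and — for the model-comparison surface — also fits the Income
#' Maximization model to the same subjects.
#'
#' @param paths List of [consumption_path()]s (subjects with estimable
#'   discounting parameters).
#' @param dp_list List of per-subject [discount_params()], parallel to
#'   `paths`.
#' @param cfg A [task_config()].
#' @param n_sims Simulated paths per subject for the block R-squared.
#' @param seed Base seed.
#' @param ... Fitting settings passed to [fit_subject()].
#' @return A list with per-model `fits`, `bic`, `r2`, and
#'   `delta_bic_combined_vs_income_max` (Income Maximization minus combined;
#'   positive favours the combined model).
#' @export
run_discounting_comparison <- function(paths, dp_list, cfg = task_config(),
                                       n_sims = 10000, seed = 1, ...) {
  stopifnot(length(paths) == length(dp_list))
  fits_opt <- fit_cohort("optimal", paths, cfg, dp_list = dp_list,
                         seed = seed, ...)
  fits_comb <- fit_cohort("combined", paths, cfg, dp_list = dp_list,
                          seed = seed + 500L, ...)
  fits_im <- fit_cohort("income_max", paths, cfg, seed = seed + 1000L, ...)
  pol_opt <- lapply(seq_along(paths), function(i) {
    build_policy("optimal", fits_opt[[i]]$par, cfg, dp_list[[i]])
  })
  pol_comb <- lapply(seq_along(paths), function(i) {
    build_policy("combined", fits_comb[[i]]$par, cfg, dp_list[[i]])
  })
  bic_opt <- group_bic(fits_opt)
  bic_comb <- group_bic(fits_comb)
  bic_im <- group_bic(fits_im)
  list(fits = list(optimal = fits_opt, combined = fits_comb,
                   income_max = fits_im),
       bic = list(optimal = bic_opt, combined = bic_comb,
                  income_max = bic_im),
       r2 = list(
         optimal = ten_trial_r2(pol_opt, paths, cfg, n_sims, seed)$r_squared,
         combined = ten_trial_r2(pol_comb, paths, cfg, n_sims, seed)$r_squared),
       delta_bic_combined_vs_income_max = bic_im$bic - bic_comb$bic)
}

#' Mixture-weight timecourse along observed paths
#'
#' For policy tables that carry inverse-variance mixture weights (Direct
#' Action and Income Maximization), extracts the component weights at each
#' subject's observed state on every trial and averages across subjects —
#' the group-level weighting timecourse of the heuristics.
#'
#' @param policies List of per-subject `policy_table`s with a `weights`
#'   array.
#' @param paths Matching list of [consumption_path()]s.
#' @return A `T x 3` matrix of mean weights (`spend`, `spread`, third
#'   component: save or income-maximization).
#' @export
weight_timecourse <- function(policies, paths) {
  stopifnot(length(policies) == length(paths))
  acc <- 0
  for (i in seq_along(paths)) {
    w <- policies[[i]]$weights # 3 x (S+1) x T
    tt <- seq_len(paths[[i]]$n_trials)
    acc <- acc + vapply(1:3, function(cmp) {
      w[cbind(cmp, paths[[i]]$capital + 1L, tt)]
    }, numeric(length(tt)))
  }
  out <- acc / length(paths)
  colnames(out) <- c("spend", "spread", "third")
  out
}
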