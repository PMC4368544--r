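#' Heuristic action propensities
#'
#' The three rule-of-thumb propensities over consumption `c` given the mean
#' relief remaining `rho`:
#' * spend-now-suffer-later: `M_spend = c` (linear pull toward the cap);
#' * spread-spending: `M_spread = -|rho - c|` (penalises deviation from even
#'   spreading);
#' * save-now-spend-later: `M_save = rho - c` while `rho < cap`, and 0 for
#'   every action once the mean relief remaining reaches the per-trial cap
#'   (the policy component goes uniform and the other heuristics take over).
#'
#' Propensities are evaluated with the real-valued `rho`.
#'
#' @param c Consumption in units (vectorised).
#' @param rho Mean relief remaining, units/trial.
#' @param cap Per-trial consumption cap in units.
#' @return Propensity in utils.
#' @export
propensity_spend <- function(c) c

#' @rdname propensity_spend
#' @export
propensity_spread <- function(rho, c) -abs(rho - c)

#' @rdname propensity_spend
#' @export
propensity_save <- function(rho, c, cap = 12) {
  out <- rho - c
  out[rep_len(rho >= cap, length(out))] <- 0
  out
}

#' Gaussian spending bias toward a salient quantity
#'
#' Action values proportional to a Gaussian density with standard deviation 2
#' units, centred at 0 (`"min"`), at the mean relief remaining (`"mean"`), or
#' at the largest feasible spend `min(cap, s)` (`"max"`).  Values are raw pdf
#' ordinates (any rescaling is absorbed by the bias weights omega).
#'
#' @param kind One of `"min"`, `"mean"`, `"max"`.
#' @param s Capital in units.
#' @param t Trial index.
#' @param cfg A [task_config()].
#' @return Numeric vector over actions `c = 0..cap`.
#' @export
gaussian_bias <- function(kind = c("min", "mean", "max"), s, t,
                          cfg = task_config()) {
  kind <- match.arg(kind)
  acts <- 0:cfg$max_per_trial_units
  centre <- switch(kind,
                   min = 0,
                   mean = mean_relief_remaining(s, t, cfg),
                   max = min(cfg$max_per_trial_units, s))
  dnorm(acts, mean = centre, sd = 2)
}

#' Combine component policies by inverse-variance weighting
#'
#' Each component policy implies a distribution over the consumption amount;
#' the mixture weight of component `i` is proportional to the reciprocal of
#' `Var(c)` under that component (floored at 1e-10 so that a single
#' degenerate component cannot claim infinite weight), and the mixed policy
#' is the weighted average of the component probabilities.
#'
#' @param policies A matrix with one row per component policy, columns being
#'   probabilities over the same action set (each row sums to 1).
#' @param floor Variance floor.
#' @return A list with `mix` (the combined probability vector) and `weights`.
#' @export
inverse_variance_mix <- function(policies, floor = 1e-10) {
  if (is.null(dim(policies)) || nrow(policies) < 2) {
    stop("need at least two component policies")
  }
  acts <- seq_len(ncol(policies)) - 1
  v <- apply(policies, 1, function(p) sum(p * acts^2) - sum(p * acts)^2)
  if (all(v <= 0) && floor <= 0) stop("all component variances are zero")
  iv <- 1 / pmax(v, floor)
  w <- iv / sum(iv)
  list(mix = as.numeric(w %*% policies), weights = w)
}

#' Direct Action heuristic policy at given states
#'
#' The three propensities are implemented as separate softmax policies with
#' their own inverse temperatures and combined by inverse-variance weighting
#' at each state.  This evaluates the mixed policy at arbitrary `(s, t)`
#' pairs (the model is local in state, so the likelihood only needs the 60
#' observed states).
#'
#' @param s Capital in units (vectorised).
#' @param t Trial index (vectorised, same length).
#' @param params Named list/vector with `beta_spend`, `beta_spread`,
#'   `beta_save`, each in `[0, 10]`.
#' @param cfg A [task_config()].
#' @return A `length(s) x (cap+1)` matrix of choice probabilities.
#' @export
direct_action_policy_at <- function(s, t, params, cfg = task_config()) {
  params <- as.list(params)
  A <- cfg$max_per_trial_units
  acts <- 0:A
  n <- length(s)
  rho <- mean_relief_remaining(s, t, cfg)
  feas <- outer(s, acts, ">=") # c <= min(s, A); acts already <= A
  row_softmax <- function(M, beta) {
    M[!feas] <- NA
    P <- exp(beta * (M - apply(M, 1, max, na.rm = TRUE)))
    P[!feas] <- 0
    P / rowSums(P)
  }
  Cmat <- matrix(acts, n, A + 1, byrow = TRUE)
  P1 <- row_softmax(Cmat, params$beta_spend)
  P2 <- row_softmax(-abs(rho - Cmat), params$beta_spread)
  Rmat <- matrix(rho, n, A + 1)
  P3 <- row_softmax(propensity_save(Rmat, Cmat, A), params$beta_save)
  mix_rows(P1, P2, P3, acts)
}

# Inverse-variance mixture applied row-wise to three policy matrices.
mix_rows <- function(P1, P2, P3, acts, floor = 1e-10) {
  vars <- function(P) pmax(P %*% acts^2 - (P %*% acts)^2, floor)
  iv1 <- 1 / vars(P1); iv2 <- 1 / vars(P2); iv3 <- 1 / vars(P3)
  z <- iv1 + iv2 + iv3
  out <- (c(iv1) * P1 + c(iv2) * P2 + c(iv3) * P3) / c(z)
  attr(out, "weights") <- cbind(spend = c(iv1 / z), spread = c(iv2 / z),
                                third = c(iv3 / z))
  out
}

#' Direct Action heuristic policy table
#'
#' Full `p(c | s, t)` table for the Direct Action model (see
#' [direct_action_policy_at()]).
#'
#' @inheritParams direct_action_policy_at
#' @return A `policy_table` carrying a `weights` array
#'   (`3 x (S+1) x T`: spend, spread, save mixture weights).
#' @export
direct_action_policy <- function(params, cfg = task_config()) {
  S <- cfg$budget_units
  T <- cfg$n_trials
  prob <- array(0, c(cfg$max_per_trial_units + 1L, S + 1L, T))
  wts <- array(0, c(3, S + 1L, T))
  for (t in seq_len(T)) {
    P <- direct_action_policy_at(0:S, rep(t, S + 1), params, cfg)
    prob[, , t] <- t(P)
    wts[, , t] <- t(attr(P, "weights"))
  }
  new_policy_table(prob, "direct_action", as.list(params), cfg,
                   extras = list(weights = wts))
}

#' Income Maximization heuristic policy table
#'
#' Replaces the save propensity of the Direct Action model with an
#' action-value that maximises the expected stream of mean relief remaining
#' (`rho`) over a `gamma`-discounted future horizon, computed by backward
#' induction under the mixture policy itself: the trial-`t` mixture depends
#' only on mixtures at `t+1..T`, so the circularity resolves strictly
#' backward.  Components are mixed by inverse-variance weighting as in the
#' Direct Action model.
#'
#' @param params Named list/vector with `beta_spend`, `beta_spread`,
#'   `beta_maximize` in `[0, 10]` and `gamma` in `[0, 1]` (the probability of
#'   searching one step deeper; `gamma = 0` makes the component uniform).
#' @param cfg A [task_config()].
#' @return A `policy_table` carrying `weights` (`3 x (S+1) x T`) and `w`
#'   (`(S+1) x T`, the income value table used by [income_max_q()]).
#' @export
income_max_policy <- function(params, cfg = task_config()) {
  params <- as.list(params)
  stopifnot(params$gamma >= 0, params$gamma <= 1)
  res <- cpp_income_max_policy(cfg$n_trials, cfg$budget_units,
                               cfg$max_per_trial_units,
                               params$beta_spend, params$beta_spread,
                               params$beta_maximize, params$gamma)
  wts <- res$weights
  dim(wts) <- c(3, cfg$budget_units + 1L, cfg$n_trials)
  w <- res$w
  dim(w) <- c(cfg$budget_units + 1L, cfg$n_trials)
  new_policy_table(res$prob, "income_max", params, cfg,
                   extras = list(weights = wts, w = w))
}

#' Income-maximization action values at a state
#'
#' `Q(s, c, t) = rho_t(s) + gamma * W_{t+1}(s - c)` where `W` is the
#' expected discounted stream of mean relief remaining under the fitted
#' mixture policy (taken from an [income_max_policy()] table).  At `t = T`
#' there is no future and the value is `rho_T(s)` for every action.
#'
#' @param policy An [income_max_policy()] table.
#' @param s Capital in units.
#' @param t Trial index.
#' @param cfg A [task_config()].
#' @return Numeric vector over feasible actions `c = 0..min(s, cap)`.
#' @export
income_max_q <- function(policy, s, t, cfg = task_config()) {
  stopifnot(policy$model == "income_max")
  acts <- 0:min(s, cfg$max_per_trial_units)
  rho <- mean_relief_remaining(s, t, cfg)
  if (t < cfg$n_trials) {
    rho + policy$params$gamma * policy$w[s - acts + 1L, t + 1L]
  } else {
    rep(rho, length(acts))
  }
}

#' Combined optimal-plus-heuristic policy
#'
#' Augments the sophisticated anticipation-discounting Q-values with Gaussian
#' biases toward spending zero, the mean remaining, or the maximum relief
#' (see [gaussian_bias()]), weighted by `omega_min`, `omega_mean`,
#' `omega_max`, before the softmax.  The future policy inside the planner's
#' expectation is the biased policy itself (the agent is sophisticated about
#' its own biases).  With all omegas zero this reduces exactly to
#' [sophisticated_policy()].
#'
#' @param dp A [discount_params()] (held fixed, e.g. from one-off binary
#'   choice estimates).
#' @param params Named list/vector with `beta` in `[0, 10]`, `k` in `(0, 1]`,
#'   and nonnegative `omega_min`, `omega_mean`, `omega_max`.
#' @param cfg A [task_config()].
#' @return A `policy_table`.
#' @export
combined_policy <- function(dp, params, cfg = task_config()) {
  params <- as.list(params)
  stopifnot(params$omega_min >= 0, params$omega_mean >= 0,
            params$omega_max >= 0)
  res <- cpp_anticipation_policy(cfg$n_trials, cfg$budget_units,
                                 cfg$max_per_trial_units,
                                 dp$alpha, dp$gamma_c, dp$gamma_a,
                                 params$k, params$beta,
                                 params$omega_min, params$omega_mean,
                                 params$omega_max, FALSE)
  new_policy_table(res$prob, "combined",
                   c(params, list(alpha = dp$alpha, gamma_c = dp$gamma_c,
                                  gamma_a = dp$gamma_a)),
                   cfg, params$beta)
}

#' Registered choice models
#'
#' Model names used by the fitting interface, with their free parameters and
#' fitting bounds.  The heuristic softmax temperatures are bounded `[0, 10]`,
#' the income-maximization search-continuation probability `gamma` is in
#' `[0, 1]`, the utility exponent `k` in `(0, 1]`, and the bias weights of
#' the combined model in `[0, 100]`.
#'
#' @return `relief_models()`: character vector of model names.
#' @export
relief_models <- function() {
  c("direct_action", "income_max", "optimal", "combined")
}

#' @rdname relief_models
#' @param model Model name.
#' @return `model_bounds()`: a list with named `lower` and `upper` vectors.
#' @export
model_bounds <- function(model) {
  switch(match.arg(model, relief_models()),
    direct_action = list(
      lower = c(beta_spend = 0, beta_spread = 0, beta_save = 0),
      upper = c(beta_spend = 10, beta_spread = 10, beta_save = 10)),
    income_max = list(
      lower = c(beta_spend = 0, beta_spread = 0, beta_maximize = 0, gamma = 0),
      upper = c(beta_spend = 10, beta_spread = 10, beta_maximize = 10,
                gamma = 1)),
    optimal = list(lower = c(beta = 0, k = 0.01),
                   upper = c(beta = 10, k = 1)),
    combined = list(
      lower = c(beta = 0, k = 0.01, omega_min = 0, omega_mean = 0,
                omega_max = 0),
      upper = c(beta = 10, k = 1, omega_min = 100, omega_mean = 100,
                omega_max = 100))
  )
}

#' Build a policy table for a registered model
#'
#' @param model One of [relief_models()].
#' @param params Named parameter vector/list (see [model_bounds()]).
#' @param cfg A [task_config()].
#' @param dp A [discount_params()]; required for `"optimal"` and
#'   `"combined"`.
#' @return A `policy_table`.
#' @export
build_policy <- function(model, params, cfg = task_config(), dp = NULL) {
  model <- match.arg(model, relief_models())
  params <- as.list(params)
  switch(model,
    direct_action = direct_action_policy(params, cfg),
    income_max = income_max_policy(params, cfg),
    optimal = {
      if (is.null(dp)) stop("the optimal model needs discount parameters")
      sophisticated_policy(dp, k = params$k, beta = params$beta, cfg)
    },
    combined = {
      if (is.null(dp)) stop("the combined model needs discount parameters")
      combined_policy(dp, params, cfg)
    })
}
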