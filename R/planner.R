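#' Softmax choice probabilities over feasible actions
#'
#' `p_i = exp(beta * q_i) / sum_j exp(beta * q_j)`, computed with
#' max-subtraction for numerical stability.  `beta = 0` yields the uniform
#' distribution; large `beta` concentrates mass on the maximising action
#' (exact ties split evenly; no argmax is ever taken).
#'
#' @param values Action values (one per feasible action).
#' @param beta Inverse temperature, `>= 0`.
#' @return Probability vector of the same length as `values`.
#' @export
softmax_policy <- function(values, beta) {
  if (length(values) == 0) stop("empty action set")
  if (beta < 0) stop("beta must be non-negative")
  z <- exp(beta * (values - max(values)))
  z / sum(z)
}

new_policy_table <- function(prob, model, params, cfg, beta = NULL,
                             extras = list()) {
  A1 <- cfg$max_per_trial_units + 1L
  S1 <- cfg$budget_units + 1L
  dim(prob) <- c(A1, S1, cfg$n_trials)
  out <- c(list(prob = prob, model = model, params = params,
                n_trials = cfg$n_trials, budget_units = cfg$budget_units,
                max_per_trial_units = cfg$max_per_trial_units, beta = beta),
           extras)
  class(out) <- "policy_table"
  out
}

#' @export
print.policy_table <- function(x, ...) {
  cat(sprintf("policy_table (%s): p(c | s, t) on c = 0..%d, s = 0..%d, t = 1..%d\n",
              x$model, x$max_per_trial_units, x$budget_units, x$n_trials))
  invisible(x)
}

#' Extract choice probabilities from a policy table
#'
#' @param policy A `policy_table`.
#' @param s Capital in units (vectorised, same length as `t`).
#' @param t Trial index (vectorised).
#' @return A `length(s) x (cap+1)` matrix of probabilities over `c = 0..cap`.
#' @export
policy_prob <- function(policy, s, t) {
  stopifnot(length(s) == length(t))
  out <- t(vapply(seq_along(s),
                  function(i) policy$prob[, s[i] + 1L, t[i]],
                  numeric(policy$max_per_trial_units + 1L)))
  colnames(out) <- 0:policy$max_per_trial_units
  out
}

#' Check normalisation and feasibility of a policy table
#'
#' Every state/trial row must sum to 1 (within `tol`) and place zero mass on
#' infeasible actions `c > min(s, cap)`.  Used throughout the test-suite.
#'
#' @param policy A `policy_table`.
#' @param tol Normalisation tolerance.
#' @return `TRUE` invisibly; otherwise an error.
#' @export
check_policy <- function(policy, tol = 1e-9) {
  p <- policy$prob
  sums <- apply(p, c(2, 3), sum)
  if (any(abs(sums - 1) > tol)) stop("policy rows not normalised")
  A <- policy$max_per_trial_units
  for (s in 0:min(A - 1, policy$budget_units)) {
    if (any(p[(s + 2):(A + 1), s + 1, ] != 0)) {
      stop("positive mass on infeasible action at s = ", s)
    }
  }
  invisible(TRUE)
}

#' Sophisticated optimal policy under anticipation-discounting
#'
#' Solves the finite-horizon consumption-savings task by backward induction
#' for a fully sophisticated agent: the Q-value of consuming `c` at `(s, t)`
#' is the immediate utility plus the policy-expected, delay-weighted utility
#' of all future consumption, with delay weights given by the
#' anticipation-discounting function `Delta(d)`.  Because `Delta` is not
#' exponential, the recursion is carried by three coupled value tables (an
#' exponential table at rate `gamma_c`, one at `gamma_a`, and the
#' anticipation stream); the decomposition is exact algebra, verified against
#' [brute_force_policy()] in the tests.
#'
#' @param dp A [discount_params()].
#' @param k Utility exponent, `(0, 1]`.
#' @param beta Softmax inverse temperature (the published optimal-path
#'   simulations use `beta = 10000`).
#' @param cfg A [task_config()].
#' @param keep_q Keep the Q-value table alongside the probabilities.
#' @return A `policy_table`; with `keep_q = TRUE` it carries a `q` array of
#'   the same shape (NA at infeasible actions).
#' @export
sophisticated_policy <- function(dp, k = 1, beta = 10000, cfg = task_config(),
                                 keep_q = FALSE) {
  stopifnot(beta >= 0, k > 0, k <= 1)
  res <- cpp_anticipation_policy(cfg$n_trials, cfg$budget_units,
                                 cfg$max_per_trial_units,
                                 dp$alpha, dp$gamma_c, dp$gamma_a,
                                 k, beta, 0, 0, 0, keep_q)
  extras <- list()
  if (keep_q) {
    q <- res$q
    dim(q) <- c(cfg$max_per_trial_units + 1L, cfg$budget_units + 1L,
                cfg$n_trials)
    extras$q <- q
  }
  new_policy_table(res$prob, "optimal",
                   list(alpha = dp$alpha, gamma_c = dp$gamma_c,
                        gamma_a = dp$gamma_a, k = k, beta = beta),
                   cfg, beta, extras)
}

#' Simulate consumption paths from a policy table
#'
#' Samples `n` trial-by-trial paths with exact budget bookkeeping: at each
#' trial the action is drawn from `p(c | s_t, t)` and capital is advanced
#' deterministically.
#'
#' @param policy A `policy_table`.
#' @param cfg A [task_config()] (consistent with the policy).
#' @param n Number of paths.
#' @param seed Optional integer seed for reproducibility.
#' @return An `n x T` integer matrix of consumption in units.
#' @export
simulate_paths <- function(policy, cfg = task_config(), n = 1, seed = NULL) {
  stopifnot(n >= 1, policy$n_trials == cfg$n_trials,
            policy$budget_units == cfg$budget_units)
  if (!is.null(seed)) set.seed(seed)
  T <- cfg$n_trials
  paths <- matrix(0L, n, T)
  s <- rep(cfg$budget_units, n)
  acts <- 0:cfg$max_per_trial_units
  for (t in seq_len(T)) {
    for (v in unique(s)) {
      idx <- which(s == v)
      p <- policy$prob[, v + 1L, t]
      paths[idx, t] <- sample(acts, length(idx), replace = TRUE, prob = p)
    }
    s <- s - paths[, t]
  }
  paths
}

# (S+1) x (A+1) matrix of future-state indices s - c + 1, NA where infeasible.
future_index_matrix <- function(S, A) {
  idx <- outer(0:S, 0:A, function(s, c) ifelse(c <= pmin(s, A), s - c + 1L, NA))
  idx
}

#' Naive planner: Q-values from a fixed planning perspective
#'
#' A naive agent planning at trial `i` weights utility at trial `t >= i` by
#' `Delta(t - i)` and assumes its future selves will share those weights.
#' This solves the corresponding backward induction from `T` down to `i`,
#' where the imagined future policy at each `t` is the softmax of the
#' perspective-`i` Q-values.  With `alpha = 0` the weights are exponential
#' and planning is dynamically consistent; with anticipation (`alpha > 0`)
#' the realised behaviour of later selves deviates from the plan.
#'
#' @param dp A [discount_params()].
#' @param k Utility exponent.
#' @param beta Softmax inverse temperature.
#' @param cfg A [task_config()].
#' @param i Planning trial (perspective), `1 <= i <= T`.
#' @return A list with `prob` and `q` arrays of dimension
#'   `(cap+1) x (S+1) x T`; entries for `t < i` are NA/0 (never planned).
#' @export
naive_policy <- function(dp, k = 1, beta = 10000, cfg = task_config(), i = 1L) {
  stopifnot(i >= 1, i <= cfg$n_trials)
  T <- cfg$n_trials; S <- cfg$budget_units; A <- cfg$max_per_trial_units
  U <- utility(0:A, k)
  w <- anticipation_discount(0:(T - i), dp) # Delta(t - i) for t = i..T
  idx <- future_index_matrix(S, A)
  Umat <- matrix(U, S + 1, A + 1, byrow = TRUE)
  Umat[is.na(idx)] <- NA
  prob <- array(0, c(A + 1, S + 1, T))
  qarr <- array(NA_real_, c(A + 1, S + 1, T))
  V1 <- numeric(S + 1)
  for (t in T:i) {
    Q <- w[t - i + 1] * Umat
    if (t < T) Q <- Q + matrix(V1[idx], S + 1, A + 1)
    P <- exp(beta * (Q - apply(Q, 1, max, na.rm = TRUE)))
    P[is.na(P)] <- 0
    P <- P / rowSums(P)
    V1 <- rowSums(P * ifelse(is.na(Q), 0, Q))
    prob[, , t] <- t(P)
    qarr[, , t] <- t(Q)
  }
  list(prob = prob, q = qarr, i = i)
}

#' Naive consumption plan made at trial i
#'
#' The intended consumption sequence for trials `t = i..T`, computed as the
#' expected consumption under the perspective-`i` policy, propagating the
#' full distribution over capital forward from `s_i` (deterministic; no
#' argmax or sampling involved).
#'
#' @inheritParams naive_policy
#' @param s_i Capital in units held at trial `i`.
#' @return Numeric vector of planned consumption for `t = i..T`.
#' @export
naive_plan <- function(dp, k = 1, beta = 10000, cfg = task_config(),
                       i = 1L, s_i = cfg$budget_units) {
  pol <- naive_policy(dp, k, beta, cfg, i)
  S <- cfg$budget_units; A <- cfg$max_per_trial_units
  dist <- numeric(S + 1); dist[s_i + 1] <- 1
  plan <- numeric(cfg$n_trials - i + 1)
  for (t in i:cfg$n_trials) {
    P <- pol$prob[, , t] # (A+1) x (S+1)
    ec <- colSums(P * 0:A)
    plan[t - i + 1] <- sum(dist * ec)
    nxt <- numeric(S + 1)
    for (s in which(dist > 0) - 1L) {
      p <- P[, s + 1]
      cs <- which(p > 0) - 1L
      nxt[s - cs + 1L] <- nxt[s - cs + 1L] + dist[s + 1] * p[cs + 1L]
    }
    dist <- nxt
  }
  plan
}

#' Simulate realised consumption paths for a naive agent
#'
#' At each actual trial `i` the agent re-plans from scratch
#' ([naive_policy()] at perspective `i`) and samples its trial-`i` action from
#' the softmax over the perspective-`i` Q-values at the current capital
#' (`Delta(0) = 1`, so the immediate term is undiscounted), then advances.
#'
#' @inheritParams naive_policy
#' @param n Number of paths.
#' @param seed Optional integer seed.
#' @return An `n x T` integer matrix of consumption in units.
#' @export
simulate_naive_paths <- function(dp, k = 1, beta = 10000, cfg = task_config(),
                                 n = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  T <- cfg$n_trials
  paths <- matrix(0L, n, T)
  s <- rep(cfg$budget_units, n)
  acts <- 0:cfg$max_per_trial_units
  for (i in seq_len(T)) {
    pol <- naive_policy(dp, k, beta, cfg, i)
    for (v in unique(s)) {
      idx <- which(s == v)
      p <- pol$prob[, v + 1L, i]
      paths[idx, i] <- sample(acts, length(idx), replace = TRUE, prob = p)
    }
    s <- s - paths[, i]
  }
  paths
}

#' Brute-force sophisticated policy by path enumeration (testing oracle)
#'
#' Computes the sophisticated Q-values directly from their definition: for
#' each state and action, every future action sequence is enumerated
#' depth-first, weighted by its probability under the (already computed)
#' later-trial softmax policies, and its delay-weighted utilities
#' `Delta(d) * U(c)` are summed.  No exponential decomposition is involved,
#' which makes this an independent oracle for [sophisticated_policy()].
#' Refuses instances beyond `T <= 6` or budgets above 12 units.
#'
#' @inheritParams sophisticated_policy
#' @return A list with `prob` and `q` arrays of dimension
#'   `(cap+1) x (S+1) x T`.
#' @export
brute_force_policy <- function(dp, k = 1, beta = 1, cfg) {
  T <- cfg$n_trials; S <- cfg$budget_units; A <- cfg$max_per_trial_units
  if (T > 6 || S > 12) stop("brute-force enumeration limited to T <= 6, budget <= 12")
  delta <- anticipation_discount(0:T, dp)
  U <- utility(0:A, k)
  prob <- array(0, c(A + 1, S + 1, T))
  qarr <- array(NA_real_, c(A + 1, S + 1, T))
  # Expected sum of Delta(off + j) * U(c_{tp + j}) over all sequences from
  # (sp, tp), recursing down the action tree with policy weights.
  stream <- function(sp, tp, off) {
    if (tp > T) return(0)
    p <- prob[, sp + 1, tp]
    val <- 0
    for (c in 0:min(sp, A)) {
      if (p[c + 1] == 0) next
      val <- val + p[c + 1] * (delta[off + 1] * U[c + 1] +
                                 stream(sp - c, tp + 1, off + 1))
    }
    val
  }
  for (t in T:1) {
    for (s in 0:S) {
      cs <- 0:min(s, A)
      q <- vapply(cs, function(c) U[c + 1] + stream(s - c, t + 1, 1), numeric(1))
      prob[cs + 1, s + 1, t] <- softmax_policy(q, beta)
      qarr[cs + 1, s + 1, t] <- q
    }
  }
  list(prob = prob, q = qarr)
}

#' @rdname brute_force_policy
#' @export
brute_force_q <- function(dp, k = 1, beta = 1, cfg) {
  brute_force_policy(dp, k, beta, cfg)$q
}

#' Total delay-weighted value of a complete consumption path
#'
#' Evaluates `sum_t Delta(t - 1) * U(c_t)` for a fixed path as seen from the
#' first trial.  With linear utility and no discounting this equals total
#' consumption, so every budget-exhausting path has the same value.
#'
#' @param units Consumption path in units.
#' @param dp A [discount_params()].
#' @param k Utility exponent.
#' @return Scalar path value in utils.
#' @export
path_value <- function(units, dp, k = 1) {
  d <- seq_along(units) - 1
  sum(anticipation_discount(d, dp) * utility(units, k))
}
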