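# Shared fixtures and independent reference implementations used as oracles.

# Small task variants (the shock-mapping fields keep their defaults, which
# remain mutually consistent).
tiny_cfg <- function(T, S) task_config(n_trials = T, budget_mg = S * 10)
demo_cfg <- function() task_config(n_trials = 10, budget_mg = 400)

# The study-scale synthetic cohort is expensive to build; cache it per run.
.fixture_cache <- new.env(parent = emptyenv())
study_fixture <- function() {
  if (is.null(.fixture_cache$cohort)) {
    .fixture_cache$cohort <- synthetic_study_cohort(task_config())
  }
  .fixture_cache$cohort
}

# Plain-R reference for the Income Maximization mixture policy: direct
# softmaxes (no factorisation), direct variance computation.  Independent of
# the C++ kernel.
r_income_max_policy <- function(par, cfg) {
  T <- cfg$n_trials; S <- cfg$budget_units; A <- cfg$max_per_trial_units
  prob <- array(0, c(A + 1, S + 1, T))
  W1 <- numeric(S + 1)
  Wt <- matrix(0, S + 1, T)
  sm <- function(v, b) { z <- exp(b * (v - max(v))); z / sum(z) }
  for (t in T:1) {
    W0 <- numeric(S + 1)
    for (s in 0:S) {
      n <- min(s, A) + 1; acts <- 0:(n - 1); rho <- s / (T - t + 1)
      p1 <- sm(acts, par$beta_spend)
      p2 <- sm(-abs(rho - acts), par$beta_spread)
      q3 <- if (t < T) rho + par$gamma * W1[s - acts + 1] else rep(rho, n)
      p3 <- sm(q3, par$beta_maximize)
      v <- sapply(list(p1, p2, p3),
                  function(p) sum(p * acts^2) - sum(p * acts)^2)
      iv <- 1 / pmax(v, 1e-10)
      w <- iv / sum(iv)
      pmix <- w[1] * p1 + w[2] * p2 + w[3] * p3
      prob[acts + 1, s + 1, t] <- pmix
      W0[s + 1] <- rho + if (t < T) par$gamma * sum(pmix * W1[s - acts + 1]) else 0
    }
    Wt[, t] <- W0
    W1 <- W0
  }
  list(prob = prob, w = Wt)
}

# Expected gamma-discounted stream of mean-relief-remaining from (s, t) under
# an arbitrary policy array, by explicit tree recursion (enumeration oracle).
enum_income_stream <- function(prob, s, t, gam, cfg) {
  T <- cfg$n_trials; A <- cfg$max_per_trial_units
  rho <- s / (T - (t - 1))
  if (t == T) return(rho)
  val <- rho
  p <- prob[, s + 1, t]
  for (c in 0:min(s, A)) {
    if (p[c + 1] == 0) next
    val <- val + p[c + 1] * gam * enum_income_stream(prob, s - c, t + 1, gam, cfg)
  }
  val
}
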