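test_that("softmax choice probabilities behave across the temperature range", {
  expect_equal(softmax_policy(rnorm(13), 0), rep(1 / 13, 13))
  expect_equal(softmax_policy(c(2, 2), 5), c(0.5, 0.5))
  p <- softmax_policy(c(1, 1.01, 0.5), 10000)
  expect_gt(p[2], 0.999)
  expect_error(softmax_policy(numeric(0), 1), "empty")
  expect_error(softmax_policy(c(1, 2), -1), "non-negative")
})

test_that("backward induction matches brute-force path enumeration on tiny tasks", {
  set.seed(21)
  for (i in 1:10) {
    cfg <- tiny_cfg(sample(2:6, 1), sample(4:12, 1))
    dp <- discount_params(runif(1, 0, 2), runif(1, 0.4, 1), runif(1, 0.4, 1))
    k <- runif(1, 0.3, 1); beta <- runif(1, 0, 3)
    bf <- brute_force_policy(dp, k, beta, cfg)
    sp <- sophisticated_policy(dp, k, beta, cfg, keep_q = TRUE)
    expect_lt(max(abs(bf$q - sp$q), na.rm = TRUE), 1e-8)
    expect_lt(max(abs(bf$prob - sp$prob)), 1e-8)
  }
  expect_error(brute_force_policy(discount_params(1, 0.9), 1, 1,
                                  task_config()), "limited")
})

test_that("single-trial and two-period Q values have their closed forms", {
  dp <- discount_params(0, 0.5, 1)
  cfg1 <- tiny_cfg(1, 8)
  q1 <- sophisticated_policy(dp, k = 0.7, beta = 2, cfg1, keep_q = TRUE)$q
  for (s in 0:8) {
    expect_equal(q1[1:(min(s, 8) + 1), s + 1, 1], utility(0:min(s, 8), 0.7))
  }
  # T = 2, alpha = 0, gamma_c = 0.5: Q(s,c,1) = U(c) + 0.5 * E_pi2[U(c')]
  cfg2 <- tiny_cfg(2, 8)
  beta <- 1.3; k <- 0.8
  pol <- sophisticated_policy(dp, k, beta, cfg2, keep_q = TRUE)
  for (s in c(0, 3, 8)) {
    for (c in 0:min(s, 8)) {
      u2 <- utility(0:(s - c), k)
      eu2 <- sum(softmax_policy(u2, beta) * u2)
      expect_equal(pol$q[c + 1, s + 1, 1], utility(c, k) + 0.5 * eu2,
                   tolerance = 1e-12)
    }
  }
})

test_that("with linear utility and no discounting all budget-exhausting paths tie", {
  dp <- discount_params(0, 1, 1)
  cfg <- task_config()
  set.seed(22)
  vals <- replicate(10, {
    u <- integer(60); s <- 240L
    for (t in 1:59) {
      lo <- max(0L, s - 12L * (60L - t)) # keep exhaustion feasible
      u[t] <- sample(lo:min(s, 12L), 1)
      s <- s - u[t]
    }
    u[60] <- s
    path_value(u, dp, k = 1)
  })
  expect_equal(vals, rep(240, 10))
  # whereas concave utility strictly prefers the even path
  dpc <- discount_params(0, 1, 1)
  expect_gt(path_value(rep(4, 60), dpc, 0.75),
            path_value(c(rep(0, 30), rep(8, 30)), dpc, 0.75))
})

test_that("concave utility with no discounting spreads: the 4-unit flat path", {
  cfg <- task_config()
  pol <- sophisticated_policy(discount_params(0, 1, 1), k = 0.75,
                              beta = 10000, cfg)
  paths <- simulate_paths(pol, cfg, n = 5, seed = 3)
  expect_true(all(paths == 4L))
})

test_that("path simulation respects the budget and the uniform-policy mean", {
  cfg <- task_config()
  uni <- direct_action_policy(list(beta_spend = 0, beta_spread = 0,
                                   beta_save = 0), cfg)
  expect_equal(uni$prob[, 241, 1], rep(1 / 13, 13))
  paths <- simulate_paths(uni, cfg, n = 2000, seed = 4)
  # feasibility/budget conservation for every path
  caps <- 240 - t(apply(paths, 1, cumsum))
  expect_true(all(caps >= 0))
  expect_true(all(paths <= 12))
  # mean first-trial consumption ~ mean of uniform over 0..12
  se <- sqrt((13^2 - 1) / 12) / sqrt(2000)
  expect_lt(abs(mean(paths[, 1]) - 6), 3 * se)
  # determinism and degenerate policies
  expect_identical(simulate_paths(uni, cfg, 3, seed = 9),
                   simulate_paths(uni, cfg, 3, seed = 9))
  det <- direct_action_policy(list(beta_spend = 0, beta_spread = 10,
                                   beta_save = 0), cfg)
  pd <- simulate_paths(det, cfg, n = 4, seed = 5)
  expect_true(all(apply(pd, 2, function(x) length(unique(x)) == 1)))
})

test_that("exponential discounting makes naive and sophisticated agents agree", {
  cfg <- demo_cfg()
  # undiscounted case: policies identical at any temperature
  dp0 <- discount_params(0, 1, 1)
  sp <- sophisticated_policy(dp0, k = 0.75, beta = 5, cfg)
  np <- naive_policy(dp0, k = 0.75, beta = 5, cfg, i = 1)
  expect_lt(max(abs(sp$prob - np$prob)), 1e-10)
  # discounted exponential case: near-deterministic paths coincide
  dp2 <- discount_params(0, 0.9, 1)
  ps <- simulate_paths(sophisticated_policy(dp2, 0.75, 10000, cfg), cfg,
                       n = 3, seed = 1)
  pn <- simulate_naive_paths(dp2, 0.75, 10000, cfg, n = 3, seed = 1)
  expect_identical(ps, pn)
  # and the trial-2 plan is the tail of the trial-1 plan
  plan1 <- naive_plan(dp2, 0.75, 10000, cfg, i = 1)
  s2 <- 40 - round(plan1[1]) # capital after the planned first action
  plan2 <- naive_plan(dp2, 0.75, 10000, cfg, i = 2, s_i = s2)
  expect_equal(plan1[-1], plan2, tolerance = 1e-6)
})

test_that("anticipation produces the published plan-versus-realization gaps", {
  cfg <- demo_cfg()
  # savoring-dominant: the naive agent consumes less than it planned
  dp_sav <- discount_params(2, 1, 1)
  plan <- naive_plan(dp_sav, 0.75, 10000, cfg, i = 1)
  real <- simulate_naive_paths(dp_sav, 0.75, 10000, cfg, n = 1, seed = 1)
  expect_lt(sum(real[1, 1:6]), sum(plan[1:6]))
  # discounting-dominant: the naive agent consumes more than it planned
  dp_dis <- discount_params(0.1, 0.7, 1)
  expect_true(all(diff(anticipation_discount(0:9, dp_dis)) < 0))
  plan_d <- naive_plan(dp_dis, 0.75, 10000, cfg, i = 1)
  real_d <- simulate_naive_paths(dp_dis, 0.75, 10000, cfg, n = 1, seed = 1)
  expect_gt(sum(real_d[1, 1:5]), sum(plan_d[1:5]))
  # with savoring, naive and sophisticated paths may diverge; here they are
  # both increasing (saving) profiles
  sp <- simulate_paths(sophisticated_policy(dp_sav, 0.75, 10000, cfg), cfg,
                       n = 1, seed = 2)
  expect_gt(coef(lm(sp[1, ] ~ seq_len(10)))[2], 0)
})

test_that("policy tables validate normalisation and feasibility", {
  cfg <- tiny_cfg(5, 10)
  pol <- sophisticated_policy(discount_params(1, 0.8, 0.9), 0.6, 3, cfg)
  expect_true(check_policy(pol))
  P <- policy_prob(pol, s = c(10, 3), t = c(1, 4))
  expect_equal(rowSums(P), c(1, 1))
  expect_true(all(P[2, 5:13] == 0)) # c > s has no mass
})
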