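test_that("heuristic propensities follow their defining rules", {
  expect_equal(propensity_spend(12), 12)
  expect_equal(propensity_spend(0), 0)
  expect_equal(which.max(propensity_spend(0:12)), 13) # argmax at the cap
  expect_equal(propensity_spread(4, 4), 0)
  expect_equal(propensity_spread(4, 0), -4)
  expect_equal(propensity_spread(4, 12), -8)
  expect_equal(propensity_save(4, 0), 4)
  expect_equal(propensity_save(4, 12), -8)
  # at rho >= cap the save propensity switches off for every action
  expect_equal(propensity_save(12, 0:12), rep(0, 13))
})

test_that("Gaussian biases are centred correctly with sd two units", {
  cfg <- task_config()
  b_min <- gaussian_bias("min", s = 240, t = 1, cfg)
  expect_equal(which.max(b_min), 1)
  expect_equal(b_min[1], 1 / (2 * sqrt(2 * pi)), tolerance = 1e-12)
  # max bias centres at capital when below the cap
  b_max <- gaussian_bias("max", s = 5, t = 50, cfg)
  expect_equal(which.max(b_max), 6)
  expect_equal(gaussian_bias("max", s = 200, t = 1, cfg),
               dnorm(0:12, 12, 2))
  # mean bias is symmetric about rho
  b_mean <- gaussian_bias("mean", s = 240, t = 1, cfg) # rho = 4
  expect_equal(b_mean[4 + 1 - 3], b_mean[4 + 1 + 3], tolerance = 1e-12)
})

test_that("inverse-variance mixing weights components by precision", {
  # three equal-variance components share weight equally
  p <- rbind(c(0.5, 0, 0.5, 0, 0), c(0, 0.5, 0, 0.5, 0), c(0.5, 0, 0.5, 0, 0))
  m <- inverse_variance_mix(p)
  expect_equal(m$weights, rep(1 / 3, 3))
  expect_equal(sum(m$mix), 1)
  # variances (1, 2, 2) give weights (0.5, 0.25, 0.25)
  q <- 0.5 - sqrt(2) / 4 # two-point mass on {0, 4} with variance 2
  p2 <- rbind(c(0.5, 0, 0.5, 0, 0), # var 1
              c(1 - q, 0, 0, 0, q), c(1 - q, 0, 0, 0, q))
  m2 <- inverse_variance_mix(p2)
  expect_equal(m2$weights, c(0.5, 0.25, 0.25), tolerance = 1e-12)
  expect_equal(sum(m2$mix), 1)
  expect_error(inverse_variance_mix(p[1, , drop = FALSE]), "at least two")
})

test_that("the Direct Action mixture expresses its dominant heuristic", {
  cfg <- task_config()
  # all temperatures zero: uniform policy everywhere
  uni <- direct_action_policy_at(c(240, 100, 7), c(1, 30, 59),
                                 list(beta_spend = 0, beta_spread = 0,
                                      beta_save = 0), cfg)
  expect_equal(uni[1, ], rep(1 / 13, 13))
  expect_equal(sum(uni[3, 1:8]), 1) # s = 7: only c <= 7 feasible
  expect_equal(uni[3, 1:8], rep(1 / 8, 8))
  # dominant save heuristic piles mass on zero while rho < cap
  sav <- direct_action_policy_at(240, 1, list(beta_spend = 0, beta_spread = 0,
                                              beta_save = 8), cfg)
  expect_gt(sav[1, 1], 0.9)
  # dominant spread heuristic concentrates within one unit of rho
  spr <- direct_action_policy_at(240, 1, list(beta_spend = 0, beta_spread = 8,
                                              beta_save = 0), cfg)
  expect_gt(sum(spr[1, 4:6]), 0.9) # rho = 4
  # table form agrees with pointwise form
  tab <- direct_action_policy(list(beta_spend = 0.5, beta_spread = 3,
                                   beta_save = 1), cfg)
  expect_true(check_policy(tab))
  at <- direct_action_policy_at(c(240, 55), c(1, 33),
                                list(beta_spend = 0.5, beta_spread = 3,
                                     beta_save = 1), cfg)
  expect_equal(policy_prob(tab, c(240, 55), c(1, 33)), at,
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("income-maximization action values match tree enumeration", {
  cfg <- tiny_cfg(3, 6)
  # uniform mixture (all temperatures zero) with gamma = 0.5
  par <- list(beta_spend = 0, beta_spread = 0, beta_maximize = 0, gamma = 0.5)
  pol <- income_max_policy(par, cfg)
  expect_true(check_policy(pol))
  for (s in c(0, 2, 6)) {
    for (t in 1:3) {
      q <- income_max_q(pol, s, t, cfg)
      rho <- mean_relief_remaining(s, t, cfg)
      q_ref <- vapply(0:min(s, 6), function(c) {
        if (t == 3) rho
        else rho + 0.5 * enum_income_stream(pol$prob, s - c, t + 1, 0.5, cfg)
      }, numeric(1))
      expect_equal(q, q_ref, tolerance = 1e-10)
    }
  }
  # gamma = 0 collapses the income values to the action-independent rho
  pol0 <- income_max_policy(list(beta_spend = 0, beta_spread = 0,
                                 beta_maximize = 5, gamma = 0), cfg)
  expect_equal(income_max_q(pol0, 6, 1, cfg), rep(2, 7))
  expect_equal(pol0$prob[1:7, 7, 1], rep(1 / 7, 7), tolerance = 1e-12)
  # at t = T the value is rho for every action (uniform component)
  cfgT <- task_config()
  polT <- income_max_policy(list(beta_spend = 0, beta_spread = 0,
                                 beta_maximize = 7, gamma = 0.9), cfgT)
  expect_equal(income_max_q(polT, 30, 60, cfgT), rep(30, 13))
})

test_that("the compiled income-max kernel matches a plain-R implementation", {
  set.seed(31)
  # full parameter bounds on a short-horizon task (at long horizons and
  # extreme temperatures the W recursion amplifies rounding noise, so exact
  # cross-implementation agreement is only meaningful away from that regime)
  for (i in 1:4) {
    cfg <- tiny_cfg(6, 12)
    par <- list(beta_spend = runif(1, 0, 10), beta_spread = runif(1, 0, 10),
                beta_maximize = runif(1, 0, 10), gamma = runif(1))
    ref <- r_income_max_policy(par, cfg)
    pol <- income_max_policy(par, cfg)
    expect_lt(max(abs(ref$prob - pol$prob)), 1e-8)
    expect_lt(max(abs(ref$w - pol$w)), 1e-6)
  }
  # moderate temperatures at the full 60-trial scale: the two
  # implementations agree to the level the recursion itself preserves
  # (rounding noise grows backward through the softmax/variance mixing at
  # bimodal high-capital states, so exact equality is not attainable there)
  cfg <- task_config()
  par <- list(beta_spend = 0.7, beta_spread = 2.5, beta_maximize = 2.2,
              gamma = 0.85)
  ref <- r_income_max_policy(par, cfg)
  pol <- income_max_policy(par, cfg)
  expect_lt(max(abs(ref$prob - pol$prob)), 0.005)
  expect_lt(stats::median(abs(ref$prob - pol$prob)), 1e-12)
  expect_true(check_policy(pol))
  # mixture weights lie on the simplex everywhere
  expect_equal(apply(pol$weights, c(2, 3), sum),
               matrix(1, 241, 60), ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("the combined model nests the pure anticipation-discounting policy", {
  cfg <- task_config()
  dp <- discount_params(0.8, 0.95, 0.9)
  base <- sophisticated_policy(dp, k = 0.8, beta = 4, cfg)
  comb0 <- combined_policy(dp, list(beta = 4, k = 0.8, omega_min = 0,
                                    omega_mean = 0, omega_max = 0), cfg)
  expect_equal(comb0$prob, base$prob, tolerance = 1e-12)
  # a dominant mean bias at high temperature spends near round(rho)
  comb <- combined_policy(dp, list(beta = 10, k = 0.8, omega_min = 0,
                                   omega_mean = 100, omega_max = 0), cfg)
  expect_true(check_policy(comb))
  expect_equal(unname(which.max(policy_prob(comb, 240, 1))) - 1, 4) # rho = 4
  p_mid <- policy_prob(comb, 120, 31) # rho = 4 mid-session
  expect_equal(unname(which.max(p_mid)) - 1, 4)
})

test_that("model registry exposes bounded parameterisations", {
  expect_setequal(relief_models(),
                  c("direct_action", "income_max", "optimal", "combined"))
  b <- model_bounds("income_max")
  expect_equal(b$upper[["gamma"]], 1)
  expect_equal(b$upper[["beta_maximize"]], 10)
  expect_error(build_policy("optimal", list(beta = 2, k = 0.5)),
               "discount parameters")
  set.seed(32)
  for (m in c("direct_action", "income_max")) {
    b <- model_bounds(m)
    par <- as.list(runif(length(b$lower), b$lower, pmin(b$upper, 6)))
    names(par) <- names(b$lower)
    expect_true(check_policy(build_policy(m, par, task_config())))
  }
})
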