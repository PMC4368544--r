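test_that("path likelihood conditions on observed capital", {
  cfg <- task_config()
  uni <- direct_action_policy(list(beta_spend = 0, beta_spread = 0,
                                   beta_save = 0), cfg)
  # all-zero path keeps 13 feasible actions on every trial
  p0 <- consumption_path(rep(0, 60), cfg)
  expect_equal(path_nll(uni, p0), 60 * log(13), tolerance = 1e-12)
  # a near-deterministic policy assigns its modal path likelihood near zero
  det <- direct_action_policy(list(beta_spend = 0, beta_spread = 10,
                                   beta_save = 0), cfg)
  p4 <- consumption_path(rep(4, 60), cfg)
  expect_lt(path_nll(det, p4), 0.01)
  # probability floor keeps the objective finite
  spend_all <- consumption_path(c(rep(12, 20), rep(0, 40)), cfg)
  expect_true(is.finite(path_nll(det, spend_all)))
})

test_that("the likelihood is informative about the generating temperature", {
  cfg <- task_config()
  gen <- list(beta_spend = 0.2, beta_spread = 3, beta_save = 0.2)
  pol <- direct_action_policy(gen, cfg)
  path <- consumption_path(simulate_paths(pol, cfg, 1, seed = 41), cfg)
  fn <- reliefdyn:::model_nll_fn("direct_action", path, cfg)
  prof <- vapply(c(0.5, 1.5, 3, 7),
                 function(b) fn(list(beta_spend = 0.2, beta_spread = b,
                                     beta_save = 0.2)), numeric(1))
  expect_lt(prof[3], prof[1]) # closer to truth fits better
  expect_lt(prof[3], prof[4])
})

test_that("generating parameters beat parameter-space corners on average", {
  cfg <- task_config()
  b <- model_bounds("direct_action")
  corners <- list(b$lower, b$upper,
                  c(beta_spend = 10, beta_spread = 0, beta_save = 0),
                  c(beta_spend = 0, beta_spread = 0, beta_save = 10))
  set.seed(44)
  nll_true <- nll_corner <- matrix(NA_real_, 20, length(corners))
  for (r in 1:20) {
    gen <- list(beta_spend = runif(1, 0, 2), beta_spread = runif(1, 1, 6),
                beta_save = runif(1, 0, 4))
    pol <- direct_action_policy(gen, cfg)
    path <- consumption_path(simulate_paths(pol, cfg, 1, seed = 100 + r), cfg)
    fn <- reliefdyn:::model_nll_fn("direct_action", path, cfg)
    for (j in seq_along(corners)) {
      nll_true[r, j] <- fn(gen)
      nll_corner[r, j] <- fn(as.list(corners[[j]]))
    }
  }
  expect_true(all(colMeans(nll_true) <= colMeans(nll_corner)))
})

test_that("subject fits are deterministic, bounded and locally optimal", {
  cfg <- task_config()
  gen <- list(beta_spend = 0.3, beta_spread = 4, beta_save = 1)
  pol <- direct_action_policy(gen, cfg)
  path <- consumption_path(simulate_paths(pol, cfg, 1, seed = 42), cfg)
  f1 <- fit_subject("direct_action", path, cfg, n_iterations = 2,
                    n_starts = 12, seed = 7, maxit = 300)
  f2 <- fit_subject("direct_action", path, cfg, n_iterations = 2,
                    n_starts = 12, seed = 7, maxit = 300)
  expect_identical(f1, f2)
  b <- model_bounds("direct_action")
  expect_true(all(f1$par >= b$lower & f1$par <= b$upper))
  # no +-0.1 neighbour on the parameter grid improves the optimum
  fn <- reliefdyn:::model_nll_fn("direct_action", path, cfg)
  for (j in seq_along(f1$par)) {
    for (dlt in c(-0.1, 0.1)) {
      par <- f1$par
      par[j] <- min(max(par[j] + dlt, b$lower[j]), b$upper[j])
      expect_gte(fn(as.list(par)), f1$nll - 1e-6)
    }
  }
})

test_that("group BIC implements fixed-effects accounting", {
  mk <- function(nll) structure(list(subject_id = "x", model = "direct_action",
                                     par = c(a = 1), nll = nll, n_obs = 60,
                                     n_par = 3), class = "fit_result")
  fits <- list(mk(400), mk(600)) # L = -1000
  g <- group_bic(fits, k = 3, n = 1800)
  expect_equal(g$bic, 2000 + 3 * log(1800), tolerance = 1e-12)
  # one extra parameter at unchanged likelihood costs log(n)
  g4 <- group_bic(fits, k = 4, n = 1800)
  expect_equal(g4$bic - g$bic, log(1800))
  # default accounting: parameters and observations summed over subjects
  gd <- group_bic(fits)
  expect_equal(gd$k, 6)
  expect_equal(gd$n, 120)
  bad <- list(mk(1), structure(list(model = "income_max", nll = 1,
                                    n_obs = 60, n_par = 4),
                               class = "fit_result"))
  expect_error(group_bic(bad), "same model")
})

test_that("robust slope recovers clean trends and resists outliers", {
  tt <- rep(1:60, each = 5)
  expect_equal(suppressWarnings(robust_slope(3 + 0.8 * tt, tt)), 0.8,
               tolerance = 1e-6)
  # constant data: slope zero (IRLS cannot strictly converge on zero residuals)
  expect_equal(suppressWarnings(robust_slope(rep(40, 300), tt)), 0,
               tolerance = 1e-9)
  y <- 3 + 0.8 * tt
  y[c(10, 100, 200)] <- 1200 # gross outliers barely move the bisquare fit
  expect_equal(robust_slope(y, tt), 0.8, tolerance = 0.02)
  expect_error(robust_slope(c(1, 2), c(1, 1)), "distinct")
})

test_that("behavioral classification implements the deviation thresholds", {
  cfg <- task_config()
  even <- classify_behavior(consumption_path(rep(4, 60), cfg), cfg)
  expect_equal(even$class, "spreading")
  expect_equal(even$mean_abs_deviation, 0)
  expect_equal(even$abs_slope, abs(even$slope))
  saver <- classify_behavior(
    consumption_path(c(rep(0, 40), rep(12, 20)), cfg), cfg)
  expect_equal(saver$class, "saving")
  expect_lt(saver$mean_signed_deviation, -1)
  spender <- classify_behavior(
    consumption_path(c(rep(12, 20), rep(0, 40)), cfg), cfg)
  expect_equal(spender$class, "early-spending")
  # high deviation with near-zero signed mean is reported as mixed
  mixed <- classify_behavior(
    consumption_path(rep(c(0, 8), 30), cfg), cfg)
  expect_equal(mixed$class, "mixed")
})

test_that("block-level R-squared is one when predictions equal observations", {
  cfg <- task_config()
  det_spread <- direct_action_policy(list(beta_spend = 0, beta_spread = 10,
                                          beta_save = 0), cfg)
  det_decline <- sophisticated_policy(discount_params(0, 0.7, 1), k = 0.75,
                                      beta = 10000, cfg)
  paths <- list(consumption_path(simulate_paths(det_spread, cfg, 1, seed = 1),
                                 cfg, "a"),
                consumption_path(simulate_paths(det_decline, cfg, 1, seed = 2),
                                 cfg, "b"))
  r2 <- suppressWarnings( # lm flags the (intended) essentially perfect fit
    ten_trial_r2(list(det_spread, det_decline), paths, cfg, n_sims = 50,
                 seed = 3))
  expect_equal(r2$r_squared, 1, tolerance = 1e-9)
  expect_length(r2$observed, 12)
})
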