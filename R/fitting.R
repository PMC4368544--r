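#' Negative log-likelihood of an observed path under a policy
#'
#' `-sum_t log p(c_t | s_t, t)`, conditioning on the subject's actual capital
#' at each trial.  Probabilities are floored at 1e-12 inside the log so that
#' numerical underflow cannot produce an infinite objective (the softmax
#' itself never yields exact zeros at finite beta).
#'
#' @param policy A `policy_table`.
#' @param path A [consumption_path()].
#' @return Negative log-likelihood in nats.
#' @export
path_nll <- function(policy, path) {
  p <- policy$prob[cbind(path$units + 1L, path$capital + 1L,
                         seq_len(path$n_trials))]
  -sum(log(pmax(p, 1e-12)))
}

# Per-model NLL closures.  The Direct Action model is local in state, so its
# likelihood is evaluated only at the 60 observed (s, t) pairs; the other
# models need the full backward induction per evaluation.
model_nll_fn <- function(model, path, cfg, dp = NULL) {
  model <- match.arg(model, relief_models())
  tt <- seq_len(path$n_trials)
  if (model == "direct_action") {
    function(par) {
      P <- direct_action_policy_at(path$capital, tt, par, cfg)
      p <- P[cbind(tt, path$units + 1L)]
      -sum(log(pmax(p, 1e-12)))
    }
  } else {
    function(par) path_nll(build_policy(model, par, cfg, dp), path)
  }
}

# Smooth sine bijection between unconstrained z and box [lo, hi].
bound_transform <- function(z, lo, hi) lo + (hi - lo) * (sin(z) + 1) / 2
bound_inverse <- function(x, lo, hi) {
  asin(pmin(1, pmax(-1, 2 * (x - lo) / (hi - lo) - 1)))
}

#' Fit one subject's consumption path by maximum likelihood
#'
#' Bounded Nelder-Mead with a random multistart overlay.  Bounds are imposed
#' by a smooth sine transformation of the parameters.  On each of
#' `n_iterations` iterations, `n_starts` candidate starting points are drawn
#' uniformly within the bounds and the objective evaluated at each; the
#' simplex search is then run from the best candidate (`start_rule = "best"`,
#' the default) or from every candidate (`start_rule = "all"`).  The best
#' point seen anywhere (starts included) is returned.  Deterministic under a
#' fixed seed.
#'
#' @param model One of [relief_models()].
#' @param path A [consumption_path()].
#' @param cfg A [task_config()].
#' @param dp A [discount_params()] for the `"optimal"`/`"combined"` models.
#' @param n_iterations Number of multistart iterations.
#' @param n_starts Random starting points drawn per iteration.
#' @param seed Integer seed.
#' @param maxit Maximum Nelder-Mead iterations per simplex run.
#' @param reltol Relative convergence tolerance of the simplex.
#' @param start_rule `"best"` or `"all"` (see above).
#' @return A `fit_result`: subject id, model, named ML parameters, `nll`,
#'   `n_obs`, `n_par`.
#' @export
fit_subject <- function(model, path, cfg = task_config(), dp = NULL,
                        n_iterations = 3, n_starts = 20, seed = 1,
                        maxit = 200, reltol = 1e-8,
                        start_rule = c("best", "all")) {
  model <- match.arg(model, relief_models())
  start_rule <- match.arg(start_rule)
  b <- model_bounds(model)
  lo <- b$lower; hi <- b$upper
  npar <- length(lo)
  nll_fn <- model_nll_fn(model, path, cfg, dp)
  obj <- function(par) {
    v <- nll_fn(setNames(as.list(par), names(lo)))
    if (!is.finite(v)) 1e10 else v
  }
  obj_z <- function(z) obj(bound_transform(z, lo, hi))

  set.seed(seed)
  best <- list(par = NULL, nll = Inf)
  n_converged <- 0L
  for (it in seq_len(n_iterations)) {
    starts <- matrix(runif(n_starts * npar, rep(lo, each = n_starts),
                           rep(hi, each = n_starts)), n_starts, npar)
    vals <- apply(starts, 1, obj)
    for (j in seq_len(n_starts)) {
      if (vals[j] < best$nll) best <- list(par = starts[j, ], nll = vals[j])
    }
    from <- if (start_rule == "best") which.min(vals) else seq_len(n_starts)
    for (j in from) {
      z0 <- bound_inverse(starts[j, ], lo, hi)
      opt <- optim(z0, obj_z, method = "Nelder-Mead",
                   control = list(maxit = maxit, reltol = reltol))
      if (opt$convergence == 0) n_converged <- n_converged + 1L
      if (opt$value < best$nll) {
        best <- list(par = bound_transform(opt$par, lo, hi), nll = opt$value)
      }
    }
  }
  if (!is.finite(best$nll)) {
    stop("optimisation failed on every start for subject ", path$subject_id)
  }
  structure(list(subject_id = path$subject_id, model = model,
                 par = setNames(as.numeric(best$par), names(lo)),
                 nll = best$nll, n_obs = path$n_trials, n_par = npar,
                 n_converged = n_converged),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result '%s' (%s): NLL = %.2f\n  ", x$subject_id, x$model,
              x$nll))
  cat(paste(names(x$par), signif(x$par, 4), sep = " = ", collapse = ", "),
      "\n")
  invisible(x)
}

#' Fit every subject in a cohort with the same model
#'
#' @param model One of [relief_models()].
#' @param paths List of [consumption_path()] objects.
#' @param cfg A [task_config()].
#' @param dp_list Optional list of per-subject [discount_params()] (for the
#'   `"optimal"`/`"combined"` models), parallel to `paths`.
#' @param seed Base seed; subject `i` uses `seed + i`.
#' @param ... Passed to [fit_subject()].
#' @return A list of `fit_result` objects (class `fit_cohort`).
#' @export
fit_cohort <- function(model, paths, cfg = task_config(), dp_list = NULL,
                       seed = 1, ...) {
  fits <- lapply(seq_along(paths), function(i) {
    fit_subject(model, paths[[i]], cfg,
                dp = if (is.null(dp_list)) NULL else dp_list[[i]],
                seed = (seed + i) %% .Machine$integer.max, ...)
  })
  class(fits) <- "fit_cohort"
  fits
}

#' Group-level fixed-effects BIC
#'
#' `BIC = -2 L + k log(n)` where `L` is the summed log-likelihood across
#' subjects, `k` the total number of free parameters (parameters per subject
#' times subjects, the fixed-effects accounting) and `n` the total number of
#' observations (subjects x trials).  Only BIC differences between models
#' fitted to the same subjects are meaningful.
#'
#' @param fits A list of `fit_result` objects from a single model.
#' @param k Optional override of the parameter count.
#' @param n Optional override of the observation count.
#' @return A list with `bic`, `log_lik`, `k`, `n`, `model`.
#' @export
group_bic <- function(fits, k = NULL, n = NULL) {
  models <- unique(vapply(fits, `[[`, character(1), "model"))
  if (length(models) != 1) stop("all fits must come from the same model")
  L <- -sum(vapply(fits, `[[`, numeric(1), "nll"))
  if (is.null(k)) k <- sum(vapply(fits, `[[`, numeric(1), "n_par"))
  if (is.null(n)) n <- sum(vapply(fits, `[[`, numeric(1), "n_obs"))
  list(bic = -2 * L + k * log(n), log_lik = L, k = k, n = n, model = models)
}

#' Tabulate a cohort of fits
#'
#' @param fits A list of `fit_result`s.
#' @return A data.frame, one row per subject.
#' @export
fits_as_data_frame <- function(fits) {
  pars <- do.call(rbind, lapply(fits, function(f) f$par))
  data.frame(subject_id = vapply(fits, `[[`, character(1), "subject_id"),
             model = vapply(fits, `[[`, character(1), "model"),
             pars,
             nll = vapply(fits, `[[`, numeric(1), "nll"),
             row.names = NULL)
}
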