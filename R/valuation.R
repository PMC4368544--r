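#' Anticipation-discounting parameters
#'
#' Bundles the three parameters of the anticipation-discounting function:
#' `alpha`, the weight on the forward-looking anticipation (dread/savoring)
#' stream; `gamma_c`, the per-trial exponential discount factor applied to
#' consumption (equated with the pain discount factor `gamma_P` when carrying
#' parameters over from one-off binary choices); and `gamma_a`, the discount
#' factor on anticipation itself (`gamma_D` from the binary-choice fits).
#'
#' @param alpha Anticipation weight, `>= 0`.
#' @param gamma_c Consumption discount factor, in `(0, 1]`.
#' @param gamma_a Anticipation discount factor, in `(0, 1]`.
#' @return An object of class `discount_params`.
#' @export
discount_params <- function(alpha, gamma_c, gamma_a = 1) {
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha >= 0,
            is.numeric(gamma_c), length(gamma_c) == 1,
            gamma_c > 0, gamma_c <= 1,
            is.numeric(gamma_a), length(gamma_a) == 1,
            gamma_a > 0, gamma_a <= 1)
  structure(list(alpha = alpha, gamma_c = gamma_c, gamma_a = gamma_a),
            class = "discount_params")
}

#' Instantaneous utility of relief consumption
#'
#' `U(c) = c^k` with exponent `k` in `(0, 1]`: linear at `k = 1`, strictly
#' concave below, with `U(0) = 0`.
#'
#' @param c Consumption in units, `>= 0` (vectorised).
#' @param k Utility exponent.
#' @return Utility in utils.
#' @export
utility <- function(c, k = 1) {
  stopifnot(k > 0, k <= 1)
  if (any(c < 0)) stop("consumption must be non-negative")
  c^k
}

#' The anticipation-discounting function
#'
#' Weight applied to an outcome at delay `d` trials:
#' `Delta(d) = gamma_c^d + alpha * B(d)` with
#' `B(d) = sum_{tau=0}^{d-1} gamma_c^(d-tau) * gamma_a^tau`, the discounted
#' anticipation accumulated while waiting.  `Delta(0) = 1` (the empty sum):
#' current-period utility is undiscounted.  With `alpha = 0` this is plain
#' exponential discounting; with `gamma_c = gamma_a = 1` and `alpha > 0` the
#' weight grows linearly with delay (anticipation dominates, producing
#' negative time preference).
#'
#' The sum is evaluated term by term (never via a geometric closed form), so
#' the function is exact at `gamma = 1` and stable for small `gamma_c`.
#'
#' @param d Delay in trials, non-negative integer(s).
#' @param dp A [discount_params()] object (or a list with `alpha`, `gamma_c`,
#'   `gamma_a`).
#' @return `Delta(d)`, vectorised over `d`.
#' @export
anticipation_discount <- function(d, dp) {
  if (any(d < 0)) stop("delay must be non-negative")
  d <- as.integer(d)
  vapply(d, function(di) {
    if (di == 0) return(1)
    tau <- 0:(di - 1)
    dp$gamma_c^di + dp$alpha * sum(dp$gamma_c^(di - tau) * dp$gamma_a^tau)
  }, numeric(1))
}

#' Exponential and anticipation components of the discount function
#'
#' Exact algebraic split used by the backward-induction planner:
#' returns `gamma_c^d` and `B(d)` (see [anticipation_discount()]) such that
#' `gamma_c^d + alpha * B(d) = Delta(d)`.  `B` satisfies the recursion
#' `B(1) = gamma_c`, `B(d) = gamma_c * B(d-1) + gamma_c * gamma_a^(d-1)`,
#' which is what makes the non-exponential planner reducible to three coupled
#' exponential value tables.
#'
#' @param d Delay in trials, `>= 1` (vectorised).
#' @param dp A [discount_params()].
#' @return A list with components `exponential` (`gamma_c^d`) and
#'   `anticipation` (`B(d)`).
#' @export
delta_components <- function(d, dp) {
  if (any(d < 1)) stop("delay must be >= 1")
  d <- as.integer(d)
  B <- vapply(d, function(di) {
    tau <- 0:(di - 1)
    sum(dp$gamma_c^(di - tau) * dp$gamma_a^tau)
  }, numeric(1))
  list(exponential = dp$gamma_c^d, anticipation = B)
}
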