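#' Energy-allocation strategies for forward simulation
#'
#' Five regimes of symbiont energy allocation are compared:
#' \describe{
#'   \item{optimal}{follow the host-optimal policy `u*(E, W, t)` from
#'     [solve_policy()] (bilinear lookup at off-grid states).}
#'   \item{imperfect}{optimal with execution noise: each step
#'     `u ~ U(u* - halfwidth, u* + halfwidth)`, clamped to `[0, N]`.}
#'   \item{fixed}{a constant allocation regardless of state (default 3).}
#'   \item{proportional}{allocation proportional to symbiont density,
#'     `u = factor * W` (default factor 0.3), clamped to `[0, N]`.}
#'   \item{symbiont_optimal}{follow the policy that maximizes symbiont
#'     fitness (a [solve_policy()] run with `objective = "symbiont"`).}
#' }
#'
#' @param policy A `symb_policy` for the policy-based strategies.
#' @param halfwidth Half-width of the uniform execution noise (default 1).
#' @param u Fixed allocation amount (default 3).
#' @param factor Proportionality constant (default 0.3).
#' @return An object of class `symb_strategy`.
#' @name strategies
NULL

new_strategy <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "symb_strategy")
}

#' @rdname strategies
#' @export
strategy_optimal <- function(policy) {
  stopifnot(inherits(policy, "symb_policy"))
  new_strategy("optimal", policy = policy)
}

#' @rdname strategies
#' @export
strategy_imperfect <- function(policy, halfwidth = 1) {
  stopifnot(inherits(policy, "symb_policy"), halfwidth >= 0)
  new_strategy("imperfect", policy = policy, halfwidth = halfwidth)
}

#' @rdname strategies
#' @export
strategy_fixed <- function(u = 3) {
  new_strategy("fixed", fixed_u = u)
}

#' @rdname strategies
#' @export
strategy_proportional <- function(factor = 0.3) {
  stopifnot(factor > 0)
  new_strategy("proportional", prop_factor = factor)
}

#' @rdname strategies
#' @export
strategy_symbiont_optimal <- function(policy) {
  stopifnot(inherits(policy, "symb_policy"),
            policy$scenario$objective == "symbiont")
  new_strategy("symbiont_optimal", policy = policy)
}

#' @export
print.symb_strategy <- function(x, ...) {
  cat(sprintf("<symb_strategy> %s\n", x$kind))
  invisible(x)
}

#' Allocation decided by a strategy in a given state
#'
#' Vectorized over hosts.  Policy-based strategies read `u*` by bilinear
#' interpolation of the policy slice at time `t`; the imperfect strategy adds
#' uniform noise (consuming random draws).  All results are clamped to
#' `[0, n_intake]`.
#'
#' @param strategy A `symb_strategy`.
#' @param e,w Host states.
#' @param t Time step (scalar).
#' @param params A [model_params()] object.
#' @return Numeric vector of allocations.
#' @export
decide_allocation <- function(strategy, e, w, t, params) {
  n <- length(e)
  u <- switch(strategy$kind,
    optimal = ,
    symbiont_optimal = lookup_policy(strategy$policy, e, w, t),
    imperfect = lookup_policy(strategy$policy, e, w, t) +
      stats::runif(n, -strategy$halfwidth, strategy$halfwidth),
    fixed = rep_len(strategy$fixed_u, n),
    proportional = strategy$prop_factor * w,
    stop("unknown strategy kind: ", strategy$kind, call. = FALSE)
  )
  clamp(u, 0, params$n_intake)
}

lookup_policy <- function(policy, e, w, t) {
  if (is.null(policy)) {
    stop("this strategy requires a solved policy", call. = FALSE)
  }
  interpolate_value(policy_slice(policy, t), policy$grid, e, w)
}
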