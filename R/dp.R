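#' Discretization grid for the dynamic-programming solver
#'
#' The value function and policy are computed on a rectangular grid over the
#' state space `(E, W)` with a finite set of candidate allocations `u`.
#' Defaults: integer steps over `[0, e_max] x [0, w_max]` and allocations
#' `0, 0.1, ..., n_intake` (the model's action set is continuous; a fine
#' grid approximates it).
#'
#' @param params A [model_params()] object (supplies the bounds).
#' @param e_step,w_step State grid resolutions (default 1).
#' @param u_step Action grid resolution (default 0.1).
#' @return An object of class `symb_grid` with components `e`, `w`, `u`
#'   (increasing numeric vectors whose endpoints equal the bounds).
#' @export
state_grid <- function(params, e_step = 1, w_step = 1, u_step = 0.1) {
  axis <- function(hi, step) {
    v <- seq(0, hi, by = step)
    if (max(v) < hi) v <- c(v, hi)
    v
  }
  structure(list(e = axis(params$e_max, e_step),
                 w = axis(params$w_max, w_step),
                 u = axis(params$n_intake, u_step)),
            class = "symb_grid")
}

#' @export
print.symb_grid <- function(x, ...) {
  cat(sprintf("<symb_grid> %d x %d states, %d actions\n",
              length(x$e), length(x$w), length(x$u)))
  invisible(x)
}

# Vectorized bilinear interpolation of a matrix z (rows ~ xg, cols ~ yg) at
# query points (x, y), which must already lie within the grid bounds.
bilinear <- function(xg, yg, z, x, y) {
  nx <- length(xg); ny <- length(yg)
  ix <- clamp(findInterval(x, xg), 1L, nx - 1L)
  iy <- clamp(findInterval(y, yg), 1L, ny - 1L)
  fx <- (x - xg[ix]) / (xg[ix + 1L] - xg[ix])
  fy <- (y - yg[iy]) / (yg[iy + 1L] - yg[iy])
  z[cbind(ix, iy)] * (1 - fx) * (1 - fy) +
    z[cbind(ix + 1L, iy)] * fx * (1 - fy) +
    z[cbind(ix, iy + 1L)] * (1 - fx) * fy +
    z[cbind(ix + 1L, iy + 1L)] * fx * fy
}

#' Interpolate a value (or policy) slice at off-grid states
#'
#' Continuous dynamics carry hosts off the state grid; values there are read
#' by bilinear interpolation on the enclosing grid rectangle, after clamping
#' the query point into the grid bounds.  Exact at grid nodes.
#'
#' @param slice Numeric matrix indexed `[e, w]` on the grid axes.
#' @param grid A [state_grid()] object.
#' @param e,w Query coordinates (vectors).
#' @return Interpolated values.
#' @export
interpolate_value <- function(slice, grid, e, w) {
  bilinear(grid$e, grid$w,
           slice,
           clamp(e, min(grid$e), max(grid$e)),
           clamp(w, min(grid$w), max(grid$w)))
}

#' Terminal value slice at the horizon
#'
#' At `t = T` the reproductive value equals the immediate fitness obtainable
#' at that step (events 1-2 only; no decision remains).  With the base-case
#' schedule the last reproduction is at `t = 48 < T = 50`, so this slice is
#' identically zero.
#'
#' @inheritParams solve_policy
#' @return Numeric matrix `length(grid$e) x length(grid$w)`.
#' @export
terminal_values <- function(grid, params, scenario = scenario_config()) {
  eff <- effective_params(params, scenario)
  st <- expand_states(grid)
  e_prime <- energy_after_expenditure(st$e, eff)
  rep <- reproduction_event(e_prime, st$w, eff$horizon, eff, scenario)
  matrix(objective_fitness(rep$e_rep, rep$w_rep, scenario),
         nrow = length(grid$e))
}

expand_states <- function(grid) {
  list(e = rep(grid$e, times = length(grid$w)),
       w = rep(grid$w, each = length(grid$e)))
}

# Objective H = B + S * V(next) for every grid state (rows) and candidate
# action (columns), given the value slice at t + 1.
objective_matrix <- function(st, t, v_next, grid, eff, scenario) {
  n_s <- length(st$e)
  u <- grid$u
  n_u <- length(u)
  e_prime <- energy_after_expenditure(st$e, eff)
  rep <- reproduction_event(e_prime, st$w, t, eff, scenario)
  b <- objective_fitness(rep$e_rep, rep$w_rep, scenario)
  u_m <- matrix(u, n_s, n_u, byrow = TRUE)
  w_p <- matrix(rep$w_prime, n_s, n_u)
  w_dp <- ifelse(w_p > 0, w_p + (u_m - eff$alpha * w_p) * eff$beta, 0)
  e_tp <- matrix(rep$e_dprime + eff$n_intake, n_s, n_u) - u_m
  s <- survival_probability(e_tp, w_dp, t, eff, scenario)
  v <- interpolate_value(v_next, grid,
                         clamp(e_tp, 0, eff$e_max),
                         clamp(w_dp, 0, eff$w_max))
  matrix(b, n_s, n_u) + s * v
}

#' Expected objective of one state-action pair
#'
#' The dynamic-programming objective
#' `H(E, W; u) = B(E, W; u) + S(E, W; u) * V(E(t+1), W(t+1))`, where `B` is
#' the immediate contribution to fitness under the active objective, `S` the
#' survival probability, and `V` the (interpolated) reproductive value at the
#' resulting state.
#'
#' @inheritParams interpolate_value
#' @param t Time step.
#' @param u Candidate allocation (scalar).
#' @param v_next Value slice at `t + 1` (matrix on the grid).
#' @param params,scenario Model parameters and scenario.
#' @return Numeric vector of objective values.
#' @export
expected_objective <- function(e, w, t, u, v_next, grid, params,
                               scenario = scenario_config()) {
  eff <- effective_params(params, scenario)
  g1 <- grid
  g1$u <- u
  drop(objective_matrix(list(e = e, w = w), t, v_next, g1, eff, scenario))
}

#' Optimal allocation at one state
#'
#' Maximizes [expected_objective()] over the action grid; ties are broken
#' toward the largest allocation (an indifferent host passes surplus energy
#' on to its symbiont, which is what lets the symbiont proliferate once no
#' future reproduction can return value to the host).
#'
#' @inheritParams expected_objective
#' @return A list with `u_star` (the maximizing allocation) and `h_star`
#'   (the maximized objective).
#' @export
best_action <- function(e, w, t, v_next, grid, params,
                        scenario = scenario_config()) {
  eff <- effective_params(params, scenario)
  h <- objective_matrix(list(e = e, w = w), t, v_next, grid, eff, scenario)
  j <- max.col(h, ties.method = "last")
  list(u_star = grid$u[j], h_star = h[cbind(seq_len(nrow(h)), j)])
}

#' Solve the host's optimal energy-allocation policy by backward induction
#'
#' Iterates the dynamic-programming equation backwards from the horizon,
#' filling the reproductive-value table `V(E, W, t)` and the optimal-policy
#' table `u*(E, W, t)` on the state grid.  Decisions are made at
#' `t = 1, ..., T - 1`; the horizon contributes only its terminal value.
#' Deterministic given its inputs.
#'
#' @param params A [model_params()] object.
#' @param scenario A [scenario_config()] object; its `variant` shapes the
#'   dynamics and its `objective` selects host- or symbiont-fitness
#'   maximization.
#' @param grid A [state_grid()]; defaults to `state_grid(params)`.
#' @return An object of class `symb_policy`: list with `value`
#'   (array `e x w x t`, `t = 1..T`), `policy` (array `e x w x t`,
#'   `t = 1..T-1`), and the `grid`, `params`, `scenario` used.
#' @examples
#' p <- model_params(horizon = 10)
#' pol <- solve_policy(p, grid = state_grid(p, u_step = 1))
#' dplyr::filter(tidy(pol), t == 1, e == 20, w %in% c(1, 20))
#' @export
solve_policy <- function(params, scenario = scenario_config(),
                         grid = state_grid(params)) {
  eff <- effective_params(params, scenario)
  n_e <- length(grid$e); n_w <- length(grid$w); tt <- eff$horizon
  st <- expand_states(grid)
  value <- array(0, dim = c(n_e, n_w, tt))
  policy <- array(0, dim = c(n_e, n_w, max(tt - 1L, 1L)))
  value[, , tt] <- terminal_values(grid, params, scenario)
  for (t in rev(seq_len(tt - 1L))) {
    h <- objective_matrix(st, t, value[, , t + 1L], grid, eff, scenario)
    j <- max.col(h, ties.method = "last")
    value[, , t] <- h[cbind(seq_along(j), j)]
    policy[, , t] <- grid$u[j]
  }
  structure(list(value = value, policy = policy, grid = grid,
                 params = params, scenario = scenario),
            class = "symb_policy")
}

#' @export
print.symb_policy <- function(x, ...) {
  cat(sprintf(
    "<symb_policy> %s/%s: %d x %d grid, horizon %d, %d actions\n",
    x$scenario$variant, x$scenario$objective,
    length(x$grid$e), length(x$grid$w), x$params$horizon, length(x$grid$u)))
  invisible(x)
}

# Policy slice (matrix) at time t, for forward simulation.
policy_slice <- function(policy, t) {
  t_idx <- min(t, dim(policy$policy)[3])
  policy$policy[, , t_idx]
}
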