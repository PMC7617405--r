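#' Brute-force reproductive value by exhaustive action-sequence enumeration
#'
#' Independent oracle for the dynamic-programming solver.  Because the
#' within-step dynamics are deterministic (survival enters the objective as a
#' multiplicative weight, not a branching event), the closed-loop optimum
#' equals the best open-loop action sequence.  This function recurses over
#' the continuous state space, trying every candidate action at every step —
#' exponential in the remaining horizon and usable only on tiny instances,
#' but entirely free of state-grid interpolation.
#'
#' @param e,w State at time `t` (scalars).
#' @param t Current time step.
#' @param params,scenario Model configuration.
#' @param u_values Candidate allocations to enumerate.
#' @return Maximal expected lifetime fitness from `(e, w, t)` onward.
#' @seealso [solve_policy()], [make_fixture()]
#' @export
enumerate_value <- function(e, w, t, params, scenario = scenario_config(),
                            u_values = state_grid(params)$u) {
  eff <- effective_params(params, scenario)
  recurse <- function(e, w, t) {
    e_prime <- e - (eff$mu * e + eff$omega)
    rep <- reproduction_event(e_prime, w, t, eff, scenario)
    b <- objective_fitness(rep$e_rep, rep$w_rep, scenario)
    if (t >= eff$horizon) return(b)
    best <- -Inf
    for (u in u_values) {
      w_dp <- symbiont_growth(rep$w_prime, u, eff)
      e_tp <- rep$e_dprime + eff$n_intake - u
      s <- survival_probability(e_tp, w_dp, t, eff, scenario)
      v <- recurse(clamp(e_tp, 0, eff$e_max), clamp(w_dp, 0, eff$w_max),
                   t + 1L)
      h <- b + s * v
      if (h > best) best <- h
    }
    best
  }
  recurse(e, w, as.integer(t))
}

#' Enumerated value table for a whole grid
#'
#' Applies [enumerate_value()] to every node of a state grid for every time
#' step, returning an array comparable with `solve_policy()$value`.
#'
#' @inheritParams solve_policy
#' @return Array `length(grid$e) x length(grid$w) x horizon`.
#' @export
enumerate_values <- function(params, scenario = scenario_config(),
                             grid = state_grid(params)) {
  tt <- params$horizon
  out <- array(0, dim = c(length(grid$e), length(grid$w), tt))
  for (t in seq_len(tt)) {
    for (j in seq_along(grid$w)) {
      for (i in seq_along(grid$e)) {
        out[i, j, t] <- enumerate_value(grid$e[i], grid$w[j], t,
                                        params, scenario, grid$u)
      }
    }
  }
  out
}
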