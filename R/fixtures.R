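#' Named tiny model instances with brute-force solutions
#'
#' Small instances whose exact optimal values can be computed by the
#' exhaustive enumeration oracle ([enumerate_values()]) rather than the DP
#' solver, for regression and equivalence testing.
#'
#' `"tiny-T4"` is a 4-step, 5 x 5-state, 3-action instance whose dynamics
#' were chosen to keep every reachable state exactly on the integer grid
#' (no expenditure; maintenance cost 1 and growth efficiency 2 so the
#' density update maps integers to integers; transfer proportions 1/2 with
#' reproduction thresholds at the state bound 4), so grid interpolation in
#' the DP solver is exact and the two routes must agree to rounding error.
#' `"tiny-T3-offgrid"` is a 3-step instance with base-case-style dynamics
#' whose successors fall between grid nodes, for interpolation-tolerance
#' checks.
#'
#' @param name Fixture name: `"tiny-T4"` or `"tiny-T3-offgrid"`.
#' @param seed Integer recorded with the fixture (the instances are
#'   deterministic; the seed is used by callers simulating from them).
#' @return A list with `name`, `seed`, `params`, `scenario`, `grid`, and
#'   `oracle_value` (the enumerated value array).
#' @export
make_fixture <- function(name = c("tiny-T4", "tiny-T3-offgrid"), seed = 1L) {
  name <- match.arg(name)
  fx <- switch(name,
    "tiny-T4" = {
      p <- model_params(horizon = 4, e_max = 4, w_max = 4,
                        e_crit = 4, w_crit = 4, n_intake = 4,
                        mu = 0, omega = 0, alpha = 1, beta = 2,
                        lambda = 0.5, gamma = 0.5,
                        repro_first = 2, repro_interval = 2, repro_last = 4)
      list(params = p, scenario = scenario_config(),
           grid = state_grid(p, e_step = 1, w_step = 1, u_step = 1))
    },
    "tiny-T3-offgrid" = {
      p <- model_params(horizon = 3, e_max = 6, w_max = 6,
                        e_crit = 2, w_crit = 2, n_intake = 3,
                        mu = 0.2, omega = 1, alpha = 0.5, beta = 0.5,
                        lambda = 0.3, gamma = 0.2,
                        repro_first = 2, repro_interval = 1, repro_last = 3)
      list(params = p, scenario = scenario_config(),
           grid = state_grid(p, e_step = 1, w_step = 1, u_step = 1))
    }
  )
  fx$name <- name
  fx$seed <- as.integer(seed)
  fx$oracle_value <- enumerate_values(fx$params, fx$scenario, fx$grid)
  fx
}
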