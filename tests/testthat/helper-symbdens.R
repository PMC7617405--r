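# Shared tiny instances for fast tests.

tiny_params <- function(...) {
  model_params(horizon = 12, ...)
}

# A coarse but fully functional base-case setup (cheap to solve).
coarse_grid <- function(params, u_step = 0.5) {
  state_grid(params, u_step = u_step)
}

# Minimal hand-built cohort object for summary-level functions.
fake_cohort <- function(W, params = model_params(horizon = ncol(W)),
                        scenario = scenario_config()) {
  n <- nrow(W); tt <- ncol(W)
  structure(list(
    E = matrix(10, n, tt), W = W, U = matrix(0, n, tt),
    B = matrix(0, n, tt), W_rep = matrix(0, n, tt), S = matrix(1, n, tt),
    alive = matrix(TRUE, n, tt),
    fitness = tibble::tibble(host = seq_len(n), e_init = 10, w_init = W[, 1],
                             v_host = 0, v_symb = 0, lifespan = tt),
    params = params, scenario = scenario,
    strategy_kind = "fixed", survival_mode = "deterministic",
    seed = NULL, replicates = 1
  ), class = "symb_cohort")
}
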