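#' Within-time-step dynamics of the host-symbiont model
#'
#' Each time step a living host passes through six events, in order:
#' (1) metabolic expenditure, (2) reproduction (on schedule, if thresholds are
#' met), (3) feeding, (4) the allocation decision `u`, (5) the symbiont
#' density update, and (6) storage of the unallocated energy.  These
#' functions implement the individual events; [host_step()] composes them.
#'
#' All functions are vectorized over states.  Intermediate quantities
#' (`E'`, `E''`, `E'''`, `W'`, `W''`) are used unclamped within the step;
#' only stored next-step states are clamped into
#' `[0, e_max] x [0, w_max]`, and survival into `[0, 1]`.
#'
#' @param e,w Host energy reserves and symbiont density at the start of the
#'   step.
#' @param params A [model_params()] object.
#' @name step-events
NULL

#' @describeIn step-events Event (1): reserves after metabolic expenditure,
#'   `E' = E - (mu * E + omega)`.  May be negative (an intermediate value).
#' @export
energy_after_expenditure <- function(e, params) {
  e - (params$mu * e + params$omega)
}

#' @describeIn step-events Event (2): reproduction.  On a reproductive time
#'   step with `E' >= e_crit` and `W >= w_crit`, a proportion `lambda` of
#'   post-expenditure reserves and `gamma` of the symbiont population are
#'   transferred to offspring.  Returns a tibble with columns `e_dprime`,
#'   `w_prime`, `e_rep`, `w_rep`, `reproduced`.
#' @param e_prime Reserves after expenditure (`E'`).
#' @param t Time step index.
#' @param scenario A [scenario_config()] object.
#' @export
reproduction_event <- function(e_prime, w, t, params,
                               scenario = scenario_config()) {
  eff <- effective_params(params, scenario)
  gate <- is_repro_step(t, eff) & e_prime >= eff$e_crit & w >= eff$w_crit
  e_rep <- ifelse(gate, eff$lambda * e_prime, 0)
  w_rep <- ifelse(gate, eff$gamma * w, 0)
  tibble::tibble(
    e_dprime = e_prime - e_rep,
    w_prime = w - w_rep,
    e_rep = e_rep, w_rep = w_rep,
    reproduced = gate
  )
}

#' @describeIn step-events Event (5): next-step symbiont density
#'   `W'' = W' + (u - alpha * W') * beta` when `W' > 0`, and 0 when the
#'   population is extinct (`W' = 0`); clamped to `[0, w_max]`.
#' @param w_prime Density after reproduction (`W'`).
#' @param u Energy allocated to the symbiont, in `[0, n_intake]`.
#' @export
symbiont_transition <- function(w_prime, u, params) {
  check_allocation(u, params)
  clamp(symbiont_growth(w_prime, u, params), 0, params$w_max)
}

# unclamped W'' (used for survival and for the clamped stored state)
symbiont_growth <- function(w_prime, u, params) {
  ifelse(w_prime > 0,
         w_prime + (u - params$alpha * w_prime) * params$beta,
         0)
}

#' @describeIn step-events Event (6): next-step reserves
#'   `E''' = E'' + N - u`, clamped to `[0, e_max]`.
#' @param e_dprime Reserves after reproduction (`E''`).
#' @export
reserve_transition <- function(e_dprime, u, params) {
  check_allocation(u, params)
  clamp(e_dprime + params$n_intake - u, 0, params$e_max)
}

check_allocation <- function(u, params) {
  if (any(u < 0 | u > params$n_intake)) {
    stop("allocation u must lie in [0, ", params$n_intake, "]", call. = FALSE)
  }
  invisible(u)
}

#' @describeIn step-events Probability of surviving from `t` to `t + 1`:
#'   `(1 - exp(-s * E''')) * (1 - exp(-s * W''))`, evaluated on the unclamped
#'   end-of-step intermediates.  The non-essential variant offsets the density
#'   factor (`W'' + 2`); the temporary-benefit variant drops it entirely from
#'   host maturation (`t >= 8`) onwards.  Negative factors (from negative
#'   intermediate states) map to 0, so the result lies in `[0, 1]`.
#' @param e_tprime End-of-step reserves (`E'''`), possibly unclamped.
#' @param w_dprime End-of-step density (`W''`), possibly unclamped.
#' @export
survival_probability <- function(e_tprime, w_dprime, t, params,
                                 scenario = scenario_config()) {
  s <- params$s_shape
  f_e <- pmax(0, 1 - exp(-s * e_tprime))
  f_w <- switch(scenario$variant,
    non_essential = pmax(0, 1 - exp(-s * (w_dprime + scenario$ne_surv_offset))),
    temporary_benefit = ifelse(rep_len(t >= scenario$maturation_step,
                                       length(f_e)),
                               1, pmax(0, 1 - exp(-s * w_dprime))),
    pmax(0, 1 - exp(-s * w_dprime))
  )
  clamp(f_e * f_w, 0, 1)
}

#' @describeIn step-events Immediate contribution to host fitness at the end
#'   of the step: `B = E_rep * W_rep` (base), or
#'   `0.5 * E_rep * W_rep + 5` at every step for the non-essential variant.
#' @param e_rep,w_rep Energy and symbiont density transferred to offspring.
#' @export
immediate_fitness <- function(e_rep, w_rep, scenario = scenario_config()) {
  if (scenario$variant == "non_essential") {
    scenario$ne_scale * e_rep * w_rep + scenario$ne_offset
  } else {
    e_rep * w_rep
  }
}

# Objective accrued by the DP: host immediate fitness, or transferred density
# when optimizing for the symbiont.
objective_fitness <- function(e_rep, w_rep, scenario) {
  if (scenario$objective == "symbiont") w_rep
  else immediate_fitness(e_rep, w_rep, scenario)
}

#' Execute one full time step of the host-symbiont model
#'
#' Composes events (1)-(6) for living hosts in state `(E, W)` at time `t`
#' under allocation decision `u`.  Deterministic: survival is returned as a
#' probability, not drawn.
#'
#' @inheritParams step-events
#' @param t Time step index (scalar).
#' @param u Allocation decision(s) in `[0, n_intake]`.
#' @param scenario A [scenario_config()] object.
#' @param alive Logical; hosts must be alive to take a step.
#' @return A tibble with one row per input state: the intermediates
#'   `e_exp`, `e_prime`, `e_dprime`, `e_tprime`, `w_prime`, `w_dprime`, the
#'   transfers `e_rep`, `w_rep` and `reproduced`, the fitness increment
#'   `fitness`, the survival probability `survival`, and the clamped
#'   next-step state `e_next`, `w_next`.
#' @examples
#' host_step(e = 10, w = 8, t = 8, u = 3, params = model_params())
#' @export
host_step <- function(e, w, t, u, params, scenario = scenario_config(),
                      alive = TRUE) {
  if (!all(alive)) stop("host_step() requires living hosts", call. = FALSE)
  check_allocation(u, params)
  e_prime <- energy_after_expenditure(e, params)
  rep <- reproduction_event(e_prime, w, t, params, scenario)
  w_dprime <- symbiont_growth(rep$w_prime, u, params)
  e_tprime <- rep$e_dprime + params$n_intake - u
  tibble::tibble(
    e = e, w = w, t = t, u = u,
    e_exp = e - e_prime, e_prime = e_prime,
    e_dprime = rep$e_dprime, w_prime = rep$w_prime,
    e_rep = rep$e_rep, w_rep = rep$w_rep, reproduced = rep$reproduced,
    w_dprime = w_dprime, e_tprime = e_tprime,
    fitness = immediate_fitness(rep$e_rep, rep$w_rep, scenario),
    survival = survival_probability(e_tprime, w_dprime, t, params, scenario),
    e_next = clamp(e_tprime, 0, params$e_max),
    w_next = clamp(w_dprime, 0, params$w_max)
  )
}
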