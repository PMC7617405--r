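#' Default initial states of a simulated cohort
#'
#' Hosts start from every state on the integer grid
#' `{1, ..., e_max} x {1, ..., w_max}` (400 states in the base case); zero
#' reserves or zero density are excluded as dead/absorbing.
#'
#' @param params A [model_params()] object.
#' @return Tibble with columns `e`, `w`.
#' @export
initial_states <- function(params) {
  tidyr::expand_grid(e = seq_len(floor(params$e_max)),
                     w = seq_len(floor(params$w_max)))
}

#' Forward-simulate a cohort of hosts under an allocation strategy
#'
#' Each host starts at `t = 1` in its initial state and iterates the
#' within-step dynamics ([host_step()]) under the allocations chosen by
#' `strategy`.  The fitness increment `B` accrues at the end of each step;
#' in stochastic mode survival to the next step is then drawn as a Bernoulli
#' event with the step's survival probability (deterministic mode skips the
#' draw so every host reaches the horizon).  At the horizon only events
#' (1)-(2) occur: a final reproduction may accrue, then the simulation ends.
#'
#' Host lifetime fitness is `V_H = sum(B)` and symbiont fitness
#' `V_S = sum(W_rep)` over the steps the host was alive.
#'
#' @param params A [model_params()] object.
#' @param strategy A `symb_strategy` (see [strategies]).
#' @param scenario A [scenario_config()] object.
#' @param replicates Hosts per initial state (default 10; the base-case
#'   cohort is `400 x 10 = 4000` hosts).
#' @param init Tibble of initial states (`e`, `w`); defaults to
#'   [initial_states()].
#' @param survival `"stochastic"` (default) or `"deterministic"`.
#' @param seed Optional integer seed; the cohort is reproducible given
#'   `(seed, configuration)` and the global RNG state is left untouched.
#' @param perturb_times Optional integer vector: at the start of each of
#'   these steps (before metabolic expenditure) every surviving host's state
#'   is reset to its own `t = 1` values.
#' @return An object of class `symb_cohort`; see [tidy.symb_cohort()],
#'   [cohort_summary()], [glance.symb_cohort()].
#' @examples
#' p <- model_params(horizon = 12)
#' pol <- solve_policy(p, grid = state_grid(p, u_step = 0.5))
#' coh <- simulate_cohort(p, strategy_optimal(pol), replicates = 1,
#'                        survival = "deterministic")
#' cohort_summary(coh)
#' @export
simulate_cohort <- function(params, strategy,
                            scenario = scenario_config(),
                            replicates = 10,
                            init = initial_states(params),
                            survival = c("stochastic", "deterministic"),
                            seed = NULL,
                            perturb_times = NULL) {
  survival <- match.arg(survival)
  stopifnot(replicates >= 1)
  eff <- effective_params(params, scenario)
  if (!is.null(perturb_times) &&
      any(perturb_times < 1 | perturb_times > eff$horizon)) {
    stop("perturbation times must lie within 1..horizon", call. = FALSE)
  }
  run <- function() {
    simulate_cohort_impl(eff, strategy, scenario, replicates, init,
                         survival, perturb_times)
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  res$params <- params
  res$scenario <- scenario
  res$strategy_kind <- strategy$kind
  res$survival_mode <- survival
  res$seed <- seed
  res$replicates <- replicates
  res
}

simulate_cohort_impl <- function(eff, strategy, scenario, replicates, init,
                                 survival, perturb_times) {
  e1 <- rep(init$e, each = replicates)
  w1 <- rep(init$w, each = replicates)
  n_h <- length(e1)
  tt <- eff$horizon
  mat <- function() matrix(NA_real_, n_h, tt)
  E <- mat(); W <- mat(); U <- mat(); B <- mat(); WR <- mat(); S <- mat()
  alive_mat <- matrix(FALSE, n_h, tt)
  e <- e1; w <- w1; alive <- rep(TRUE, n_h)
  for (t in seq_len(tt)) {
    if (t %in% perturb_times) {
      e[alive] <- e1[alive]
      w[alive] <- w1[alive]
    }
    E[, t] <- ifelse(alive, e, NA_real_)
    W[, t] <- ifelse(alive, w, NA_real_)
    alive_mat[, t] <- alive
    e_prime <- energy_after_expenditure(e, eff)
    rep_ev <- reproduction_event(e_prime, w, t, eff, scenario)
    b <- immediate_fitness(rep_ev$e_rep, rep_ev$w_rep, scenario)
    B[, t] <- ifelse(alive, b, NA_real_)
    WR[, t] <- ifelse(alive, rep_ev$w_rep, NA_real_)
    if (t == tt) break
    u <- decide_allocation(strategy, e, w, t, eff)
    U[, t] <- ifelse(alive, u, NA_real_)
    w_dp <- symbiont_growth(rep_ev$w_prime, u, eff)
    e_tp <- rep_ev$e_dprime + eff$n_intake - u
    s <- survival_probability(e_tp, w_dp, t, eff, scenario)
    S[, t] <- ifelse(alive, s, NA_real_)
    if (survival == "stochastic") {
      # draw for every host, dead included, to keep the stream layout fixed
      alive <- alive & (stats::runif(n_h) < s)
    }
    e <- clamp(e_tp, 0, eff$e_max)
    w <- clamp(w_dp, 0, eff$w_max)
  }
  fitness <- tibble::tibble(
    host = seq_len(n_h), e_init = e1, w_init = w1,
    v_host = rowSums(B, na.rm = TRUE),
    v_symb = rowSums(WR, na.rm = TRUE),
    lifespan = rowSums(alive_mat)
  )
  structure(list(E = E, W = W, U = U, B = B, W_rep = WR, S = S,
                 alive = alive_mat, fitness = fitness),
            class = "symb_cohort")
}

#' Simulate a single host
#'
#' Convenience wrapper around [simulate_cohort()] for one initial state and
#' one replicate; returns the tidy trajectory.
#'
#' @inheritParams simulate_cohort
#' @param e,w Initial state.
#' @return Tibble trajectory (one row per time step alive).
#' @export
simulate_host <- function(e, w, params, strategy,
                          scenario = scenario_config(),
                          survival = c("stochastic", "deterministic"),
                          seed = NULL) {
  coh <- simulate_cohort(params, strategy, scenario, replicates = 1,
                         init = tibble::tibble(e = e, w = w),
                         survival = match.arg(survival), seed = seed)
  tidy(coh)
}

#' Simulate a cohort with developmental perturbations
#'
#' Identical to [simulate_cohort()] except that at the start of each
#' perturbation step every surviving host's energy reserves and symbiont
#' density are reset to that host's own `t = 1` values, before metabolic
#' expenditure.
#'
#' @inheritParams simulate_cohort
#' @param times Perturbation time steps (default `c(7, 24, 39)`).
#' @return A `symb_cohort`.
#' @export
simulate_perturbed_cohort <- function(params, strategy,
                                      scenario = scenario_config(),
                                      times = c(7, 24, 39), ...) {
  simulate_cohort(params, strategy, scenario, perturb_times = times, ...)
}

#' @export
print.symb_cohort <- function(x, ...) {
  cat(sprintf(
    "<symb_cohort> %d hosts, horizon %d, strategy '%s', %s survival\n",
    nrow(x$fitness), ncol(x$E), x$strategy_kind, x$survival_mode))
  cat(sprintf("  mean V_H = %.2f, mean V_S = %.2f, %.1f%% alive at horizon\n",
              mean(x$fitness$v_host), mean(x$fitness$v_symb),
              100 * mean(x$alive[, ncol(x$alive)])))
  invisible(x)
}

#' Per-time-step summary of a simulated cohort
#'
#' @param cohort A `symb_cohort`.
#' @return Tibble with one row per time step: mean/min/max symbiont density
#'   and energy reserves over surviving hosts, mean allocation, and the
#'   fraction of hosts still alive.
#' @export
cohort_summary <- function(cohort) {
  stopifnot(inherits(cohort, "symb_cohort"))
  col_stat <- function(m, f) apply(m, 2, function(x) {
    x <- x[!is.na(x)]
    if (length(x)) f(x) else NA_real_
  })
  tibble::tibble(
    t = seq_len(ncol(cohort$W)),
    w_mean = col_stat(cohort$W, mean),
    w_min = col_stat(cohort$W, min),
    w_max = col_stat(cohort$W, max),
    e_mean = col_stat(cohort$E, mean),
    e_min = col_stat(cohort$E, min),
    e_max = col_stat(cohort$E, max),
    u_mean = col_stat(cohort$U, mean),
    frac_alive = colMeans(cohort$alive)
  )
}

#' Plateau symbiont density of a cohort
#'
#' The level around which the symbiont density stabilizes, operationalized as
#' the mean of `W` over all time steps of the reproductive phase of life
#' (from the first reproductive event to the end of the schedule or the
#' horizon), across surviving hosts.
#'
#' @param cohort A `symb_cohort`.
#' @param params Parameters defining the reproductive schedule; defaults to
#'   the cohort's own.
#' @return Scalar plateau density, or `NA` if no host survived into the
#'   reproductive phase.
#' @export
plateau_density <- function(cohort, params = NULL) {
  params <- effective_params(params %||% cohort$params,
                             cohort$scenario %||% scenario_config())
  rs <- repro_steps(params)
  if (!length(rs)) return(NA_real_)
  window <- seq.int(min(rs), min(max(rs), ncol(cohort$W)))
  w <- cohort$W[, window, drop = FALSE]
  if (all(is.na(w))) return(NA_real_)
  mean(w, na.rm = TRUE)
}
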