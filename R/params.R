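#' Model parameters for the host-symbiont energy-allocation model
#'
#' Constructs the full parameter set of the base-case host-symbiont model.
#' The host is an iteroparous female that feeds once per time step, pays
#' metabolic costs, reproduces on a fixed schedule when its energy reserves
#' and symbiont density exceed thresholds, and each step decides how much of
#' the meal to allocate to its compartmentalized symbiont population.
#'
#' @param horizon Time horizon `T`: the maximum number of time steps a host
#'   can live (default 50).
#' @param e_max,w_max Upper bounds of the two state variables: host energy
#'   reserves `E` and within-host symbiont density `W` (default 20 each).
#'   Stored states are clamped into `[0, e_max]` and `[0, w_max]`.
#' @param e_crit,w_crit Minimum reserves / density required to reproduce
#'   (default 6 each).
#' @param n_intake Dietary energy `N` gained per time step (default 8); the
#'   allocation decision `u` is constrained to `[0, N]`.
#' @param mu Proportional increase of metabolic expenditure with reserves
#'   (default 0.2).
#' @param omega Fixed metabolic expenditure per step (default 2).
#' @param alpha Maintenance cost of the symbiont population, energy per unit
#'   of density per step (default 0.5).
#' @param beta Symbiont density gained per unit of net energy invested
#'   (default 0.5).
#' @param lambda Proportion of post-expenditure reserves invested in
#'   reproduction (default 0.3).
#' @param gamma Proportion of the symbiont population transmitted vertically
#'   to offspring at reproduction (default 0.2).
#' @param s_shape Shape coefficient of the survival function (default 0.3);
#'   survival from one step to the next is
#'   `(1 - exp(-s_shape * E''')) * (1 - exp(-s_shape * W''))`.
#' @param repro_first First reproductive time step (default 8).
#' @param repro_interval Steps between reproductive events (default 4).
#' @param repro_last Last possible reproductive step; defaults to `horizon`.
#'   Set to 32 for a host with an extended post-reproductive life stage.
#'
#' @return An object of class `symb_params`: a named list of validated
#'   parameters.
#' @seealso [scenario_config()], [repro_steps()], [host_step()]
#' @examples
#' p <- model_params()
#' repro_steps(p)
#' @export
model_params <- function(horizon = 50, e_max = 20, w_max = 20,
                         e_crit = 6, w_crit = 6, n_intake = 8,
                         mu = 0.2, omega = 2, alpha = 0.5, beta = 0.5,
                         lambda = 0.3, gamma = 0.2, s_shape = 0.3,
                         repro_first = 8, repro_interval = 4,
                         repro_last = NULL) {
  num <- as.numeric
  p <- list(
    horizon = as.integer(horizon), e_max = num(e_max), w_max = num(w_max),
    e_crit = num(e_crit), w_crit = num(w_crit), n_intake = num(n_intake),
    mu = num(mu), omega = num(omega), alpha = num(alpha), beta = num(beta),
    lambda = num(lambda), gamma = num(gamma), s_shape = num(s_shape),
    repro_first = as.integer(round(repro_first)),
    repro_interval = as.integer(round(repro_interval)),
    repro_last = as.integer(round(repro_last %||% horizon))
  )
  class(p) <- "symb_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  bad <- character()
  chk <- function(ok, msg) if (!isTRUE(ok)) bad <<- c(bad, msg)
  chk(p$horizon >= 1, "horizon must be >= 1")
  chk(p$e_max > 0 && p$w_max > 0, "state bounds must be positive")
  chk(p$n_intake > 0, "n_intake must be positive")
  chk(p$e_crit <= p$e_max, "e_crit must not exceed e_max")
  chk(p$w_crit <= p$w_max, "w_crit must not exceed w_max")
  chk(p$mu >= 0 && p$omega >= 0 && p$alpha >= 0 && p$beta >= 0,
      "mu, omega, alpha, beta must be non-negative")
  chk(p$lambda > 0 && p$lambda < 1, "lambda must lie in (0, 1)")
  chk(p$gamma >= 0 && p$gamma < 1, "gamma must lie in [0, 1)")
  chk(p$s_shape > 0, "s_shape must be positive")
  chk(p$repro_interval >= 1, "repro_interval must be >= 1")
  if (length(bad)) {
    stop("invalid model parameters: ", paste(bad, collapse = "; "),
         call. = FALSE)
  }
  invisible(p)
}

#' Reproductive schedule of a parameter set
#'
#' @param params A [model_params()] object.
#' @return Integer vector of reproductive time steps,
#'   `{repro_first, repro_first + repro_interval, ...} <= min(repro_last, horizon)`.
#' @export
repro_steps <- function(params) {
  last <- min(params$repro_last, params$horizon)
  if (params$repro_first > last) return(integer(0))
  seq.int(params$repro_first, last, by = params$repro_interval)
}

is_repro_step <- function(t, params) t %in% repro_steps(params)

#' @export
print.symb_params <- function(x, ...) {
  cat("<symb_params>\n")
  cat(sprintf("  horizon %d, E in [0, %g], W in [0, %g]\n",
              x$horizon, x$e_max, x$w_max))
  cat(sprintf("  intake N = %g, expenditure mu = %g, omega = %g\n",
              x$n_intake, x$mu, x$omega))
  cat(sprintf("  symbiont alpha = %g, beta = %g; transfer lambda = %g, gamma = %g\n",
              x$alpha, x$beta, x$lambda, x$gamma))
  cat(sprintf("  thresholds E_crit = %g, W_crit = %g; survival shape %g\n",
              x$e_crit, x$w_crit, x$s_shape))
  rs <- repro_steps(x)
  cat(sprintf("  reproduction at t = %s\n",
              if (length(rs)) paste(utils::head(rs, 4), collapse = ", ") else "never"),
      if (length(rs) > 4) sprintf("  ... %d\n", max(rs)) else "")
  invisible(x)
}

#' Scenario configuration: host-symbiont ecology variants and DP objective
#'
#' Selects which host-symbiont ecology the model describes and which fitness
#' quantity the dynamic-programming solver maximizes.
#'
#' Variants:
#' \describe{
#'   \item{`base`}{Obligate, vertically transmitted symbiont; host fitness
#'     `B = E_rep * W_rep` accrues at reproduction.}
#'   \item{`non_essential`}{Symbiont is not required for reproduction
#'     (`W_crit = 0`), contributes to survival only through an offset density
#'     (`W'' + 2`), and host fitness is `0.5 * E_rep * W_rep + 5` at every
#'     time step.}
#'   \item{`temporary_benefit`}{The symbiont contributes to survival only
#'     before host maturation: from `t >= maturation_step` survival depends
#'     on energy reserves alone.}
#'   \item{`post_reproductive`}{The host has an extended post-reproductive
#'     life stage: the final reproductive event occurs at
#'     `t = post_repro_last` (32).}
#'   \item{`symbiont_optimal`}{Base-case dynamics, but the DP objective is
#'     symbiont fitness: the density transferred to offspring, `W_rep`.}
#' }
#'
#' @param variant One of `"base"`, `"non_essential"`, `"temporary_benefit"`,
#'   `"post_reproductive"`, `"symbiont_optimal"`.
#' @param objective Quantity maximized by the DP: `"host"` or `"symbiont"`.
#'   Defaults to `"symbiont"` for the `symbiont_optimal` variant and `"host"`
#'   otherwise.
#' @param ne_scale,ne_offset Fitness constants of the non-essential variant:
#'   `B = ne_scale * E_rep * W_rep + ne_offset` (defaults 0.5 and 5).
#' @param ne_surv_offset Density offset in the non-essential survival factor
#'   (default 2).
#' @param maturation_step Host maturation step for the temporary-benefit
#'   variant (default 8).
#' @param post_repro_last Final reproductive step for the post-reproductive
#'   variant (default 32).
#' @return An object of class `symb_scenario`.
#' @examples
#' scenario_config("non_essential")
#' @export
scenario_config <- function(variant = c("base", "non_essential",
                                        "temporary_benefit",
                                        "post_reproductive",
                                        "symbiont_optimal"),
                            objective = NULL,
                            ne_scale = 0.5, ne_offset = 5, ne_surv_offset = 2,
                            maturation_step = 8, post_repro_last = 32) {
  variant <- match.arg(variant)
  objective <- objective %||% if (variant == "symbiont_optimal") "symbiont" else "host"
  objective <- match.arg(objective, c("host", "symbiont"))
  structure(list(variant = variant, objective = objective,
                 ne_scale = ne_scale, ne_offset = ne_offset,
                 ne_surv_offset = ne_surv_offset,
                 maturation_step = as.integer(maturation_step),
                 post_repro_last = as.integer(post_repro_last)),
            class = "symb_scenario")
}

#' @export
print.symb_scenario <- function(x, ...) {
  cat(sprintf("<symb_scenario> variant '%s', objective '%s'\n",
              x$variant, x$objective))
  invisible(x)
}

# Parameters as seen through a scenario: the non-essential variant removes the
# density threshold for reproduction, the post-reproductive variant caps the
# reproductive schedule.
effective_params <- function(params, scenario) {
  if (scenario$variant == "non_essential") params$w_crit <- 0
  if (scenario$variant == "post_reproductive") {
    params$repro_last <- min(params$repro_last, scenario$post_repro_last)
  }
  params
}

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
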