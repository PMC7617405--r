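#' Run configuration: parameters, scenario, strategy, and run settings
#'
#' Bundles everything needed to reproduce a run.  Serializes losslessly to
#' YAML; omitted fields take the base-case defaults, so an empty file
#' reproduces the base-case model.
#'
#' @param params A [model_params()] object.
#' @param scenario A [scenario_config()] object.
#' @param strategy Strategy settings as a list: `kind` plus any of
#'   `fixed_u`, `prop_factor`, `halfwidth` (policies are re-solved at run
#'   time, not serialized).
#' @param seed Integer seed.
#' @param replicates Hosts per initial state.
#' @param survival `"stochastic"` or `"deterministic"`.
#' @return An object of class `symb_run_config`.
#' @export
run_config <- function(params = model_params(),
                       scenario = scenario_config(),
                       strategy = list(kind = "optimal"),
                       seed = 1L, replicates = 10,
                       survival = "stochastic") {
  survival <- match.arg(survival, c("stochastic", "deterministic"))
  stopifnot(is.list(strategy), !is.null(strategy$kind))
  structure(list(params = params, scenario = scenario, strategy = strategy,
                 seed = as.integer(seed), replicates = replicates,
                 survival = survival),
            class = "symb_run_config")
}

config_field_names <- list(
  top = c("params", "scenario", "strategy", "seed", "replicates", "survival"),
  params = c("horizon", "e_max", "w_max", "e_crit", "w_crit", "n_intake",
             "mu", "omega", "alpha", "beta", "lambda", "gamma", "s_shape",
             "repro_first", "repro_interval", "repro_last"),
  scenario = c("variant", "objective", "ne_scale", "ne_offset",
               "ne_surv_offset", "maturation_step", "post_repro_last"),
  strategy = c("kind", "fixed_u", "prop_factor", "halfwidth")
)

#' Read a run configuration from a YAML file
#'
#' Unknown keys are rejected with an error naming them; every omitted field
#' takes its base-case default, so an empty file yields the base-case
#' configuration.  Parameter bounds are validated.
#'
#' @param path Path to a YAML file.
#' @return A [run_config()] object.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  check_keys <- function(x, allowed, where) {
    extra <- setdiff(names(x), allowed)
    if (length(extra)) {
      stop("unknown config key(s) in ", where, ": ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
  }
  check_keys(raw, config_field_names$top, "top level")
  check_keys(raw$params %||% list(), config_field_names$params, "params")
  check_keys(raw$scenario %||% list(), config_field_names$scenario, "scenario")
  check_keys(raw$strategy %||% list(), config_field_names$strategy, "strategy")
  params <- do.call(model_params, raw$params %||% list())
  scenario <- do.call(scenario_config, raw$scenario %||% list())
  strategy <- utils::modifyList(list(kind = "optimal"),
                                raw$strategy %||% list())
  run_config(params = params, scenario = scenario, strategy = strategy,
             seed = raw$seed %||% 1L,
             replicates = raw$replicates %||% 10,
             survival = raw$survival %||% "stochastic")
}

#' Write a run configuration to a YAML file
#'
#' @param config A [run_config()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "symb_run_config"))
  out <- list(
    params = unclass(config$params),
    scenario = unclass(config$scenario),
    strategy = config$strategy,
    seed = config$seed, replicates = config$replicates,
    survival = config$survival
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Build the strategy object a configuration describes
#'
#' Solves the required policy for policy-based strategies.
#'
#' @param config A [run_config()] object.
#' @param grid Optional [state_grid()] override.
#' @return A `symb_strategy`.
#' @export
config_strategy <- function(config, grid = state_grid(config$params)) {
  sp <- config$strategy
  switch(sp$kind,
    optimal = strategy_optimal(
      solve_policy(config$params, config$scenario, grid)),
    imperfect = strategy_imperfect(
      solve_policy(config$params, config$scenario, grid),
      halfwidth = sp$halfwidth %||% 1),
    fixed = strategy_fixed(sp$fixed_u %||% 3),
    proportional = strategy_proportional(sp$prop_factor %||% 0.3),
    symbiont_optimal = strategy_symbiont_optimal(
      solve_policy(config$params,
                   scenario_config(config$scenario$variant,
                                   objective = "symbiont"),
                   grid)),
    stop("unknown strategy kind: ", sp$kind, call. = FALSE)
  )
}
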