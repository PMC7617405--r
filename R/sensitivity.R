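#' Default parameter ranges for the sensitivity sweep
#'
#' Ranges over which each of the ten swept parameters is varied (the state
#' bounds `e_max`, `w_max` stay fixed at 20).  Ranges were chosen so that
#' models remain non-degenerate: host fitness can be non-zero and states are
#' not driven to their bounds.
#'
#' @return Tibble with columns `parameter`, `lo`, `hi`.
#' @export
sweep_ranges <- function() {
  tibble::tribble(
    ~parameter,  ~lo,  ~hi,
    "horizon",    40,   60,
    "n_intake",    6,   15,
    "e_crit",      1,   14,
    "w_crit",      1,   12,
    "mu",          0,    2,
    "omega",       0,    5,
    "alpha",     0.1,  1.5,
    "beta",     0.01,    5,
    "lambda",    0.1,  0.9,
    "gamma",     0.1,  0.9
  )
}

#' Design of a Latin-hypercube sensitivity sweep
#'
#' @param n Number of parameter samples (default 400).
#' @param ranges Tibble of parameter ranges as in [sweep_ranges()].
#' @param seed Integer seed for the sampling plan.
#' @return An object of class `symb_design`.
#' @export
sweep_design <- function(n = 400, ranges = sweep_ranges(), seed = 1L) {
  stopifnot(n >= 3, all(c("parameter", "lo", "hi") %in% names(ranges)),
            all(ranges$hi >= ranges$lo))
  structure(list(n = as.integer(n), ranges = ranges, seed = as.integer(seed)),
            class = "symb_design")
}

#' Latin-hypercube sample of a sweep design
#'
#' Stratified sampling: each parameter's range is divided into `n` equal
#' intervals with exactly one draw per interval, permuted independently
#' across parameters.  `horizon` is rounded to an integer; degenerate ranges
#' (`lo == hi`) are held constant.
#'
#' @param design A [sweep_design()].
#' @return Tibble of `n` parameter vectors (one column per parameter).
#' @export
lhs_sample <- function(design) {
  stopifnot(inherits(design, "symb_design"))
  r <- design$ranges
  unit <- withr::with_seed(design$seed,
                           lhs::randomLHS(design$n, nrow(r)))
  cols <- purrr::pmap(list(seq_len(nrow(r)), r$lo, r$hi),
                      function(j, lo, hi) lo + unit[, j] * (hi - lo))
  names(cols) <- r$parameter
  out <- tibble::as_tibble(cols)
  if ("horizon" %in% names(out)) out$horizon <- round(out$horizon)
  out
}

#' Run the full solve-then-simulate sensitivity sweep
#'
#' For every Latin-hypercube sample the swept parameters overwrite the base
#' parameter set, the optimal policy is re-solved, a cohort is simulated
#' under it, and the plateau symbiont density ([plateau_density()]) is
#' recorded.  Samples whose plateau is undefined (no host reaches the
#' reproductive phase) are flagged and excluded from correlation.
#'
#' @param design A [sweep_design()].
#' @param params Base parameters (defaults to [model_params()]).
#' @param scenario Scenario (default base).
#' @param replicates Hosts per initial state per sample (default 2, reduced
#'   from the cohort default of 10 for sweep speed).
#' @param survival Survival mode for the per-sample cohorts (default
#'   stochastic: hosts whose symbiont population collapses must die and drop
#'   out of the plateau average, exactly as in the full simulations;
#'   deterministic mode would keep them at `W = 0` and bias the plateau).
#' @param u_step Action resolution of the per-sample DP solves.
#' @param .progress Print a dot every 25 samples.
#' @return An object of class `symb_sweep`: the samples with their plateau
#'   values, plus the design.
#' @export
run_sweep <- function(design, params = model_params(),
                      scenario = scenario_config(),
                      replicates = 2,
                      survival = "stochastic",
                      u_step = 0.1,
                      .progress = FALSE) {
  samples <- lhs_sample(design)
  plateau <- purrr::map_dbl(seq_len(nrow(samples)), function(i) {
    if (.progress && i %% 25 == 0) cat(".")
    p <- params
    for (nm in names(samples)) p[[nm]] <- samples[[nm]][i]
    p$horizon <- as.integer(p$horizon)
    p$repro_last <- p$horizon
    p <- tryCatch(validate_params(p), error = function(e) NULL)
    if (is.null(p)) return(NA_real_)
    pol <- solve_policy(p, scenario, state_grid(p, u_step = u_step))
    coh <- simulate_cohort(p, strategy_optimal(pol), scenario,
                           replicates = replicates, survival = survival,
                           seed = design$seed + i)
    plateau_density(coh)
  })
  if (.progress) cat("\n")
  structure(list(samples = dplyr::mutate(samples, plateau = plateau),
                 design = design, n_failed = sum(is.na(plateau))),
            class = "symb_sweep")
}

#' @export
print.symb_sweep <- function(x, ...) {
  cat(sprintf("<symb_sweep> %d samples (%d undefined plateaus)\n",
              nrow(x$samples), x$n_failed))
  invisible(x)
}

#' Pearson correlation of each swept parameter with the plateau density
#'
#' Sample Pearson correlation with two-sided p-values from the t-distribution
#' on `n - 2` degrees of freedom (via [stats::cor.test()]); samples with an
#' undefined plateau are excluded listwise; zero-variance parameter columns
#' yield `NA`.
#'
#' @param sweep A `symb_sweep` (or a data frame with a `plateau` column and
#'   one column per parameter).
#' @param alpha Significance criterion (default 0.05).
#' @return Tibble with columns `parameter`, `estimate` (R), `p_value`,
#'   `significant`.
#' @export
sweep_correlations <- function(sweep, alpha = 0.05) {
  df <- if (inherits(sweep, "symb_sweep")) sweep$samples else tibble::as_tibble(sweep)
  df <- dplyr::filter(df, !is.na(.data$plateau))
  if (nrow(df) < 3) stop("need at least 3 valid samples", call. = FALSE)
  pars <- setdiff(names(df), "plateau")
  purrr::map_dfr(pars, function(nm) {
    x <- df[[nm]]
    if (stats::sd(x) == 0) {
      return(tibble::tibble(parameter = nm, estimate = NA_real_,
                            p_value = NA_real_, significant = NA))
    }
    ct <- stats::cor.test(x, df$plateau, method = "pearson")
    tibble::tibble(parameter = nm, estimate = unname(ct$estimate),
                   p_value = ct$p.value,
                   significant = ct$p.value < alpha)
  })
}
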