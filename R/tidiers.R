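#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a solved policy into a long tibble
#'
#' @param x A `symb_policy`.
#' @param ... Unused.
#' @return Tibble with columns `t`, `e`, `w`, `u_star` (`NA` at the horizon,
#'   where no decision remains) and `value`.
#' @export
tidy.symb_policy <- function(x, ...) {
  tt <- dim(x$value)[3]
  out <- tidyr::expand_grid(t = seq_len(tt), w = x$grid$w, e = x$grid$e)
  out <- out[c("t", "e", "w")]
  out$u_star <- NA_real_
  idx <- out$t < tt
  out$u_star[idx] <- c(x$policy[, , seq_len(tt - 1), drop = FALSE])
  out$value <- c(x$value)
  tibble::as_tibble(out)
}

#' One-row summary of a solved policy
#'
#' @param x A `symb_policy`.
#' @param ... Unused.
#' @export
glance.symb_policy <- function(x, ...) {
  tibble::tibble(
    variant = x$scenario$variant, objective = x$scenario$objective,
    horizon = x$params$horizon,
    n_e = length(x$grid$e), n_w = length(x$grid$w), n_u = length(x$grid$u),
    value_max = max(x$value), value_t1_max = max(x$value[, , 1])
  )
}

#' Tidy cohort trajectories into a long tibble
#'
#' @param x A `symb_cohort`.
#' @param ... Unused.
#' @return Tibble with one row per host per time step survived: `host`,
#'   `t`, `e`, `w`, `u`, `b`, `w_rep`, `survival`, `alive`.
#' @export
tidy.symb_cohort <- function(x, ...) {
  n_h <- nrow(x$E); tt <- ncol(x$E)
  out <- tibble::tibble(
    host = rep(seq_len(n_h), times = tt),
    t = rep(seq_len(tt), each = n_h),
    e = c(x$E), w = c(x$W), u = c(x$U),
    b = c(x$B), w_rep = c(x$W_rep), survival = c(x$S),
    alive = c(x$alive)
  )
  dplyr::arrange(dplyr::filter(out, .data$alive), .data$host, .data$t)
}

#' One-row fitness summary of a cohort
#'
#' @param x A `symb_cohort`.
#' @param ... Unused.
#' @return Tibble with host/symbiont fitness means and SDs, cohort size and
#'   survival to the horizon.
#' @export
glance.symb_cohort <- function(x, ...) {
  tibble::tibble(
    strategy = x$strategy_kind %||% NA_character_,
    n_hosts = nrow(x$fitness),
    v_host_mean = mean(x$fitness$v_host),
    v_host_sd = stats::sd(x$fitness$v_host),
    v_symb_mean = mean(x$fitness$v_symb),
    v_symb_sd = stats::sd(x$fitness$v_symb),
    frac_alive_horizon = mean(x$alive[, ncol(x$alive)])
  )
}

#' Tidy a sensitivity sweep into per-parameter correlations
#'
#' @param x A `symb_sweep`.
#' @param ... Passed to [sweep_correlations()].
#' @export
tidy.symb_sweep <- function(x, ...) sweep_correlations(x, ...)

#' One-row summary of a sensitivity sweep
#'
#' @param x A `symb_sweep`.
#' @param ... Unused.
#' @export
glance.symb_sweep <- function(x, ...) {
  ok <- !is.na(x$samples$plateau)
  tibble::tibble(n = nrow(x$samples), n_failed = x$n_failed,
                 plateau_mean = mean(x$samples$plateau[ok]),
                 plateau_sd = stats::sd(x$samples$plateau[ok]))
}

#' Tidy a strategy comparison into its pairwise test table
#'
#' @param x A `symb_comparison`.
#' @param ... Unused.
#' @export
tidy.symb_comparison <- function(x, ...) x$pairwise

#' Kruskal-Wallis summary of a strategy comparison
#'
#' @param x A `symb_comparison`.
#' @param ... Unused.
#' @export
glance.symb_comparison <- function(x, ...) x$kruskal
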