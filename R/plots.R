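#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an optimal allocation policy as state-space heat maps
#'
#' @param object A `symb_policy`.
#' @param t Time steps to display (default `5:8`, one full reproductive
#'   cycle of the converged base-case strategy).
#' @param what `"policy"` (optimal allocation, default) or `"value"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.symb_policy <- function(object, t = 5:8, what = c("policy", "value"),
                                 ...) {
  what <- match.arg(what)
  df <- dplyr::filter(tidy(object), .data$t %in% !!t)
  fill <- if (what == "policy") "u_star" else "value"
  ggplot2::ggplot(df, ggplot2::aes(.data$e, .data$w,
                                   fill = .data[[fill]])) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~t, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_viridis_c(name = if (what == "policy") "u*" else "V") +
    ggplot2::labs(x = "energy reserves E", y = "symbiont density W") +
    ggplot2::theme_minimal()
}

#' Plot cohort symbiont-density dynamics
#'
#' Mean symbiont density over surviving hosts with the min-max envelope;
#' reproductive steps are marked on the x-axis.
#'
#' @param object A `symb_cohort`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.symb_cohort <- function(object, ...) {
  sm <- cohort_summary(object)
  rs <- repro_steps(effective_params(object$params, object$scenario))
  ggplot2::ggplot(sm, ggplot2::aes(.data$t, .data$w_mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$w_min, ymax = .data$w_max),
                         fill = "grey80") +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::geom_rug(data = tibble::tibble(t = rs), ggplot2::aes(x = .data$t),
                      inherit.aes = FALSE, sides = "b") +
    ggplot2::labs(x = "time step", y = "symbiont density W",
                  title = sprintf("strategy: %s", object$strategy_kind)) +
    ggplot2::theme_minimal()
}

#' Plot a strategy comparison (means, 1 SD error bars, letter groups)
#'
#' @param object A `symb_comparison`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.symb_comparison <- function(object, ...) {
  sm <- object$summary
  ggplot2::ggplot(sm, ggplot2::aes(.data$strategy, .data$mean,
                                   fill = .data$fitness_type)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.9)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           position = ggplot2::position_dodge(0.9),
                           width = 0.25) +
    ggplot2::geom_text(ggplot2::aes(label = .data$letter,
                                    y = .data$mean + .data$sd),
                       position = ggplot2::position_dodge(0.9), vjust = -0.5) +
    ggplot2::labs(x = NULL, y = "lifetime fitness", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot sensitivity-sweep correlations
#'
#' @param object A `symb_sweep`.
#' @param ... Passed to [sweep_correlations()].
#' @return A ggplot.
#' @export
autoplot.symb_sweep <- function(object, ...) {
  df <- sweep_correlations(object, ...)
  ggplot2::ggplot(df, ggplot2::aes(stats::reorder(.data$parameter,
                                                  .data$estimate),
                                   .data$estimate,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Pearson R with plateau density") +
    ggplot2::theme_minimal()
}
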