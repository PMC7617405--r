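#' Kruskal-Wallis rank-sum test across strategy groups
#'
#' Thin wrapper around [stats::kruskal.test()] (tie-corrected H, chi-squared
#' p on `k - 1` degrees of freedom) that handles the degenerate case of all
#' observations identical, which is reported as `H = 0`, `p = 1`.
#'
#' @param values Numeric vector of observations.
#' @param groups Factor (or coercible) of group labels, same length.
#' @return Tibble with `statistic`, `df`, `p_value`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.factor(groups)
  stopifnot(length(values) == length(groups), nlevels(groups) >= 2)
  if (length(unique(values)) == 1) {
    return(tibble::tibble(statistic = 0, df = nlevels(groups) - 1L,
                          p_value = 1))
  }
  kt <- stats::kruskal.test(values, groups)
  tibble::tibble(statistic = unname(kt$statistic),
                 df = unname(kt$parameter),
                 p_value = kt$p.value)
}

#' Pairwise two-sided Wilcoxon rank-sum tests between strategy groups
#'
#' Mann-Whitney tests for every unordered pair of groups, reported both raw
#' and Holm-adjusted.  Pairs whose pooled observations are all identical are
#' reported as `p = 1`.
#'
#' @inheritParams kruskal_wallis
#' @return Tibble with `group1`, `group2`, `p_raw`, `p_holm`.
#' @export
pairwise_wilcoxon <- function(values, groups) {
  groups <- as.factor(groups)
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  p_raw <- apply(pairs, 2, function(pr) {
    x <- values[groups == pr[1]]
    y <- values[groups == pr[2]]
    if (length(unique(c(x, y))) == 1) return(1)
    suppressWarnings(stats::wilcox.test(x, y, exact = FALSE)$p.value)
  })
  tibble::tibble(group1 = pairs[1, ], group2 = pairs[2, ],
                 p_raw = p_raw,
                 p_holm = stats::p.adjust(p_raw, method = "holm"))
}

#' Compare host and symbiont fitness across allocation strategies
#'
#' Assembles the lifetime-fitness samples (`V_H`, `V_S`) of one simulated
#' cohort per strategy, tests for overall differences with Kruskal-Wallis
#' and for pairwise differences with two-sided Wilcoxon rank-sum tests
#' (raw and Holm-adjusted), and summarizes each strategy by mean, SD, and a
#' compact significance-letter grouping (strategies sharing a letter are not
#' significantly different on the Holm-adjusted matrix at the 5% criterion).
#'
#' @param cohorts Either a named list of `symb_cohort` objects (one per
#'   strategy) or a tibble with columns `strategy`, `v_host`, `v_symb`.
#' @param alpha Significance criterion (default 0.05).
#' @param adjust Use `"holm"`-adjusted (default) or `"raw"` pairwise
#'   p-values for the letter grouping.
#' @return An object of class `symb_comparison` with elements `fitness`
#'   (long tibble), `kruskal`, `pairwise`, `summary`.
#' @seealso [tidy.symb_comparison()], [glance.symb_comparison()],
#'   [autoplot.symb_comparison()]
#' @export
compare_strategies <- function(cohorts, alpha = 0.05,
                               adjust = c("holm", "raw")) {
  adjust <- match.arg(adjust)
  fitness <- if (is.data.frame(cohorts)) {
    tibble::as_tibble(cohorts)
  } else {
    if (is.null(names(cohorts)) || any(names(cohorts) == "")) {
      stop("`cohorts` list must be named by strategy", call. = FALSE)
    }
    purrr::imap_dfr(cohorts, function(coh, nm) {
      stopifnot(inherits(coh, "symb_cohort"))
      dplyr::mutate(coh$fitness[c("v_host", "v_symb")], strategy = nm,
                    .before = 1)
    })
  }
  stopifnot(all(c("strategy", "v_host", "v_symb") %in% names(fitness)))
  fitness$strategy <- factor(fitness$strategy,
                             levels = unique(fitness$strategy))
  long <- tidyr::pivot_longer(fitness, c("v_host", "v_symb"),
                              names_to = "fitness_type", values_to = "value")
  long$fitness_type <- dplyr::recode(long$fitness_type,
                                     v_host = "host", v_symb = "symbiont")
  by_type <- split(long, long$fitness_type)
  kruskal <- purrr::imap_dfr(by_type, function(d, ft) {
    dplyr::mutate(kruskal_wallis(d$value, d$strategy), fitness_type = ft,
                  .before = 1)
  })
  pairwise <- purrr::imap_dfr(by_type, function(d, ft) {
    dplyr::mutate(pairwise_wilcoxon(d$value, d$strategy), fitness_type = ft,
                  .before = 1)
  })
  summary <- purrr::imap_dfr(by_type, function(d, ft) {
    pw <- pairwise[pairwise$fitness_type == ft, ]
    p_use <- if (adjust == "holm") pw$p_holm else pw$p_raw
    means <- dplyr::summarise(dplyr::group_by(d, .data$strategy),
                              mean = mean(.data$value),
                              sd = stats::sd(.data$value), .groups = "drop")
    means$letter <- significance_letters(levels(d$strategy),
                                         pw$group1, pw$group2,
                                         p_use >= alpha, means$mean)
    dplyr::mutate(means, fitness_type = ft, .before = 1)
  })
  structure(list(fitness = fitness, kruskal = kruskal, pairwise = pairwise,
                 summary = summary, alpha = alpha, adjust = adjust),
            class = "symb_comparison")
}

# Compact letter display: letters are the maximal cliques of the
# "not significantly different" graph, ordered by descending group mean.
significance_letters <- function(groups, g1, g2, not_sig, means) {
  k <- length(groups)
  adj <- diag(TRUE, k)
  dimnames(adj) <- list(groups, groups)
  adj[cbind(g1, g2)] <- not_sig
  adj[cbind(g2, g1)] <- not_sig
  subsets <- lapply(seq_len(2^k) - 1L,
                    function(m) which(bitwAnd(m, 2^(seq_len(k) - 1L)) > 0))
  is_clique <- vapply(subsets, function(s) {
    length(s) > 0 && all(adj[s, s, drop = FALSE])
  }, logical(1))
  cliques <- subsets[is_clique]
  maximal <- cliques[vapply(seq_along(cliques), function(i) {
    !any(vapply(cliques, function(other) {
      length(other) > length(cliques[[i]]) && all(cliques[[i]] %in% other)
    }, logical(1)))
  }, logical(1))]
  maximal <- maximal[order(vapply(maximal, function(s) -max(means[s]),
                                  numeric(1)))]
  vapply(seq_len(k), function(i) {
    paste(letters[which(vapply(maximal, function(s) i %in% s, logical(1)))],
          collapse = "")
  }, character(1))
}

#' @export
print.symb_comparison <- function(x, ...) {
  cat(sprintf("<symb_comparison> %d strategies, %d observations each\n",
              nlevels(x$fitness$strategy),
              nrow(x$fitness) / nlevels(x$fitness$strategy)))
  print(x$summary)
  invisible(x)
}
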