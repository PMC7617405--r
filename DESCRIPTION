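Package: symbdens
Title: Host-Controlled Regulation of Endosymbiont Density by Optimal
    Energy Allocation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how a host should regulate the density of an
    obligate, vertically transmitted endosymbiont when control is exerted
    through the allocation of dietary energy.  A finite-horizon,
    state-dependent dynamic programming solver computes the energy-allocation
    policy that maximizes host (or symbiont) lifetime fitness over the joint
    state of host energy reserves and within-host symbiont density.  Forward
    Monte-Carlo simulation of host cohorts under the optimal policy and under
    alternative allocation rules (imperfect implementation, fixed allocation,
    density-proportional allocation, symbiont-optimal allocation) tracks
    symbiont-density dynamics, perturbation responses, and host and symbiont
    lifetime fitness.  Latin-hypercube parameter sweeps with Pearson
    correlation quantify the sensitivity of the plateau symbiont density to
    model parameters, and Kruskal-Wallis plus pairwise Wilcoxon rank-sum
    comparisons rank the allocation strategies.  Results are returned as
    tibbles with broom-style tidy() and glance() methods and ggplot2
    autoplot() visualizations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
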