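#' Write the result files of a run
#'
#' Writes the CSV outputs belonging to a result object plus a JSON run
#' manifest (configuration echo, seed, package version, timestamp) and a
#' short log file.
#'
#' Files by result type: `symb_policy` gives `policy.csv` (long format:
#' `t`, `e`, `w`, `u_star`, `value`); `symb_cohort` gives `fitness.csv`
#' (one row per host) and `summary.csv` (per time step), plus
#' `trajectories.csv` when `trajectories = TRUE`; `symb_sweep` gives
#' `samples.csv` and `correlations.csv`; `symb_comparison` gives
#' `comparison_summary.csv` and `pairwise.csv`.
#'
#' @param result A `symb_policy`, `symb_cohort`, `symb_sweep` or
#'   `symb_comparison`.
#' @param dir Output directory (created if needed).
#' @param config Optional [run_config()] echoed into the manifest.
#' @param seed Optional seed recorded in the manifest.
#' @param trajectories Also write full per-host trajectories for cohorts
#'   (default `FALSE`; the file is large).
#' @return Character vector of the files written, invisibly.
#' @export
write_outputs <- function(result, dir, config = NULL, seed = NULL,
                          trajectories = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory ", dir,
                             call. = FALSE)
  files <- character()
  put <- function(df, name) {
    path <- file.path(dir, name)
    readr::write_csv(df, path)
    files <<- c(files, path)
  }
  if (inherits(result, "symb_policy")) {
    put(tidy(result), "policy.csv")
  } else if (inherits(result, "symb_cohort")) {
    put(result$fitness, "fitness.csv")
    put(cohort_summary(result), "summary.csv")
    if (trajectories) put(tidy(result), "trajectories.csv")
  } else if (inherits(result, "symb_sweep")) {
    put(result$samples, "samples.csv")
    put(sweep_correlations(result), "correlations.csv")
  } else if (inherits(result, "symb_comparison")) {
    put(result$summary, "comparison_summary.csv")
    put(result$pairwise, "pairwise.csv")
  } else {
    stop("no writer for objects of class ", class(result)[1], call. = FALSE)
  }
  manifest <- list(
    package = "symbdens",
    version = as.character(utils::packageVersion("symbdens")),
    seed = seed %||% config$seed,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    result_class = class(result)[1],
    config = if (!is.null(config)) {
      list(params = unclass(config$params),
           scenario = unclass(config$scenario),
           strategy = config$strategy, seed = config$seed,
           replicates = config$replicates, survival = config$survival)
    }
  )
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       null = "null", digits = NA)
  log_path <- file.path(dir, "run.log")
  writeLines(sprintf("[%s] wrote %s for %s",
                     manifest$timestamp,
                     paste(basename(files), collapse = ", "),
                     class(result)[1]),
             log_path)
  invisible(c(files, manifest_path, log_path))
}
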