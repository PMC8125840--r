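# End-to-end orchestration: (extract) -> screen -> RFE -> select ->
# evaluate, with a reproducible run report.

#' Run the full frailty-biomarker pipeline
#'
#' Stages: feature extraction (when given recordings or a cohort spec),
#' normality-routed significance screening, bootstrapped recursive feature
#' elimination, phenotype-covering optimal-subset selection, and
#' bootstrap-validated performance of both the selected subset and the
#' full significant set. The run is a pure function of its inputs and
#' seeds: identical configuration yields an identical report.
#'
#' @param input One of: a feature-table tibble, a path to a feature-table
#'   CSV, a [cohort_spec()] (a synthetic cohort is simulated and
#'   features extracted), or a list of `sts_recording` objects.
#' @param alpha Screening significance level.
#' @param config A [selection_config()].
#' @param threshold Operating probability threshold for
#'   sensitivity/specificity/accuracy.
#' @param ci CI method for performance summaries.
#' @param features Feature columns to consider (default: canonical
#'   features present in the table).
#' @return A `frailty_run`: list with `screen`, `rfe`, `selection`,
#'   `performance` (selected subset), `performance_full` (all significant
#'   features), `exclusions`, and a `provenance` block (alpha, threshold,
#'   config, config hash, package version).
#' @export
#' @examples
#' tbl <- simulate_feature_table(seed = 11)
#' run <- run_frailty_pipeline(tbl, config = selection_config(B = 20, seed = 3))
#' run$selection
run_frailty_pipeline <- function(input, alpha = 0.05,
                                 config = selection_config(),
                                 threshold = 0.5,
                                 ci = c("percentile", "sem"),
                                 features = NULL) {
  ci <- match.arg(ci)
  exclusions <- tibble::tibble(subject_id = character(), n_cycles = integer())
  table <- if (inherits(input, "cohort_spec")) {
    tab <- extract_cohort_features(simulate_cohort(input))
    exclusions <- attr(tab, "excluded")
    tab
  } else if (is.character(input)) {
    read_feature_table(input)
  } else if (is.data.frame(input)) {
    tibble::as_tibble(input)
  } else if (is.list(input)) {
    tab <- extract_cohort_features(input)
    exclusions <- attr(tab, "excluded")
    tab
  } else {
    rlang::abort("`input` must be a feature table, a path, a cohort_spec or recordings.")
  }
  if (is.null(features)) features <- .feature_columns(table)

  screen <- screen_features(table, alpha = alpha, features = features)
  sig <- significant_features(screen)
  if (length(sig) < 2) {
    rlang::abort(
      sprintf("No significant features to select from (%d passed the filter at alpha = %g).",
              length(sig), alpha),
      class = "frailty_no_features"
    )
  }
  rfe <- rfe_rank(table, sig, config = config)
  selection <- select_optimal(rfe)
  perf_sel <- if (selection$admissible) {
    bootstrap_performance(table, selection$features, rfe$splits,
                          threshold = threshold, ci = ci)
  } else NULL
  perf_full <- bootstrap_performance(table, sig, rfe$splits,
                                     threshold = threshold, ci = ci)
  structure(
    list(
      n_subjects = nrow(table),
      screen = screen, rfe = rfe, selection = selection,
      performance = perf_sel, performance_full = perf_full,
      exclusions = exclusions,
      provenance = list(
        alpha = alpha, threshold = threshold, ci = ci,
        config = unclass(config)[c("B", "seed", "auc_threshold", "stratified", "direction")],
        config_hash = rlang::hash(list(alpha, threshold, ci, unclass(config))),
        package_version = as.character(utils::packageVersion("stsfrailty"))
      )
    ),
    class = "frailty_run"
  )
}

#' Write a pipeline run report to disk
#'
#' Emits `report.json` (screen results, elimination trace, ranking,
#' selection, performance summaries and provenance) plus CSVs of the
#' screen table, the elimination trace, the ranking and the performance
#' summaries. The report contains no timestamps, so identical runs write
#' byte-identical files.
#'
#' @param run A `frailty_run`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(run, dir) {
  stopifnot(inherits(run, "frailty_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(tibble::as_tibble(run$screen), file.path(dir, "screen.csv"))
  readr::write_csv(run$rfe$trace, file.path(dir, "rfe_trace.csv"))
  readr::write_csv(run$rfe$ranking, file.path(dir, "ranking.csv"))
  if (!is.null(run$performance)) {
    readr::write_csv(tibble::as_tibble(run$performance), file.path(dir, "performance.csv"))
  }
  report <- list(
    n_subjects = run$n_subjects,
    screen = tibble::as_tibble(run$screen),
    trace = run$rfe$trace,
    ranking = run$rfe$ranking,
    loo_fits = run$rfe$loo_fits,
    selection = unclass(run$selection),
    performance = if (!is.null(run$performance)) tibble::as_tibble(run$performance),
    performance_full = tibble::as_tibble(run$performance_full),
    exclusions = run$exclusions,
    provenance = run$provenance
  )
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(dir)
}

#' @export
print.frailty_run <- function(x, ...) {
  cat(sprintf("<frailty_run> n = %d subjects, %d significant feature(s)\n",
              x$n_subjects, sum(x$screen$significant)))
  print(x$selection)
  if (!is.null(x$performance)) {
    cat("Validation performance of the selected subset (%):\n")
    print(tibble::as_tibble(x$performance))
  }
  invisible(x)
}
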