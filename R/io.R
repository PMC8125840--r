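# Plain-text I/O: feature-table CSV with schema validation, per-subject
# recording CSVs with a JSON cohort manifest.

#' Validate a feature table against the canonical schema
#'
#' Checks that `status` exists and is binary 0/1 (naming the first
#' offending row otherwise), that all required feature columns are present
#' (listing the missing names), and that feature cells are numeric. Extra
#' columns are allowed with a warning.
#'
#' @param table A data frame.
#' @param features Required feature columns (default the canonical 17).
#' @return The table, invisibly, as a tibble.
#' @export
validate_feature_table <- function(table, features = sts_feature_names()) {
  table <- tibble::as_tibble(table)
  if (!"status" %in% names(table)) rlang::abort("Missing `status` column.")
  bad <- which(!table$status %in% c(0, 1))
  if (length(bad)) {
    rlang::abort(sprintf("Non-binary `status` value in row %d: %s",
                         bad[1], table$status[bad[1]]))
  }
  missing <- setdiff(features, names(table))
  if (length(missing)) {
    rlang::abort(paste("Missing feature column(s):", paste(missing, collapse = ", ")))
  }
  nonnum <- features[!vapply(table[features], is.numeric, logical(1))]
  if (length(nonnum)) {
    rlang::abort(paste("Non-numeric feature column(s):", paste(nonnum, collapse = ", ")))
  }
  extra <- setdiff(names(table), c("subject_id", "status", features))
  if (length(extra)) {
    rlang::warn(paste("Ignoring extra column(s):", paste(extra, collapse = ", ")))
  }
  invisible(table)
}

#' Read / write a feature-table CSV
#'
#' The CSV carries `subject_id`, `status` and the 17 canonical feature
#' columns; [validate_feature_table()] is applied on read.
#'
#' @param path File path.
#' @param features Required feature columns.
#' @return `read_feature_table()` returns a validated tibble.
#' @export
read_feature_table <- function(path, features = sts_feature_names()) {
  if (!file.exists(path)) rlang::abort(paste("No such file:", path))
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_feature_table(tbl, features)
  tbl
}

#' @rdname read_feature_table
#' @param table Feature table to write.
#' @export
write_feature_table <- function(table, path) {
  readr::write_csv(table, path)
  invisible(path)
}

#' Write / read a cohort of recordings as CSV files plus a JSON manifest
#'
#' One CSV per subject (columns `time_s`, `trunk_pitch_rad`,
#' `thigh_pitch_rad`, `shank_pitch_rad`, `vert_disp_m`) and a
#' `manifest.json` with subject id, status, body mass and height.
#'
#' @param cohort List with `recordings` and `manifest` (see
#'   [simulate_cohort()]).
#' @param dir Output directory (created if needed).
#' @return `read_cohort()` returns a cohort list; `write_cohort()` the
#'   directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (rec in cohort$recordings) {
    readr::write_csv(rec$data, file.path(dir, paste0(rec$subject_id, ".csv")))
  }
  jsonlite::write_json(cohort$manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows", digits = NA)
  invisible(dir)
}

#' @rdname write_cohort
#' @param sampling_rate Sampling rate of the stored recordings (Hz).
#' @export
read_cohort <- function(dir, sampling_rate = 100) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) rlang::abort(paste("No manifest.json in", dir))
  manifest <- tibble::as_tibble(jsonlite::read_json(mf, simplifyVector = TRUE))
  recs <- purrr::map(seq_len(nrow(manifest)), function(i) {
    data <- readr::read_csv(file.path(dir, paste0(manifest$subject_id[i], ".csv")),
                            show_col_types = FALSE, progress = FALSE)
    structure(
      list(data = data, sampling_rate = sampling_rate,
           mass = manifest$mass_kg[i], height = manifest$height_m[i],
           status = manifest$status[i], subject_id = manifest$subject_id[i],
           profile = NULL, cycles = NULL),
      class = "sts_recording"
    )
  })
  list(recordings = recs, manifest = manifest)
}
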