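# External-format interchange. Expression travels as a genes x samples TSV
# matrix with a sample-metadata CSV sidecar; melatonin as a long CSV;
# actigraphy as an epoch CSV with ISO-8601 timestamps plus a rest-interval
# CSV. Timestamps are anchored at an arbitrary fixed origin (midnight,
# 2000-01-03 UTC) since the simulator works in hours from recording start.

activity_origin <- function() {
  as.POSIXct("2000-01-03 00:00:00", tz = "UTC")
}

#' Write a cohort to interchange files
#'
#' Writes `expression.tsv` (genes x samples), `samples.csv` (sample metadata),
#' `melatonin.csv`, `activity_epochs.csv`, `rest_intervals.csv`, and
#' `subjects.csv` into `dir`.
#'
#' @param cohort A `circ_cohort`.
#' @param dir Output directory, created if needed.
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wide <- cohort$expression |>
    dplyr::select("gene_id", "sample_id", "value") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "value")
  readr::write_tsv(wide, file.path(dir, "expression.tsv"))
  cohort$expression |>
    dplyr::distinct(.data$sample_id, .data$subject_id, .data$clock_time,
                    .data$session) |>
    readr::write_csv(file.path(dir, "samples.csv"))
  readr::write_csv(cohort$melatonin, file.path(dir, "melatonin.csv"))
  cohort$activity$epochs |>
    dplyr::mutate(timestamp = activity_origin() + .data$time * 3600,
                  .keep = "unused", .after = "subject_id") |>
    readr::write_csv(file.path(dir, "activity_epochs.csv"))
  readr::write_csv(cohort$activity$rest_intervals,
                   file.path(dir, "rest_intervals.csv"))
  readr::write_csv(cohort$subjects, file.path(dir, "subjects.csv"))
  invisible(dir)
}

#' Read an expression matrix and sample metadata
#'
#' Inverse of the `expression.tsv` + `samples.csv` pair written by
#' [write_cohort()]: returns the long tibble format used by
#' [within_subject_normalize()] and [train_clock()].
#'
#' @param expression_tsv Genes x samples TSV; first column `gene_id`.
#' @param samples_csv Sample metadata CSV with `sample_id`, `subject_id`,
#'   `clock_time`, and optionally `session`.
#' @return Long expression tibble.
#' @export
read_expression <- function(expression_tsv, samples_csv) {
  wide <- readr::read_tsv(expression_tsv, show_col_types = FALSE)
  meta <- readr::read_csv(samples_csv, show_col_types = FALSE)
  long <- wide |>
    tidyr::pivot_longer(-"gene_id", names_to = "sample_id",
                        values_to = "value")
  missing <- setdiff(long$sample_id, meta$sample_id)
  if (length(missing) > 0) {
    abort(sprintf("Samples without metadata: %s",
                  paste(unique(missing), collapse = ", ")))
  }
  dplyr::left_join(long, meta, by = "sample_id")
}

#' Read a long melatonin CSV
#'
#' @param path CSV with columns `subject_id`, `medium`, `time`, `pg_ml`.
#' @return Tibble in the [dlmo_table()] input format.
#' @export
read_melatonin <- function(path) {
  mel <- readr::read_csv(path, show_col_types = FALSE)
  needed <- c("subject_id", "medium", "time", "pg_ml")
  if (!all(needed %in% names(mel))) {
    abort(sprintf("Melatonin CSV needs columns: %s",
                  paste(needed, collapse = ", ")))
  }
  mel
}

#' Read epoch-level actigraphy and rest intervals
#'
#' Converts ISO-8601 timestamps back to hours since the midnight preceding the
#' first epoch, the time axis used by the actigraphy metrics.
#'
#' @param epochs_csv CSV with `subject_id`, `timestamp` (ISO-8601), `counts`.
#' @param rest_csv CSV with `subject_id`, `night`, `bedtime`, `waketime`
#'   (hours on the same axis).
#' @return List with `epochs` and `rest_intervals` tibbles.
#' @export
read_activity <- function(epochs_csv, rest_csv) {
  ep <- readr::read_csv(epochs_csv, show_col_types = FALSE)
  day0 <- trunc(min(ep$timestamp), "days")
  ep <- ep |>
    dplyr::mutate(time = as.numeric(difftime(.data$timestamp, day0,
                                             units = "hours")),
                  .keep = "unused", .after = "subject_id")
  list(epochs = ep,
       rest_intervals = readr::read_csv(rest_csv, show_col_types = FALSE))
}
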