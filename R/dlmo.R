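#' Calibrate a saliva melatonin threshold from paired samples
#'
#' Saliva assays run lower than plasma; the onset threshold is therefore
#' expressed as the saliva level equivalent to a reference plasma
#' concentration. The calibration is `plasma_equivalent * mean(saliva/plasma)`
#' over the concurrent pairs -- the mean of per-pair ratios, not the ratio of
#' means.
#'
#' @param pairs Tibble or data frame with numeric columns `saliva` and
#'   `plasma` (pg/mL), one row per concurrent pair.
#' @param plasma_equivalent Reference plasma concentration, pg/mL. The
#'   conventional onset criterion is 10 pg/mL.
#' @return Saliva threshold in pg/mL.
#' @examples
#' calibrate_threshold(data.frame(saliva = c(2, 4), plasma = c(10, 10)))
#' @export
calibrate_threshold <- function(pairs, plasma_equivalent = 10) {
  if (!all(c("saliva", "plasma") %in% names(pairs))) {
    abort("`pairs` needs `saliva` and `plasma` columns.")
  }
  pairs <- pairs[stats::complete.cases(pairs[c("saliva", "plasma")]), ]
  if (nrow(pairs) == 0) {
    abort("No complete saliva/plasma pairs to calibrate from.",
          class = "circphen_calibration_error")
  }
  if (any(pairs$plasma <= 0)) {
    abort("All plasma concentrations must be positive for ratio calibration.",
          class = "circphen_calibration_error")
  }
  plasma_equivalent * mean(pairs$saliva / pairs$plasma)
}

# Index of the sustained up-crossing: the first sample at/above threshold from
# which the profile never returns below. NA when absent.
sustained_crossing <- function(conc, threshold) {
  above <- conc >= threshold
  # tail_above[i]: all samples i..n at/above threshold
  tail_above <- rev(cumprod(rev(above))) > 0
  idx <- which(tail_above)
  if (length(idx) == 0) NA_integer_ else idx[1]
}

#' Quality-control a melatonin profile for DLMO estimation
#'
#' Codifies the "hockey stick" inclusion rule as a deterministic check. A
#' profile passes when (a) at least one sample lies strictly below the
#' threshold before the first up-crossing, (b) at least two consecutive
#' samples sit at/above the threshold after it, and (c) the profile never
#' returns below the threshold after that sustained crossing. Transient
#' spikes before the sustained rise are ignored for DLMO but fail rule (c)
#' only if the final rise itself is unsustained.
#'
#' @param times Strictly increasing sampling times (monotone evening hours).
#' @param concentrations Melatonin values, pg/mL.
#' @param threshold Onset threshold, pg/mL (see [calibrate_threshold()]).
#' @return List with `qc_pass` (logical) and `qc_reason` (`"ok"`,
#'   `"insufficient_samples"`, `"onset_before_sampling"`, `"no_crossing"`, or
#'   `"unsustained_crossing"`).
#' @export
qc_profile <- function(times, concentrations, threshold) {
  res <- function(pass, reason) list(qc_pass = pass, qc_reason = reason)
  n <- length(concentrations)
  if (n < 4) return(res(FALSE, "insufficient_samples"))
  if (length(times) != n || any(diff(times) <= 0)) {
    abort("`times` must be strictly increasing and match `concentrations`.")
  }
  if (all(concentrations < threshold)) return(res(FALSE, "no_crossing"))
  if (concentrations[1] >= threshold) {
    return(res(FALSE, "onset_before_sampling"))
  }
  j <- sustained_crossing(concentrations, threshold)
  if (is.na(j) || j > n - 1) return(res(FALSE, "unsustained_crossing"))
  res(TRUE, "ok")
}

#' Dim-light melatonin onset by linear interpolation
#'
#' DLMO is the time the profile crosses the threshold at its sustained rise:
#' linear interpolation between the last sub-threshold sample preceding the
#' sustained crossing and the first sample at/above threshold,
#' `t0 + (threshold - c0) * (t1 - t0) / (c1 - c0)`. A sample exactly at
#' threshold is its own onset time. Profiles should pass [qc_profile()] first;
#' the same rules are re-checked here and violations raise errors.
#'
#' @inheritParams qc_profile
#' @return Onset time on the input time axis (monotone evening hours).
#' @examples
#' compute_dlmo(c(19, 20, 21, 22), c(2, 6, 10, 14), threshold = 4) # 19.5
#' @export
compute_dlmo <- function(times, concentrations, threshold) {
  n <- length(concentrations)
  if (length(times) != n || n < 2 || any(diff(times) <= 0)) {
    abort("`times` must be strictly increasing and match `concentrations`.")
  }
  if (concentrations[1] >= threshold) {
    abort("First sample already at/above threshold.",
          class = "circphen_onset_before_sampling")
  }
  j <- sustained_crossing(concentrations, threshold)
  if (is.na(j)) {
    abort("Profile never sustainably crosses the threshold.",
          class = "circphen_no_crossing")
  }
  t0 <- times[j - 1]; c0 <- concentrations[j - 1]
  t1 <- times[j]; c1 <- concentrations[j]
  t0 + (threshold - c0) * (t1 - t0) / (c1 - c0)
}

#' Closed-form DLMO of a noise-free generated profile
#'
#' Under the piecewise-linear melatonin generator, plasma leaves its baseline
#' at `dlmo_base - delta` and the threshold equivalent to `plasma_equivalent`
#' pg/mL is crossed `(plasma_equivalent - baseline)/rise_rate` hours later.
#' This is the generator's ground truth against which interpolated estimates
#' are compared.
#'
#' @param config A [cohort_config()].
#' @param delta Phase offset(s), hours (positive = advanced).
#' @param plasma_equivalent Reference plasma concentration, pg/mL.
#' @return Onset time(s), monotone evening hours.
#' @export
dlmo_truth <- function(config, delta, plasma_equivalent = 10) {
  config$dlmo_base - delta +
    (plasma_equivalent - config$melatonin_baseline) /
      config$melatonin_rise_rate
}

#' Per-subject DLMO from a long melatonin table
#'
#' Calibrates a cohort-wide saliva threshold from concurrent saliva/plasma
#' pairs at `pair_time`, QCs every subject's saliva profile, and interpolates
#' DLMO for the passing ones.
#'
#' @param melatonin Long tibble: `subject_id`, `medium`
#'   (`"saliva"`/`"plasma"`), `time` (monotone evening hours), `pg_ml`.
#' @param plasma_equivalent Reference plasma concentration, pg/mL.
#' @param pair_time Clock hour of the concurrent plasma draw used for
#'   calibration (the study's evening venipuncture, ~20:00).
#' @return Tibble: `subject_id`, `threshold`, `dlmo_time` (monotone evening
#'   hours; NA when QC fails), `qc_pass`, `qc_reason`.
#' @export
dlmo_table <- function(melatonin, plasma_equivalent = 10, pair_time = 20) {
  pairs <- melatonin |>
    dplyr::filter(abs(.data$time - pair_time) < 1e-8) |>
    tidyr::pivot_wider(id_cols = "subject_id", names_from = "medium",
                       values_from = "pg_ml")
  threshold <- calibrate_threshold(pairs, plasma_equivalent)
  melatonin |>
    dplyr::filter(.data$medium == "saliva") |>
    dplyr::arrange(.data$subject_id, .data$time) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_modify(function(df, key) {
      qc <- qc_profile(df$time, df$pg_ml, threshold)
      tibble::tibble(
        threshold = threshold,
        dlmo_time = if (qc$qc_pass) {
          compute_dlmo(df$time, df$pg_ml, threshold)
        } else NA_real_,
        qc_pass = qc$qc_pass,
        qc_reason = qc$qc_reason
      )
    }) |>
    dplyr::ungroup()
}
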