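#' Cohort generator configuration
#'
#' Builds and validates the full parameter set for [generate_cohort()]. The
#' defaults emulate the validation study's protocol: 40 older adults with a
#' morning-weighted chronotype mix, blood expression sampled at ~20:00 and
#' ~10:00 the next morning, hourly evening saliva sampling from 18:00 until
#' bedtime with a paired plasma draw, and 7 days of 1-minute wrist actigraphy
#' with a sleep diary.
#'
#' All modalities share one latent per-subject phase offset `delta` (hours;
#' positive = advanced internal phase). Advanced subjects peak earlier in
#' expression, cross their melatonin threshold earlier, go to bed and wake
#' earlier, and score higher on the MEQ.
#'
#' @param n_subjects Number of subjects (0 allowed; gives an empty cohort).
#' @param chronotype_probs Named sampling probabilities for the latent
#'   chronotype strata `morning`, `intermediate`, `evening`; must sum to 1.
#' @param phase_offset_mean_by_type Named mean phase offset (hours) per
#'   stratum.
#' @param phase_offset_sd Within-stratum SD of the phase offset (hours).
#' @param n_genes Size of the rhythmic gene panel.
#' @param gene_amplitude_mean,gene_amplitude_sd Mean and SD of per-gene cosinor
#'   amplitudes (expression units; amplitudes truncated below at
#'   `0.2 * gene_amplitude_mean`).
#' @param gene_mesor_mean,gene_mesor_sd Per-gene mesor (rhythm-adjusted mean)
#'   distribution, log-scale expression units.
#' @param gene_noise_sd SD of i.i.d. Gaussian measurement noise added to every
#'   expression value.
#' @param expression_design `"fixed"` samples every subject at
#'   `expression_times`; `"rotating"` samples each subject at a uniformly
#'   random start time plus `rotating_gap` hours -- the design used for clock
#'   training cohorts, where time-of-day coverage is required.
#' @param expression_times Two sampling times on a monotone session axis
#'   (hours; values > 24 are the next morning). Default `c(20, 34)` is the
#'   study protocol: 20:00 then 10:00 the next day.
#' @param rotating_gap Spacing (hours) between the two samples under the
#'   rotating design. 12 h makes the two within-subject-centered samples carry
#'   independent phase information (see the package vignette).
#' @param melatonin_baseline Pre-onset plasma melatonin level, pg/mL.
#' @param melatonin_rise_rate Post-onset plasma rise, pg/mL per hour.
#' @param saliva_plasma_ratio_true True saliva:plasma concentration ratio.
#' @param melatonin_noise_sd SD of saliva assay noise, pg/mL (values truncated
#'   at 0).
#' @param melatonin_start First evening saliva sample, clock hours.
#' @param dlmo_base Evening hour at which plasma melatonin leaves baseline for
#'   a subject with `delta = 0` (monotone evening hours); a subject's rise
#'   starts at `dlmo_base - delta`. The operational DLMO -- the crossing of
#'   the plasma-10-pg/mL-equivalent threshold -- then falls at
#'   `dlmo_base - delta + (10 - melatonin_baseline)/melatonin_rise_rate`
#'   (see [dlmo_truth()]), about two hours before bedtime under the defaults.
#' @param bedtime_base,waketime_base Diary bedtime / waketime for `delta = 0`,
#'   monotone hours (bedtime may exceed 24 = past midnight). Shifted by
#'   `-delta` per subject.
#' @param activity_day_level,activity_night_level Mean activity counts per
#'   epoch while awake / at rest.
#' @param activity_day_noise_sd,activity_night_noise_sd Gaussian noise SDs for
#'   wake and rest epochs (counts truncated at 0).
#' @param fragmentation Rest-activity fragmentation in `[0, 1]`: each epoch
#'   independently switches to the opposite behavioural state with probability
#'   `0.2 * fragmentation`.
#' @param n_days Days of actigraphy recording.
#' @param epoch_minutes Actigraphy epoch length; must divide 60.
#' @param meq_center MEQ score of a subject with `delta = 0`.
#' @param meq_slope MEQ points per hour of phase advance.
#' @param meq_noise_sd SD of MEQ measurement noise (score points).
#' @param age_mean,age_sd,age_min Age distribution (years), truncated below.
#' @param prob_female Probability a subject is coded female.
#' @param seed Integer seed; identical configs generate bit-identical cohorts.
#'
#' @return A validated list of class `cohort_config`.
#' @seealso [generate_cohort()], [read_cohort_config()]
#' @export
cohort_config <- function(n_subjects = 40,
                          chronotype_probs = c(morning = 0.7,
                                               intermediate = 0.3,
                                               evening = 0),
                          phase_offset_mean_by_type = c(morning = 2.7,
                                                        intermediate = 0.5,
                                                        evening = -1.5),
                          phase_offset_sd = 1.5,
                          n_genes = 40,
                          gene_amplitude_mean = 1,
                          gene_amplitude_sd = 0.2,
                          gene_mesor_mean = 7,
                          gene_mesor_sd = 1,
                          gene_noise_sd = 0.5,
                          expression_design = c("fixed", "rotating"),
                          expression_times = c(20, 34),
                          rotating_gap = 12,
                          melatonin_baseline = 2,
                          melatonin_rise_rate = 8,
                          saliva_plasma_ratio_true = 0.3,
                          melatonin_noise_sd = 0.5,
                          melatonin_start = 18,
                          dlmo_base = 21.6,
                          bedtime_base = 24.8,
                          waketime_base = 9.1,
                          activity_day_level = 300,
                          activity_night_level = 15,
                          activity_day_noise_sd = 60,
                          activity_night_noise_sd = 25,
                          fragmentation = 0.15,
                          n_days = 7,
                          epoch_minutes = 1,
                          meq_center = 53,
                          meq_slope = 5,
                          meq_noise_sd = 3.5,
                          age_mean = 71.2,
                          age_sd = 4.2,
                          age_min = 65,
                          prob_female = 0.53,
                          seed = 1L) {
  config <- list(
    n_subjects = n_subjects,
    chronotype_probs = chronotype_probs,
    phase_offset_mean_by_type = phase_offset_mean_by_type,
    phase_offset_sd = phase_offset_sd,
    n_genes = n_genes,
    gene_amplitude_mean = gene_amplitude_mean,
    gene_amplitude_sd = gene_amplitude_sd,
    gene_mesor_mean = gene_mesor_mean,
    gene_mesor_sd = gene_mesor_sd,
    gene_noise_sd = gene_noise_sd,
    expression_design = match.arg(expression_design),
    expression_times = expression_times,
    rotating_gap = rotating_gap,
    melatonin_baseline = melatonin_baseline,
    melatonin_rise_rate = melatonin_rise_rate,
    saliva_plasma_ratio_true = saliva_plasma_ratio_true,
    melatonin_noise_sd = melatonin_noise_sd,
    melatonin_start = melatonin_start,
    dlmo_base = dlmo_base,
    bedtime_base = bedtime_base,
    waketime_base = waketime_base,
    activity_day_level = activity_day_level,
    activity_night_level = activity_night_level,
    activity_day_noise_sd = activity_day_noise_sd,
    activity_night_noise_sd = activity_night_noise_sd,
    fragmentation = fragmentation,
    n_days = n_days,
    epoch_minutes = epoch_minutes,
    meq_center = meq_center,
    meq_slope = meq_slope,
    meq_noise_sd = meq_noise_sd,
    age_mean = age_mean,
    age_sd = age_sd,
    age_min = age_min,
    prob_female = prob_female,
    seed = as.integer(seed)
  )
  validate_cohort_config(config)
}

config_error <- function(field, why) {
  abort(sprintf("Invalid cohort configuration: `%s` %s.", field, why),
        class = "circphen_config_error")
}

validate_cohort_config <- function(config) {
  num1 <- function(field, positive = FALSE, nonneg = FALSE) {
    x <- config[[field]]
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
      config_error(field, "must be a single finite number")
    }
    if (positive && x <= 0) config_error(field, "must be positive")
    if (nonneg && x < 0) config_error(field, "must be nonnegative")
    invisible(x)
  }
  count1 <- function(field, min = 1) {
    x <- num1(field)
    if (x < min || x != round(x)) {
      config_error(field, sprintf("must be an integer >= %d", min))
    }
  }
  count1("n_subjects", min = 0)
  count1("n_genes", min = 1)
  count1("n_days", min = 1)
  count1("epoch_minutes", min = 1)
  if (60 %% config$epoch_minutes != 0) {
    config_error("epoch_minutes", "must divide 60")
  }
  for (f in c("phase_offset_sd", "gene_amplitude_sd", "gene_mesor_sd",
              "gene_noise_sd", "melatonin_noise_sd", "meq_noise_sd",
              "activity_day_noise_sd", "activity_night_noise_sd", "age_sd")) {
    num1(f, nonneg = TRUE)
  }
  for (f in c("gene_amplitude_mean", "melatonin_rise_rate",
              "saliva_plasma_ratio_true")) {
    num1(f, positive = TRUE)
  }
  for (f in c("melatonin_baseline", "activity_day_level",
              "activity_night_level")) {
    num1(f, nonneg = TRUE)
  }
  for (f in c("gene_mesor_mean", "melatonin_start", "dlmo_base",
              "bedtime_base", "waketime_base", "meq_center", "meq_slope",
              "age_mean", "age_min", "rotating_gap")) {
    num1(f)
  }
  frag <- num1("fragmentation")
  if (frag < 0 || frag > 1) config_error("fragmentation", "must lie in [0, 1]")
  pf <- num1("prob_female")
  if (pf < 0 || pf > 1) config_error("prob_female", "must lie in [0, 1]")
  strata <- c("morning", "intermediate", "evening")
  probs <- config$chronotype_probs
  if (!is.numeric(probs) || !setequal(names(probs), strata) ||
      any(probs < 0) || abs(sum(probs) - 1) > 1e-8) {
    config_error("chronotype_probs",
                 "must be nonnegative, named morning/intermediate/evening, and sum to 1")
  }
  means <- config$phase_offset_mean_by_type
  if (!is.numeric(means) || !setequal(names(means), strata) ||
      any(!is.finite(means))) {
    config_error("phase_offset_mean_by_type",
                 "must be finite and named morning/intermediate/evening")
  }
  et <- config$expression_times
  if (!is.numeric(et) || length(et) != 2 || any(!is.finite(et)) ||
      diff(et) <= 0) {
    config_error("expression_times",
                 "must be two increasing hours on the monotone session axis")
  }
  if (!is.integer(config$seed) || length(config$seed) != 1 ||
      is.na(config$seed)) {
    config_error("seed", "must be a single integer")
  }
  structure(config, class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  %d subjects, %d genes, %d day(s) of %g-min actigraphy, seed %d\n",
              x$n_subjects, x$n_genes, x$n_days, x$epoch_minutes, x$seed))
  cat(sprintf("  chronotype mix: %s\n",
              paste(sprintf("%s %.0f%%", names(x$chronotype_probs),
                            100 * x$chronotype_probs), collapse = ", ")))
  cat(sprintf("  expression: %s design at %s h, amplitude %.2g, noise sd %.2g\n",
              x$expression_design,
              paste(x$expression_times, collapse = "/"),
              x$gene_amplitude_mean, x$gene_noise_sd))
  invisible(x)
}

#' Read or write a cohort configuration file
#'
#' Configurations round-trip through YAML or JSON (chosen by file extension).
#' Fields absent from the file take the [cohort_config()] defaults; unknown
#' fields are an error so typos do not silently fall back to defaults.
#'
#' @param path File path ending in `.yaml`, `.yml`, or `.json`.
#' @return `read_cohort_config()` returns a validated `cohort_config`;
#'   `write_cohort_config()` invisibly returns `path`.
#' @export
read_cohort_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    abort(sprintf("Unsupported config format '%s' (use yaml or json).", ext))
  )
  known <- names(formals(cohort_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    config_error(unknown[1], "is not a recognised configuration field")
  }
  for (f in c("chronotype_probs", "phase_offset_mean_by_type")) {
    if (!is.null(raw[[f]])) raw[[f]] <- unlist(raw[[f]])
  }
  do.call(cohort_config, raw)
}

#' @param config A `cohort_config` object.
#' @rdname read_cohort_config
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  ext <- tolower(tools::file_ext(path))
  x <- unclass(config)
  x$expression_design <- unname(x$expression_design)
  # named vectors must become mappings, not bare arrays, in both formats
  x <- lapply(x, function(v) if (!is.null(names(v))) as.list(v) else v)
  switch(ext,
    yaml = ,
    yml = yaml::write_yaml(x, path),
    json = jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE),
    abort(sprintf("Unsupported config format '%s' (use yaml or json).", ext))
  )
  invisible(path)
}
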