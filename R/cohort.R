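#' Draw a rhythmic gene panel
#'
#' Samples per-gene cosinor parameters for a synthetic expression panel: mesor
#' (rhythm-adjusted mean), peak-to-mesor amplitude, and acrophase (clock hour
#' of peak for a subject with zero phase offset). Acrophases are uniform over
#' the day so the panel tiles the circadian cycle. Consumes the current RNG
#' stream.
#'
#' @param config A [cohort_config()].
#' @return Tibble with columns `gene_id`, `mesor`, `amplitude`, `acrophase`.
#' @export
draw_gene_panel <- function(config) {
  n <- config$n_genes
  tibble::tibble(
    gene_id = sprintf("g%03d", seq_len(n)),
    mesor = rnorm(n, config$gene_mesor_mean, config$gene_mesor_sd),
    amplitude = pmax(0.2 * config$gene_amplitude_mean,
                     rnorm(n, config$gene_amplitude_mean,
                           config$gene_amplitude_sd)),
    acrophase = runif(n, 0, 24)
  )
}

#' Simulate blood expression samples for one subject
#'
#' Each gene follows a cosinor curve in the subject's internal time:
#' `x_g(t) = mesor_g + amplitude_g * cos(2*pi*(t - (acrophase_g - delta))/24)`
#' plus i.i.d. Gaussian noise. A positive phase offset `delta` advances the
#' subject: every gene peaks `delta` hours earlier in clock time. Noise-free
#' output equals the cosinor curve exactly. Consumes the current RNG stream.
#'
#' @param subject One-row tibble with at least `subject_id` and
#'   `phase_offset_delta`.
#' @param times Sampling times on the monotone session axis (hours; values
#'   >= 24 fall on the next day).
#' @param config A [cohort_config()].
#' @param panel Gene panel from [draw_gene_panel()]; drawn fresh from the
#'   config seed when omitted.
#' @return Long tibble: `subject_id`, `sample_id`, `session` (`"AM"` for clock
#'   hours before noon, else `"PM"`), `time` (monotone), `clock_time`
#'   (`time %% 24`), `gene_id`, `value`.
#' @export
simulate_expression <- function(subject, times, config, panel = NULL) {
  if (is.null(panel)) {
    panel <- withr::with_seed(config$seed, draw_gene_panel(config))
  }
  delta <- subject$phase_offset_delta
  purrr::imap(times, function(t, i) {
    clean <- panel$mesor + panel$amplitude *
      cos(2 * pi * (t - (panel$acrophase - delta)) / 24)
    tibble::tibble(
      subject_id = subject$subject_id,
      sample_id = sprintf("%s_T%d", subject$subject_id, i),
      session = ifelse((t %% 24) < 12, "AM", "PM"),
      time = t,
      clock_time = t %% 24,
      gene_id = panel$gene_id,
      value = clean + rnorm(nrow(panel), 0, config$gene_noise_sd)
    )
  }) |>
    purrr::list_rbind()
}

#' Simulate an evening saliva/plasma melatonin profile
#'
#' Plasma follows a piecewise-linear "hockey stick": flat at
#' `melatonin_baseline` until the subject's onset `dlmo_base - delta`, then
#' rising at `melatonin_rise_rate` pg/mL/h. Saliva is
#' `saliva_plasma_ratio_true * plasma` plus assay noise truncated at zero;
#' plasma is reported noise-free (the reference assay). Consumes the current
#' RNG stream.
#'
#' @inheritParams simulate_expression
#' @param sampling_times Monotone evening hours (may pass midnight, e.g. 24.5
#'   = 00:30), strictly increasing.
#' @return Long tibble: `subject_id`, `medium` (`"saliva"`/`"plasma"`),
#'   `time`, `pg_ml`.
#' @export
simulate_melatonin <- function(subject, sampling_times, config) {
  if (any(diff(sampling_times) <= 0)) {
    abort("`sampling_times` must be strictly increasing.")
  }
  dlmo_s <- config$dlmo_base - subject$phase_offset_delta
  plasma <- config$melatonin_baseline +
    config$melatonin_rise_rate * pmax(0, sampling_times - dlmo_s)
  saliva <- pmax(0, config$saliva_plasma_ratio_true * plasma +
                   rnorm(length(plasma), 0, config$melatonin_noise_sd))
  dplyr::bind_rows(
    tibble::tibble(subject_id = subject$subject_id, medium = "saliva",
                   time = sampling_times, pg_ml = saliva),
    tibble::tibble(subject_id = subject$subject_id, medium = "plasma",
                   time = sampling_times, pg_ml = plasma)
  )
}

#' Simulate multi-day wrist actigraphy with diary rest intervals
#'
#' A two-level square-wave schedule: counts near `activity_day_level` while
#' awake (between the subject's waketime and bedtime, both advanced by the
#' phase offset) and near `activity_night_level` during rest, with Gaussian
#' noise truncated at zero. Each epoch independently switches to the opposite
#' behavioural state with probability `0.2 * fragmentation`, emulating brief
#' nocturnal arousals and daytime naps. Diary rest intervals cover the
#' complete nights inside the recording span. Consumes the current RNG stream.
#'
#' @inheritParams simulate_expression
#' @return List with `epochs` (tibble: `subject_id`, `time` hours since
#'   recording start at midnight of day 1, `counts`) and `rest_intervals`
#'   (tibble: `subject_id`, `night`, `bedtime`, `waketime`, absolute hours).
#' @export
simulate_activity <- function(subject, config) {
  delta <- subject$phase_offset_delta
  waketime_s <- config$waketime_base - delta
  bedtime_s <- config$bedtime_base - delta
  ep_h <- config$epoch_minutes / 60
  times <- seq(0, config$n_days * 24 - ep_h, by = ep_h)
  wake_span <- (bedtime_s - waketime_s) %% 24
  awake <- ((times %% 24) - waketime_s) %% 24 < wake_span
  flip <- runif(length(times)) < 0.2 * config$fragmentation
  state <- xor(awake, flip)
  level <- ifelse(state, config$activity_day_level,
                  config$activity_night_level)
  noise_sd <- ifelse(state, config$activity_day_noise_sd,
                     config$activity_night_noise_sd)
  counts <- pmax(0, level + rnorm(length(times), 0, noise_sd))
  nights <- seq_len(max(config$n_days - 1, 0))
  list(
    epochs = tibble::tibble(subject_id = subject$subject_id,
                            time = times, counts = counts),
    rest_intervals = tibble::tibble(
      subject_id = subject$subject_id,
      night = nights,
      bedtime = (nights - 1) * 24 + bedtime_s,
      waketime = nights * 24 + waketime_s
    )
  )
}

#' MEQ score and chronotype label from a latent phase offset
#'
#' The Morningness-Eveningness Questionnaire score is generated as
#' `round(meq_center + meq_slope * delta + noise)`, clipped to the
#' instrument's range 16-86, so phase-advanced subjects score higher.
#' Labels use the conventional Horne-Ostberg bands; the study's printed
#' ranges leave 59 and 41 unassigned, and those boundaries are mapped to
#' morning and evening respectively. Consumes the current RNG stream.
#'
#' @param phase_offset_delta Numeric vector of latent phase offsets (hours,
#'   positive = advanced).
#' @param config A [cohort_config()].
#' @return Tibble with `meq_score` (integer) and `chronotype_label`
#'   (`"morning"` >= 59, `"evening"` <= 41, otherwise `"intermediate"`).
#' @export
assign_meq <- function(phase_offset_delta, config) {
  raw <- config$meq_center + config$meq_slope * phase_offset_delta +
    rnorm(length(phase_offset_delta), 0, config$meq_noise_sd)
  score <- as.integer(pmin(86, pmax(16, round(raw))))
  tibble::tibble(meq_score = score, chronotype_label = meq_chronotype(score))
}

#' @param meq_score Integer MEQ scores.
#' @rdname assign_meq
#' @export
meq_chronotype <- function(meq_score) {
  dplyr::case_when(
    meq_score >= 59 ~ "morning",
    meq_score <= 41 ~ "evening",
    .default = "intermediate"
  )
}

#' Generate a seeded multimodal synthetic cohort
#'
#' Draws a gene panel and, for every subject, a latent chronotype stratum and
#' phase offset, demographics, an MEQ score, two-timepoint blood expression,
#' an evening saliva/plasma melatonin profile (hourly from `melatonin_start`
#' until the subject's bedtime), and `n_days` of wrist actigraphy. All
#' modalities are driven by the subject's single latent `phase_offset_delta`.
#'
#' Randomness uses one sub-stream per subject per modality, seeded by a stable
#' hash of the subject id, so regenerating with a larger `n_subjects` leaves
#' earlier subjects bit-identical.
#'
#' @param config A [cohort_config()].
#' @param panel Gene panel tibble from [draw_gene_panel()]. The panel encodes
#'   gene biology (acrophases, amplitudes), which is common across cohorts of
#'   people: pass the same panel when generating training and test cohorts for
#'   the same clock. Defaults to a panel drawn from `config$seed`.
#' @return A `circ_cohort` list: `subjects`, `panel`, `expression`,
#'   `melatonin`, `activity` (with `epochs` and `rest_intervals`), `config`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_subjects = 3, n_days = 2))
#' cohort$subjects
#' @export
generate_cohort <- function(config, panel = NULL) {
  config <- validate_cohort_config(config)
  if (is.null(panel)) {
    panel <- withr::with_seed(config$seed, draw_gene_panel(config))
  }
  stopifnot(is.data.frame(panel), nrow(panel) == config$n_genes)
  strata <- c("morning", "intermediate", "evening")
  cum_probs <- cumsum(config$chronotype_probs[strata])

  subject_ids <- sprintf("S%03d", seq_len(config$n_subjects))
  rows <- purrr::map(subject_ids, function(id) {
    withr::with_seed(subject_seed(config$seed, id, stream = 0L), {
      stratum <- strata[1 + findInterval(runif(1), cum_probs,
                                         left.open = TRUE)]
      delta <- rnorm(1, config$phase_offset_mean_by_type[[stratum]],
                     config$phase_offset_sd)
      age <- max(config$age_min, rnorm(1, config$age_mean, config$age_sd))
      sex <- ifelse(runif(1) < config$prob_female, "female", "male")
      meq <- assign_meq(delta, config)
      profile <- tibble::tibble(subject_id = id, age = age, sex = sex,
                                phase_offset_delta = delta,
                                meq_score = meq$meq_score,
                                chronotype_label = meq$chronotype_label)
    })
    expr_times <- if (config$expression_design == "rotating") {
      withr::with_seed(subject_seed(config$seed, id, stream = 4L),
                       runif(1, 0, 24)) + c(0, config$rotating_gap)
    } else {
      config$expression_times
    }
    expr <- withr::with_seed(
      subject_seed(config$seed, id, stream = 1L),
      simulate_expression(profile, expr_times, config, panel)
    )
    bedtime_s <- config$bedtime_base - profile$phase_offset_delta
    # hourly sampling from the protocol start until bedtime; extreme phase
    # advances still get the minimal 4-sample evening series
    mel_times <- seq(config$melatonin_start,
                     max(bedtime_s, config$melatonin_start + 3), by = 1)
    mel <- withr::with_seed(
      subject_seed(config$seed, id, stream = 2L),
      simulate_melatonin(profile, mel_times, config)
    )
    act <- withr::with_seed(
      subject_seed(config$seed, id, stream = 3L),
      simulate_activity(profile, config)
    )
    list(profile = profile, expression = expr, melatonin = mel,
         epochs = act$epochs, rest_intervals = act$rest_intervals)
  })

  structure(list(
    subjects = if (length(rows)) purrr::list_rbind(purrr::map(rows, "profile"))
               else tibble::tibble(subject_id = character(), age = numeric(),
                                   sex = character(),
                                   phase_offset_delta = numeric(),
                                   meq_score = integer(),
                                   chronotype_label = character()),
    panel = panel,
    expression = purrr::list_rbind(purrr::map(rows, "expression")),
    melatonin = purrr::list_rbind(purrr::map(rows, "melatonin")),
    activity = list(
      epochs = purrr::list_rbind(purrr::map(rows, "epochs")),
      rest_intervals = purrr::list_rbind(purrr::map(rows, "rest_intervals"))
    ),
    config = config
  ), class = "circ_cohort")
}

#' @export
print.circ_cohort <- function(x, ...) {
  cat("<circ_cohort>\n")
  cat(sprintf("  %d subjects | %d genes x %d expression samples | %d melatonin rows | %s activity epochs\n",
              nrow(x$subjects), nrow(x$panel),
              dplyr::n_distinct(x$expression$sample_id),
              nrow(x$melatonin),
              format(nrow(x$activity$epochs), big.mark = ",")))
  if (nrow(x$subjects) > 0) {
    tab <- table(x$subjects$chronotype_label)
    cat(sprintf("  chronotypes: %s\n",
                paste(names(tab), tab, sep = " = ", collapse = ", ")))
  }
  invisible(x)
}
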