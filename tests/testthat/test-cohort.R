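test_that("configuration validation names the offending field", {
  expect_error(cohort_config(n_subjects = -1), "n_subjects",
               class = "circphen_config_error")
  expect_error(cohort_config(fragmentation = 1.5), "fragmentation",
               class = "circphen_config_error")
  expect_error(cohort_config(epoch_minutes = 7), "epoch_minutes",
               class = "circphen_config_error")
  expect_error(cohort_config(chronotype_probs = c(morning = 1)),
               "chronotype_probs", class = "circphen_config_error")
  expect_error(cohort_config(gene_noise_sd = -0.1), "gene_noise_sd",
               class = "circphen_config_error")
})

test_that("config files round-trip through yaml and json", {
  cfg <- quick_config(fragmentation = 0.4)
  for (ext in c("yaml", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_cohort_config(cfg, path)
    back <- read_cohort_config(path)
    expect_equal(unclass(back), unclass(cfg), tolerance = 1e-12)
  }
  bad <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(n_subjectz = 4), bad)
  expect_error(read_cohort_config(bad), "n_subjectz",
               class = "circphen_config_error")
})

test_that("generate_cohort is deterministic and respects n_subjects", {
  cfg <- quick_config()
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$expression, b$expression)
  expect_identical(a$melatonin, b$melatonin)
  expect_identical(a$activity, b$activity)
  expect_equal(nrow(a$subjects), 6)
  expect_equal(dplyr::n_distinct(a$expression$sample_id), 12) # 2 per subject

  empty <- generate_cohort(cohort_config(n_subjects = 0))
  expect_equal(nrow(empty$subjects), 0)
})

test_that("growing the cohort leaves earlier subjects untouched", {
  small <- generate_cohort(quick_config())
  big <- generate_cohort(quick_config(n_subjects = 9))
  expect_identical(small$subjects,
                   big$subjects[seq_len(6), ])
  expect_identical(small$melatonin,
                   dplyr::semi_join(big$melatonin, small$subjects,
                                    by = "subject_id"))
})

test_that("default cohort emulates the study's chronotype mix", {
  cohort <- generate_cohort(cohort_config())
  expect_equal(nrow(cohort$subjects), 40)
  tab <- table(cohort$subjects$chronotype_label)
  # study cohort: 28 morning, 12 intermediate, no evening types
  expect_gt(tab[["morning"]], 20)
  expect_lt(tab[["morning"]], 36)
  expect_true(all(cohort$subjects$meq_score >= 16 &
                    cohort$subjects$meq_score <= 86))
})

test_that("noise-free expression equals the cosinor curve pointwise", {
  cfg <- quick_config(gene_noise_sd = 0)
  panel <- withr::with_seed(1, draw_gene_panel(cfg))

  # amplitude zero: every value is the mesor
  flat <- panel |> dplyr::mutate(amplitude = 0)
  s <- simulate_expression(one_subject(0), c(20, 34), cfg, panel = flat)
  expect_equal(s$value, rep(flat$mesor, 2), tolerance = 1e-12)

  # cosine maximum: mesor 0, amplitude 1, sampled at the acrophase
  unit <- panel |> dplyr::mutate(mesor = 0, amplitude = 1)
  s1 <- simulate_expression(one_subject(0), unit$acrophase[1], cfg,
                            panel = unit)
  expect_equal(s1$value[1], 1, tolerance = 1e-12)

  # advanced subject peaks earlier: delta = +2 moves the peak to acrophase - 2
  s2 <- simulate_expression(one_subject(2),
                            (unit$acrophase[1] - 2) %% 24, cfg, panel = unit)
  expect_equal(s2$value[1], 1, tolerance = 1e-12)
})

test_that("noise-free melatonin is the closed-form hockey stick", {
  cfg <- quick_config(melatonin_noise_sd = 0, melatonin_baseline = 2,
                      melatonin_rise_rate = 8, saliva_plasma_ratio_true = 0.3)
  subj <- one_subject(0)
  dlmo_s <- cfg$dlmo_base
  times <- seq(18, 26, by = 0.5)
  mel <- simulate_melatonin(subj, times, cfg)
  plasma <- dplyr::filter(mel, medium == "plasma")
  saliva <- dplyr::filter(mel, medium == "saliva")

  # piecewise-linear arithmetic: baseline + rise * time-above-onset
  expect_equal(plasma$pg_ml, 2 + 8 * pmax(0, times - dlmo_s),
               tolerance = 1e-12)
  # constant ratio when noise-free
  expect_equal(saliva$pg_ml, 0.3 * plasma$pg_ml, tolerance = 1e-12)

  # round trip: threshold baseline + k recovers onset + k/rise exactly
  for (k in c(4, 8, 14)) {
    est <- compute_dlmo(plasma$time, plasma$pg_ml, threshold = 2 + k)
    expect_equal(est, dlmo_s + k / 8, tolerance = 1e-12)
  }
})

test_that("noiseless activity is a square wave and perfectly stable", {
  cfg <- quick_config(activity_day_noise_sd = 0, activity_night_noise_sd = 0,
                      fragmentation = 0, activity_day_level = 300,
                      activity_night_level = 0, waketime_base = 7,
                      bedtime_base = 23, n_days = 3)
  act <- simulate_activity(one_subject(0), cfg)
  h <- act$epochs$time %% 24
  awake <- h >= 7 & h < 23
  expect_true(all(act$epochs$counts[awake] == 300))
  expect_true(all(act$epochs$counts[!awake] == 0))
  expect_equal(interdaily_stability(act$epochs), 1, tolerance = 1e-12)
  # diary intervals: complete nights inside the recording
  expect_equal(nrow(act$rest_intervals), 2)
  expect_true(all(act$rest_intervals$bedtime >= 0 &
                    act$rest_intervals$waketime <= 72))
})

test_that("intradaily variability grows with fragmentation", {
  cfg0 <- quick_config(n_days = 3)
  mean_iv <- vapply(c(0, 0.5, 1), function(frag) {
    cfg <- quick_config(n_days = 3, fragmentation = frag)
    ivs <- vapply(1:20, function(s) {
      ep <- withr::with_seed(1000 + s,
                             simulate_activity(one_subject(0), cfg))$epochs
      intradaily_variability(ep)
    }, numeric(1))
    mean(ivs)
  }, numeric(1))
  expect_true(all(diff(mean_iv) > 0))
})

test_that("MEQ scoring follows the chronotype bands and clips", {
  expect_equal(meq_chronotype(c(64, 52, 59, 41, 30)),
               c("morning", "intermediate", "morning", "evening", "evening"))
  cfg <- quick_config(meq_noise_sd = 0, meq_center = 53, meq_slope = 5)
  res <- assign_meq(c(0, 2.2, -2.4, 40), cfg)
  expect_equal(res$meq_score, c(53L, 64L, 41L, 86L)) # last clipped at 86
  expect_equal(res$chronotype_label,
               c("intermediate", "morning", "evening", "morning"))
})

test_that("latent phase offset drives all modalities coherently", {
  cohort <- generate_cohort(cohort_config(n_subjects = 200, n_days = 2,
                                          seed = 99L))
  subj <- cohort$subjects
  expect_gt(cor(subj$phase_offset_delta, subj$meq_score), 0)
  # earlier melatonin onset and bedtime for advanced subjects
  dlmo <- dlmo_truth(cohort$config, subj$phase_offset_delta)
  expect_lt(cor(subj$phase_offset_delta, dlmo), 0)
  beds <- cohort$activity$rest_intervals |>
    dplyr::summarise(bed = mean(unwrap_hours(bedtime %% 24, 24)),
                     .by = subject_id)
  expect_lt(cor(subj$phase_offset_delta,
                beds$bed[match(subj$subject_id, beds$subject_id)]), 0)
})

test_that("cohort interchange files round-trip", {
  cohort <- generate_cohort(quick_config(n_days = 2))
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  expect_setequal(list.files(dir),
                  c("expression.tsv", "samples.csv", "melatonin.csv",
                    "activity_epochs.csv", "rest_intervals.csv",
                    "subjects.csv"))
  expr <- read_expression(file.path(dir, "expression.tsv"),
                          file.path(dir, "samples.csv"))
  orig <- dplyr::arrange(cohort$expression, sample_id, gene_id)
  back <- dplyr::arrange(expr, sample_id, gene_id)
  expect_equal(back$value, orig$value, tolerance = 1e-9)
  expect_equal(back$clock_time, orig$clock_time, tolerance = 1e-9)

  act <- read_activity(file.path(dir, "activity_epochs.csv"),
                       file.path(dir, "rest_intervals.csv"))
  expect_equal(act$epochs$time, cohort$activity$epochs$time,
               tolerance = 1e-6)
  expect_equal(act$epochs$counts, cohort$activity$epochs$counts,
               tolerance = 1e-6)
  mel <- read_melatonin(file.path(dir, "melatonin.csv"))
  expect_equal(mel$pg_ml, cohort$melatonin$pg_ml, tolerance = 1e-9)
})
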