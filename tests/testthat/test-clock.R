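make_expr <- function(values_by_sample, subject_id = "S001",
                      clock_times = NULL) {
  purrr::imap(values_by_sample, function(v, i) {
    tibble::tibble(subject_id = subject_id,
                   sample_id = sprintf("%s_T%d", subject_id, i),
                   session = c("PM", "AM")[1 + (i %% 2)],
                   clock_time = if (is.null(clock_times)) 0
                                else clock_times[i],
                   gene_id = sprintf("g%02d", seq_along(v)),
                   value = v)
  }) |> purrr::list_rbind()
}

test_that("within-subject normalization centers, is idempotent and shift-invariant", {
  expr <- make_expr(list(c(5, 1), c(7, 3)))
  norm <- within_subject_normalize(expr)
  expect_equal(norm$value, c(-1, -1, 1, 1))

  expect_equal(within_subject_normalize(norm)$value, norm$value)

  shifted <- dplyr::mutate(expr, value = value + 100)
  expect_equal(within_subject_normalize(shifted)$value, norm$value)

  single <- make_expr(list(c(5, 1)))
  expect_warning(out <- within_subject_normalize(single),
                 "Single-sample")
  expect_equal(out$value, c(0, 0))
})

# analytic two-gene clock: c_hat = value of g01, s_hat = value of g02
analytic_clock <- function() {
  structure(list(gene_ids = c("g01", "g02"),
                 w_cos = c(g01 = 1, g02 = 0), w_sin = c(g01 = 0, g02 = 1),
                 b_cos = 0, b_sin = 0, ridge_penalty = 0,
                 training_meta = list()), class = "circ_clock")
}

test_that("predict_time inverts phase exactly for an analytic model", {
  model <- analytic_clock()
  for (t in c(0, 6, 20, 13.25)) {
    expr <- make_expr(list(c(cos(t * pi / 12), sin(t * pi / 12))))
    expect_equal(predict_time(model, expr)$transcriptomic_time, t,
                 tolerance = 1e-9)
  }
  # quadrant checks: (1, 0) -> 0 h, (0, 1) -> 6 h
  expect_equal(predict_time(model, make_expr(list(c(1, 0))))$
                 transcriptomic_time, 0)
  expect_equal(predict_time(model, make_expr(list(c(0, 1))))$
                 transcriptomic_time, 6)
})

test_that("predict_time errors on missing genes and undefined phase", {
  model <- analytic_clock()
  one_gene <- make_expr(list(1))
  expect_error(predict_time(model, one_gene), "g02",
               class = "circphen_missing_genes")
  expect_error(predict_time(model, make_expr(list(c(0, 0)))),
               class = "circphen_undefined_phase")
})

test_that("signed_angle wraps correctly and enforces its domain", {
  expect_equal(signed_angle(22, 20), 2)
  expect_equal(signed_angle(1, 23), 2)
  expect_equal(signed_angle(8, 20), -12) # antipodal tie-break
  expect_error(signed_angle(24, 0), class = "circphen_domain_error")
  expect_error(signed_angle(5, -1), class = "circphen_domain_error")

  # antisymmetry away from the -12 boundary; magnitude bound everywhere
  withr::with_seed(7, {
    a <- runif(300, 0, 24)
    b <- runif(300, 0, 24)
    s <- signed_angle(a, b)
    expect_true(all(s >= -12 & s < 12))
    off_boundary <- s > -12
    expect_equal(s[off_boundary], -signed_angle(b, a)[off_boundary],
                 tolerance = 1e-9)
  })
})

test_that("subject_angle averages AM and PM and flags single sessions", {
  pred <- tibble::tibble(subject_id = c("A", "A", "B"),
                         session = c("AM", "PM", "PM"),
                         angle = c(3, 1, 2))
  out <- subject_angle(pred)
  expect_equal(out$angle_mean[out$subject_id == "A"], 2)
  expect_false(out$single_session[out$subject_id == "A"])
  expect_true(out$single_session[out$subject_id == "B"])
  expect_equal(out$angle_mean[out$subject_id == "B"], 2)
  expect_error(subject_angle(pred[0, ]))

  zero <- subject_angle(tibble::tibble(subject_id = "A",
                                       session = c("AM", "PM"),
                                       angle = c(0, 0)))
  expect_equal(zero$angle_mean, 0)
})

test_that("accuracy curve matches closed forms and is sign-invariant", {
  perfect <- accuracy_curve(rep(0, 10))
  expect_true(all(perfect$curve$fraction_correct == 1))
  expect_equal(perfect$nauc, 1)

  expect_equal(accuracy_curve(6)$nauc, 0.5) # exact step-function area

  withr::with_seed(3, a <- runif(200, -12, 12))
  expect_equal(accuracy_curve(a)$nauc, accuracy_curve(-a)$nauc)
  cur <- accuracy_curve(a)$curve
  expect_true(all(diff(cur$fraction_correct) >= 0))
  expect_equal(cur$fraction_correct[cur$tolerance == 12], 1)

  expect_error(accuracy_curve(numeric(0)))
  expect_error(accuracy_curve(c(1, 2), grid_step = 0))
})

test_that("training is deterministic, needs variation, and honours the penalty limit", {
  cfg <- cohort_config(n_subjects = 12, n_genes = 20, gene_noise_sd = 0.3,
                       expression_design = "rotating",
                       phase_offset_mean_by_type = zero_mean_types,
                       seed = 31L)
  expr <- within_subject_normalize(generate_cohort(cfg)$expression)

  m1 <- train_clock(expr, ridge_penalty = 1)
  m2 <- train_clock(expr, ridge_penalty = 1)
  expect_identical(m1$w_cos, m2$w_cos)

  # degenerate design: every sample identical
  flat <- dplyr::mutate(expr, value = 0)
  expect_error(train_clock(flat, ridge_penalty = 0),
               class = "circphen_singular_error")

  # huge penalty collapses to the intercept angle (fixed 20:00/10:00 design,
  # whose mean cos/sin targets are nonzero)
  cfg_fix <- cohort_config(n_subjects = 12, n_genes = 20,
                           gene_noise_sd = 0.3,
                           phase_offset_mean_by_type = zero_mean_types,
                           seed = 31L)
  expr_fix <- within_subject_normalize(generate_cohort(cfg_fix)$expression)
  big <- train_clock(expr_fix, ridge_penalty = 1e9)
  expect_lt(max(abs(c(big$w_cos, big$w_sin))), 1e-6)
  pred <- predict_time(big, expr_fix)
  intercept_angle <- (atan2(big$b_sin, big$b_cos) * 12 / pi) %% 24
  expect_equal(pred$transcriptomic_time,
               rep(intercept_angle, nrow(pred)), tolerance = 1e-3)
})

test_that("gene order is irrelevant once ids are matched", {
  cfg <- cohort_config(n_subjects = 8, n_genes = 10, gene_noise_sd = 0.2,
                       expression_design = "rotating",
                       phase_offset_mean_by_type = zero_mean_types,
                       seed = 13L)
  expr <- within_subject_normalize(generate_cohort(cfg)$expression)
  shuffled <- withr::with_seed(5, dplyr::slice_sample(expr, prop = 1))
  m <- train_clock(expr, ridge_penalty = 1)
  m_shuf <- train_clock(shuffled, ridge_penalty = 1)
  expect_equal(predict_time(m, expr)$transcriptomic_time,
               predict_time(m_shuf, expr)$transcriptomic_time,
               tolerance = 1e-9)
})

test_that("a noiseless 12 h-spaced cohort trains to near-zero angular error", {
  cfg <- cohort_config(n_subjects = 24, n_genes = 40, gene_noise_sd = 0,
                       expression_design = "rotating", rotating_gap = 12,
                       phase_offset_sd = 0,
                       phase_offset_mean_by_type = zero_mean_types,
                       seed = 17L)
  expr <- within_subject_normalize(generate_cohort(cfg)$expression)
  model <- train_clock(expr, ridge_penalty = 0.01)
  expect_lt(model$training_meta$in_sample_mae, 0.5)

  # held-out noiseless subjects from the same panel predict within 1 h
  panel <- withr::with_seed(17L, draw_gene_panel(cfg))
  held <- generate_cohort(
    cohort_config(n_subjects = 6, n_genes = 40, gene_noise_sd = 0,
                  expression_design = "rotating", rotating_gap = 12,
                  phase_offset_sd = 0,
                  phase_offset_mean_by_type = zero_mean_types, seed = 18L),
    panel = panel)
  pred <- predict_time(model, within_subject_normalize(held$expression))
  err <- signed_angle(pred$transcriptomic_time, pred$clock_time)
  expect_true(all(abs(err) < 1))
})

test_that("AM/PM averaging cancels the two-sample midpoint offset", {
  # under the 14 h study protocol each sample lands ~1 h off (the centered
  # pair only resolves the midpoint phase) but the subject mean is clean
  cfg_train <- cohort_config(n_subjects = 30, n_genes = 40,
                             gene_noise_sd = 0, expression_design = "rotating",
                             rotating_gap = 12, phase_offset_sd = 0,
                             phase_offset_mean_by_type = zero_mean_types,
                             seed = 21L)
  panel <- withr::with_seed(21L, draw_gene_panel(cfg_train))
  model <- train_clock(
    within_subject_normalize(generate_cohort(cfg_train)$expression),
    ridge_penalty = 0.01)
  cfg_test <- cohort_config(n_subjects = 6, n_genes = 40, gene_noise_sd = 0,
                            expression_times = c(20, 34), phase_offset_sd = 0,
                            phase_offset_mean_by_type = zero_mean_types,
                            seed = 22L)
  pred <- predict_time(model,
                       within_subject_normalize(
                         generate_cohort(cfg_test, panel = panel)$expression))
  pred$angle <- signed_angle(pred$transcriptomic_time, pred$clock_time)
  means <- subject_angle(pred)
  expect_true(all(abs(means$angle_mean) < 0.5))
  # per-sample offsets are real and near +/- 1 h
  expect_gt(mean(abs(pred$angle)), 0.5)
})

test_that("clock models survive JSON serialization", {
  cfg <- cohort_config(n_subjects = 8, n_genes = 10, seed = 3L,
                       expression_design = "rotating",
                       phase_offset_mean_by_type = zero_mean_types)
  expr <- within_subject_normalize(generate_cohort(cfg)$expression)
  model <- train_clock(expr, ridge_penalty = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_clock_model(model, path)
  back <- read_clock_model(path)
  expect_equal(predict_time(back, expr)$transcriptomic_time,
               predict_time(model, expr)$transcriptomic_time,
               tolerance = 1e-12)
  expect_s3_class(tidy(model), "tbl_df")
  expect_equal(nrow(tidy(model)), 10)
  expect_equal(glance(model)$ridge_penalty, 1)
})
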