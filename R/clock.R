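#' Within-subject normalization of expression samples
#'
#' Centers every gene on the subject's own mean across that subject's samples,
#' removing inter-individual baseline differences so the clock sees only the
#' within-subject temporal signal. After normalization each subject's values
#' sum to zero per gene. The operation is idempotent and invariant to adding a
#' per-subject constant.
#'
#' Subjects contributing a single sample normalize to an all-zero vector and
#' trigger a warning: their prediction carries no temporal information.
#'
#' @param expr Long expression tibble with columns `subject_id`, `sample_id`,
#'   `gene_id`, `value` (as produced by [simulate_expression()] or
#'   [read_expression()]).
#' @return The same tibble with `value` centered within subject and gene.
#' @export
within_subject_normalize <- function(expr) {
  singles <- expr |>
    dplyr::distinct(.data$subject_id, .data$sample_id) |>
    dplyr::count(.data$subject_id) |>
    dplyr::filter(.data$n < 2)
  if (nrow(singles) > 0) {
    warn(sprintf(
      "Single-sample subject(s) normalize to zero; predictions unreliable: %s",
      paste(singles$subject_id, collapse = ", ")))
  }
  expr |>
    dplyr::mutate(value = .data$value - mean(.data$value),
                  .by = c("subject_id", "gene_id"))
}

# Closed-form ridge with unpenalized intercept (columns and target centered).
fit_ridge <- function(X, y, lambda) {
  xm <- colMeans(X)
  ym <- mean(y)
  Xc <- sweep(X, 2, xm)
  A <- crossprod(Xc)
  diag(A) <- diag(A) + lambda
  w <- tryCatch(
    drop(solve(A, crossprod(Xc, y - ym))),
    error = function(e) abort(paste0(
      "Degenerate training design (singular normal equations); ",
      "use ridge_penalty > 0."), class = "circphen_singular_error")
  )
  list(w = w, b = ym - sum(xm * w))
}

expr_to_matrix <- function(expr, gene_ids = NULL) {
  wide <- expr |>
    dplyr::select("sample_id", "gene_id", "value") |>
    tidyr::pivot_wider(names_from = "gene_id", values_from = "value")
  X <- as.matrix(wide[, -1, drop = FALSE])
  rownames(X) <- wide$sample_id
  if (!is.null(gene_ids)) {
    missing <- setdiff(gene_ids, colnames(X))
    if (length(missing) > 0) {
      abort(sprintf("Expression input lacks model gene(s): %s",
                    paste(missing, collapse = ", ")),
            class = "circphen_missing_genes")
    }
    X <- X[, gene_ids, drop = FALSE]
  }
  X
}

sample_meta <- function(expr) {
  expr |>
    dplyr::summarise(dplyr::across(dplyr::any_of(
      c("subject_id", "session", "time", "clock_time")), dplyr::first),
      .by = "sample_id")
}

#' Train the transcriptomic circadian clock
#'
#' Fits two independent ridge regressions of `cos(2*pi*t/24)` and
#' `sin(2*pi*t/24)` on within-subject-normalized expression, giving a
#' deterministic closed-form clock. Predicted time is the phase angle of the
#' fitted (cos, sin) pair.
#'
#' With `ridge_penalty = NULL` the penalty is chosen by leave-one-subject-out
#' cross-validation over `penalty_grid`, minimizing mean absolute angular
#' error -- subjects, not samples, are held out, since the two samples of a
#' subject share a phase offset.
#'
#' @param expr Normalized long expression tibble (see
#'   [within_subject_normalize()]) with `subject_id`, `sample_id`, `gene_id`,
#'   `value`, and `clock_time` (hours in `[0, 24)`).
#' @param ridge_penalty Nonnegative scalar, or `NULL` to select by LOSO.
#' @param penalty_grid Candidate penalties for automatic selection.
#' @param seed Recorded in the model metadata (training itself is
#'   deterministic).
#' @return A `circ_clock` object: `gene_ids`, `w_cos`, `w_sin`, `b_cos`,
#'   `b_sin`, `ridge_penalty`, `training_meta`.
#' @export
train_clock <- function(expr, ridge_penalty = NULL,
                        penalty_grid = c(0.01, 0.1, 1, 10), seed = NULL) {
  meta <- sample_meta(expr)
  if (nrow(meta) < 2) abort("Need at least 2 training samples.")
  if (dplyr::n_distinct(round(meta$clock_time, 9)) < 2) {
    abort("Need at least 2 distinct clock times in the training set.")
  }
  if (any(meta$clock_time < 0 | meta$clock_time >= 24)) {
    abort("`clock_time` must lie in [0, 24).")
  }
  X <- expr_to_matrix(expr)
  meta <- meta[match(rownames(X), meta$sample_id), ]
  theta <- meta$clock_time * pi / 12
  yc <- cos(theta)
  ys <- sin(theta)

  cv_errors <- NULL
  if (is.null(ridge_penalty)) {
    subjects <- unique(meta$subject_id)
    cv_errors <- vapply(penalty_grid, function(lambda) {
      errs <- purrr::map(subjects, function(s) {
        hold <- meta$subject_id == s
        fc <- fit_ridge(X[!hold, , drop = FALSE], yc[!hold], lambda)
        fs <- fit_ridge(X[!hold, , drop = FALSE], ys[!hold], lambda)
        ch <- X[hold, , drop = FALSE] %*% fc$w + fc$b
        sh <- X[hold, , drop = FALSE] %*% fs$w + fs$b
        pred <- (atan2(sh, ch) * 12 / pi) %% 24
        abs(signed_angle(pred, meta$clock_time[hold]))
      })
      mean(unlist(errs))
    }, numeric(1))
    ridge_penalty <- penalty_grid[which.min(cv_errors)]
  }
  if (ridge_penalty < 0) abort("`ridge_penalty` must be nonnegative.")

  fc <- fit_ridge(X, yc, ridge_penalty)
  fs <- fit_ridge(X, ys, ridge_penalty)
  model <- structure(list(
    gene_ids = colnames(X),
    w_cos = fc$w, w_sin = fs$w,
    b_cos = fc$b, b_sin = fs$b,
    ridge_penalty = ridge_penalty,
    training_meta = list(
      seed = seed,
      n_training_samples = nrow(X),
      n_training_subjects = dplyr::n_distinct(meta$subject_id),
      cv_errors = if (!is.null(cv_errors)) {
        stats::setNames(cv_errors, penalty_grid)
      }
    )
  ), class = "circ_clock")
  pred <- predict_time(model, expr)
  truth <- meta$clock_time[match(pred$sample_id, meta$sample_id)]
  model$training_meta$in_sample_mae <-
    mean(abs(signed_angle(pred$transcriptomic_time, truth)))
  model
}

#' Predict Transcriptomic Time
#'
#' Applies a trained clock to normalized expression samples. Genes are matched
#' by identifier, not position; missing genes are an error naming them. The
#' Transcriptomic Time of a sample is `(12/pi) * atan2(s_hat, c_hat) mod 24`.
#'
#' @param model A `circ_clock` from [train_clock()].
#' @param expr Normalized long expression tibble covering all model genes.
#' @return Sample-level tibble with the input metadata columns plus
#'   `transcriptomic_time` (hours in `[0, 24)`).
#' @export
predict_time <- function(model, expr) {
  stopifnot(inherits(model, "circ_clock"))
  X <- expr_to_matrix(expr, gene_ids = model$gene_ids)
  ch <- drop(X %*% model$w_cos) + model$b_cos
  sh <- drop(X %*% model$w_sin) + model$b_sin
  degenerate <- abs(ch) < 1e-12 & abs(sh) < 1e-12
  if (any(degenerate)) {
    abort(sprintf("Undefined phase (cos, sin both ~0) for sample(s): %s",
                  paste(rownames(X)[degenerate], collapse = ", ")),
          class = "circphen_undefined_phase")
  }
  meta <- sample_meta(expr)
  meta[match(rownames(X), meta$sample_id), ] |>
    dplyr::mutate(transcriptomic_time = unname((atan2(sh, ch) * 12 / pi) %%
                                                 24))
}

#' Signed circular angle between two clock times
#'
#' The wrapped difference `predicted - true` mapped into `[-12, 12)` hours.
#' Positive values mean the prediction is later than clock time, i.e. an
#' advanced internal phase; the antipodal 12 h difference reports -12 by
#' convention.
#'
#' @param predicted,true_time Clock hours in `[0, 24)`; recycled to a common
#'   length.
#' @return Signed hours in `[-12, 12)`.
#' @examples
#' signed_angle(22, 20) # +2
#' signed_angle(1, 23)  # +2, wraps midnight
#' @export
signed_angle <- function(predicted, true_time) {
  bad <- function(x) any(!is.finite(x) | x < 0 | x >= 24)
  if (bad(predicted) || bad(true_time)) {
    abort("Clock times must lie in [0, 24).", class = "circphen_domain_error")
  }
  ((predicted - true_time + 12) %% 24) - 12
}

#' Per-subject Transcriptomic Angle
#'
#' Computes the signed angle of every sample and averages the AM and PM
#' session angles arithmetically per subject, yielding the Transcriptomic
#' Angle. Subjects with only one session are averaged over what is present and
#' flagged.
#'
#' @param predictions Output of [predict_time()] (needs `subject_id`,
#'   `session`, `clock_time`, `transcriptomic_time`), or a tibble already
#'   carrying a signed `angle` column.
#' @return Tibble: `subject_id`, `angle_am`, `angle_pm`, `angle_mean`,
#'   `single_session`.
#' @export
subject_angle <- function(predictions) {
  if (nrow(predictions) == 0) abort("No samples to average.")
  if (!"angle" %in% names(predictions)) {
    predictions <- predictions |>
      dplyr::mutate(angle = signed_angle(.data$transcriptomic_time,
                                         .data$clock_time))
  }
  predictions |>
    dplyr::summarise(
      angle_am = mean(.data$angle[.data$session == "AM"]),
      angle_pm = mean(.data$angle[.data$session == "PM"]),
      .by = "subject_id"
    ) |>
    dplyr::mutate(
      single_session = is.nan(.data$angle_am) | is.nan(.data$angle_pm),
      angle_mean = dplyr::if_else(
        .data$single_session,
        dplyr::coalesce(ifelse(is.nan(.data$angle_am), NA, .data$angle_am),
                        ifelse(is.nan(.data$angle_pm), NA, .data$angle_pm)),
        (.data$angle_am + .data$angle_pm) / 2
      ),
      angle_am = ifelse(is.nan(.data$angle_am), NA, .data$angle_am),
      angle_pm = ifelse(is.nan(.data$angle_pm), NA, .data$angle_pm)
    ) |>
    dplyr::select("subject_id", "angle_am", "angle_pm", "angle_mean",
                  "single_session")
}

#' Tolerance-accuracy curve and normalized AUC
#'
#' For every tolerance `h` on a grid over 0-12 h, the fraction of samples
#' whose absolute signed angle is at most `h`. The normalized AUC integrates
#' the empirical step curve exactly -- `nauc = 1 - mean(min(|angle|, 12))/12`,
#' the trapezoidal area with breakpoints at the observed angles, divided by
#' 12 -- so a single 6 h error gives exactly 0.5. The `grid_step` grid is used
#' for the reported and plotted curve.
#'
#' @param angles Numeric vector of signed angles, hours in `[-12, 12)`.
#' @param grid_step Tolerance grid resolution in hours.
#' @return A `circ_accuracy` object: tibble `curve` (`tolerance`,
#'   `fraction_correct`), scalar `nauc`, sample count `n`.
#' @export
accuracy_curve <- function(angles, grid_step = 0.1) {
  if (length(angles) == 0) abort("`angles` must be non-empty.")
  if (!is.numeric(angles) || any(!is.finite(angles))) {
    abort("`angles` must be finite numbers.")
  }
  if (grid_step <= 0) abort("`grid_step` must be positive.")
  a <- pmin(abs(angles), 12)
  tolerances <- seq(0, 12, by = grid_step)
  if (tolerances[length(tolerances)] < 12) tolerances <- c(tolerances, 12)
  fraction <- vapply(tolerances, function(h) mean(a <= h), numeric(1))
  structure(list(
    curve = tibble::tibble(tolerance = tolerances,
                           fraction_correct = fraction),
    nauc = 1 - mean(a) / 12,
    n = length(angles)
  ), class = "circ_accuracy")
}

#' @export
print.circ_accuracy <- function(x, ...) {
  cat(sprintf("<circ_accuracy> n = %d samples, nAUC = %.3f\n", x$n, x$nauc))
  cat(sprintf("  fraction within 2 h: %.2f | within 4 h: %.2f\n",
              x$curve$fraction_correct[which.min(abs(x$curve$tolerance - 2))],
              x$curve$fraction_correct[which.min(abs(x$curve$tolerance - 4))]))
  invisible(x)
}

#' @export
print.circ_clock <- function(x, ...) {
  cat(sprintf("<circ_clock> %d genes, ridge penalty %g, trained on %d samples (%d subjects)\n",
              length(x$gene_ids), x$ridge_penalty,
              x$training_meta$n_training_samples,
              x$training_meta$n_training_subjects))
  invisible(x)
}

#' @rdname train_clock
#' @param x A `circ_clock` object.
#' @param ... Unused.
#' @export
tidy.circ_clock <- function(x, ...) {
  tibble::tibble(gene_id = x$gene_ids, w_cos = unname(x$w_cos),
                 w_sin = unname(x$w_sin))
}

#' @rdname train_clock
#' @export
glance.circ_clock <- function(x, ...) {
  tibble::tibble(
    n_genes = length(x$gene_ids),
    ridge_penalty = x$ridge_penalty,
    n_training_samples = x$training_meta$n_training_samples,
    n_training_subjects = x$training_meta$n_training_subjects,
    in_sample_mae = x$training_meta$in_sample_mae
  )
}

#' Serialize a clock model to JSON
#'
#' @param model A `circ_clock`.
#' @param path Output/input JSON path.
#' @return `read_clock_model()` returns the `circ_clock`;
#'   `write_clock_model()` invisibly returns `path`.
#' @export
write_clock_model <- function(model, path) {
  stopifnot(inherits(model, "circ_clock"))
  out <- list(
    gene_ids = model$gene_ids,
    w_cos = unname(model$w_cos), w_sin = unname(model$w_sin),
    b_cos = model$b_cos, b_sin = model$b_sin,
    ridge_penalty = model$ridge_penalty,
    training_meta = model$training_meta
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_clock_model
#' @export
read_clock_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$gene_ids <- as.character(raw$gene_ids)
  structure(raw, class = "circ_clock")
}
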