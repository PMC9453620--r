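#' Pearson and covariate-adjusted partial correlation
#'
#' With no covariates this is the plain Pearson correlation with its usual
#' t-based two-sided p-value. With covariates, `x` and `y` are each
#' residualized on an intercept plus the covariates by least squares and the
#' Pearson correlation of the residuals is reported, with `n - 2 - k` degrees
#' of freedom for `k` covariate columns (factors expand via model matrix).
#' Complete cases only.
#'
#' @param data Data frame holding the variables.
#' @param x,y Column names of the two variables.
#' @param covariates Character vector of covariate column names (may be
#'   empty).
#' @return One-row tibble: `variable_pair`, `r`, `p_value`, `n`, `covariates`.
#' @export
partial_correlation <- function(data, x, y, covariates = character()) {
  cols <- c(x, y, covariates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("Column(s) not found: %s",
                  paste(missing_cols, collapse = ", ")))
  }
  d <- data[stats::complete.cases(data[cols]), cols, drop = FALSE]
  xv <- as.numeric(d[[x]])
  yv <- as.numeric(d[[y]])
  n <- length(xv)
  # constant covariates carry no adjustment information; drop them so factors
  # with a single observed level do not break the model matrix
  covariates <- covariates[vapply(covariates,
                                  function(v) dplyr::n_distinct(d[[v]]) > 1,
                                  logical(1))]
  if (length(covariates) > 0) {
    Z <- stats::model.matrix(stats::reformulate(covariates), data = d)
  } else {
    Z <- matrix(1, n, 1)
  }
  k <- ncol(Z) - 1L
  if (n <= 2 + k) {
    abort(sprintf("Need n > 2 + %d covariate columns; have n = %d.", k, n))
  }
  rx <- stats::lm.fit(Z, xv)$residuals
  ry <- stats::lm.fit(Z, yv)$residuals
  if (stats::var(rx) < 1e-12 * max(stats::var(xv), 1) ||
      stats::var(ry) < 1e-12 * max(stats::var(yv), 1)) {
    abort("Residual variance ~0 (variable collinear with covariates).",
          class = "circphen_degenerate_input")
  }
  r <- cor(rx, ry)
  df <- n - 2L - k
  tstat <- r * sqrt(df / (1 - r^2))
  tibble::tibble(
    variable_pair = paste(x, y, sep = " ~ "),
    r = r,
    p_value = 2 * pt(-abs(tstat), df),
    n = n,
    covariates = paste(covariates, collapse = ",")
  )
}

#' @importFrom stats pt
NULL

#' Z-scored Bland-Altman agreement
#'
#' Both measures are standardized to z-scores (so differently scaled
#' phenotypes are comparable), then per-subject differences `z(x) - z(y)` are
#' summarized by their mean and 1.96 SD limits of agreement. With complete
#' cases the mean difference is analytically zero, making the limits of
#' agreement the informative output; their half-width equals
#' `1.96 * sqrt(2 - 2r)` for correlation `r`.
#'
#' Set `flip_y = TRUE` for clock-time measures where larger = delayed (DLMO,
#' bedtime, waketime, M10 start): `y` is negated before z-scoring so both
#' measures share the "positive = advanced phase" orientation of the
#' Transcriptomic Angle.
#'
#' @param x,y Numeric vectors of equal length (n >= 3), complete cases used.
#' @param flip_y Negate `y` before z-scoring?
#' @param labels Length-2 character vector naming the measures.
#' @return A `circ_bland_altman` object: tibble `points` (`average`,
#'   `difference` in z-units), `mean_difference`, `loa_lower`, `loa_upper`,
#'   `n`, `labels`.
#' @export
bland_altman <- function(x, y, flip_y = FALSE, labels = c("x", "y")) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3) abort("Bland-Altman needs at least 3 complete pairs.")
  if (flip_y) y <- -y
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Zero-variance input; z-scores undefined.",
          class = "circphen_degenerate_input")
  }
  zx <- (x - mean(x)) / sd(x)
  zy <- (y - mean(y)) / sd(y)
  d <- zx - zy
  md <- mean(d)
  half <- 1.96 * sd(d)
  structure(list(
    points = tibble::tibble(average = (zx + zy) / 2, difference = d),
    mean_difference = md,
    loa_lower = md - half,
    loa_upper = md + half,
    n = length(d),
    labels = labels,
    flip_y = flip_y
  ), class = "circ_bland_altman")
}

#' @export
print.circ_bland_altman <- function(x, ...) {
  cat(sprintf("<circ_bland_altman> %s vs %s%s, n = %d\n", x$labels[1],
              x$labels[2], if (x$flip_y) " (y negated)" else "", x$n))
  cat(sprintf("  mean difference %.3g z, limits of agreement [%.3f, %.3f]\n",
              x$mean_difference, x$loa_lower, x$loa_upper))
  invisible(x)
}

#' Two-group comparison
#'
#' Continuous variables use the equal-variance Student's t-test; categorical
#' variables use the chi-squared test of independence without continuity
#' correction. Exactly two groups are required.
#'
#' @param values Numeric (t-test) or character/factor (chi-squared) vector.
#' @param groups Grouping vector with exactly two levels after dropping
#'   missing values.
#' @return One-row tibble: `test` (`"t"` or `"chisq"`), `statistic`,
#'   `p_value`, `significant` (at 0.05).
#' @export
group_compare <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- as.character(groups[ok])
  lv <- unique(groups)
  if (length(lv) != 2) abort("`groups` must have exactly 2 levels.")
  if (is.numeric(values)) {
    if (min(table(groups)) < 2) {
      abort("Each group needs at least 2 observations for the t-test.")
    }
    fit <- stats::t.test(values[groups == lv[1]], values[groups == lv[2]],
                         var.equal = TRUE)
    out <- tibble::tibble(test = "t", statistic = unname(fit$statistic),
                          p_value = fit$p.value)
  } else {
    tab <- table(values, groups)
    fit <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    out <- tibble::tibble(test = "chisq", statistic = unname(fit$statistic),
                          p_value = fit$p.value)
  }
  dplyr::mutate(out, significant = .data$p_value < 0.05)
}

#' Kolmogorov-Smirnov normality check
#'
#' One-sample KS test of `x` against a normal distribution with the sample's
#' own mean and SD. Because the parameters are estimated from the same data,
#' the nominal p-value is conservative (the Lilliefors caveat); a warning
#' says so. Intended to mirror exploratory normality screening, not formal
#' inference.
#'
#' @param x Numeric vector, n >= 5, non-constant.
#' @return One-row tibble: `statistic` (KS D in `[0, 1]`), `p_value`.
#' @export
normality_check <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 5) abort("Normality check needs n >= 5.")
  if (sd(x) == 0) {
    abort("Constant input; normality test undefined.",
          class = "circphen_degenerate_input")
  }
  warn(paste("KS test uses mean/SD estimated from the sample;",
             "the p-value is conservative (Lilliefors caveat)."),
       class = "circphen_lilliefors_warning")
  fit <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), sd(x)))
  tibble::tibble(statistic = unname(fit$statistic), p_value = fit$p.value)
}

#' Correlate the Transcriptomic Angle with other phenotypes
#'
#' Convenience wrapper running [partial_correlation()] of one variable against
#' a set of others, by default adjusted for age and sex.
#'
#' @param phenotypes One row per subject (see [build_phenotype_table()]).
#' @param x Focal variable name.
#' @param variables Character vector of comparison variable names.
#' @param covariates Covariate column names (empty for plain Pearson).
#' @return Tibble with one row per comparison: `variable`, `r`, `p_value`,
#'   `n`, `covariates`.
#' @export
correlate_phenotypes <- function(phenotypes,
                                 x = "transcriptomic_angle",
                                 variables = c("waketime", "m10_start",
                                               "bedtime", "amplitude",
                                               "dlmo_time", "meq_score"),
                                 covariates = c("age", "sex")) {
  purrr::map(variables, function(v) {
    row <- tryCatch(
      partial_correlation(phenotypes, x, v, covariates),
      error = function(e) {
        warn(sprintf("Correlation with '%s' not estimable: %s", v,
                     conditionMessage(e)))
        tibble::tibble(variable_pair = NA_character_, r = NA_real_,
                       p_value = NA_real_,
                       n = sum(stats::complete.cases(
                         phenotypes[c(x, v)])),
                       covariates = paste(covariates, collapse = ","))
      })
    row |>
      dplyr::mutate(variable = v, .before = 1) |>
      dplyr::select(-"variable_pair")
  }) |>
    purrr::list_rbind()
}
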