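#' Plot a tolerance-accuracy curve
#'
#' Fraction of correctly predicted samples against the error tolerance in
#' hours, with the 2 h and 4 h bands marked and the normalized AUC in the
#' subtitle.
#'
#' @param object A `circ_accuracy` from [accuracy_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.circ_accuracy <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$tolerance,
                               y = .data$fraction_correct)) +
    ggplot2::geom_vline(xintercept = c(2, 4), linetype = "dotted",
                        colour = "grey55") +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "Transcriptomic Angle tolerance (h)",
      y = "Fraction of samples within tolerance",
      title = "Transcriptomic clock tolerance-accuracy curve",
      subtitle = sprintf("nAUC = %.3f (n = %d samples)", object$nauc,
                         object$n)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a Bland-Altman agreement
#'
#' Per-subject difference of the z-scored measures against their average, with
#' the mean difference (solid) and 1.96 SD limits of agreement (dashed).
#'
#' @param object A `circ_bland_altman` from [bland_altman()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.circ_bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$average, y = .data$difference)) +
    ggplot2::geom_hline(yintercept = object$mean_difference,
                        colour = "firebrick") +
    ggplot2::geom_hline(yintercept = c(object$loa_lower, object$loa_upper),
                        colour = "firebrick", linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = sprintf("Average of z(%s) and z(%s)", object$labels[1],
                  object$labels[2]),
      y = "Difference (z-units)",
      title = sprintf("Bland-Altman: %s vs %s", object$labels[1],
                      object$labels[2])
    ) +
    ggplot2::theme_minimal()
}

#' Plot evening melatonin profiles
#'
#' Saliva (and optionally plasma) concentration against evening time, one line
#' per subject, with the calibrated threshold as a horizontal reference.
#'
#' @param melatonin Long melatonin tibble (`subject_id`, `medium`, `time`,
#'   `pg_ml`).
#' @param threshold Optional threshold line, pg/mL.
#' @param medium Which medium to show.
#' @return A ggplot.
#' @export
plot_melatonin_profiles <- function(melatonin, threshold = NULL,
                                    medium = "saliva") {
  p <- ggplot2::ggplot(
    dplyr::filter(melatonin, .data$medium == !!medium),
    ggplot2::aes(x = .data$time, y = .data$pg_ml,
                 group = .data$subject_id)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = "Evening time (h, monotone past midnight)",
                  y = sprintf("%s melatonin (pg/mL)", medium),
                  title = "Evening melatonin profiles") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold,
                                 linetype = "dashed", colour = "firebrick")
  }
  p
}

#' Plot an average 24 h activity profile
#'
#' @param profile Output of [average_profile()].
#' @return A ggplot.
#' @export
plot_activity_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$bin_start,
                                        y = .data$mean_counts)) +
    ggplot2::geom_step() +
    ggplot2::scale_x_continuous(breaks = seq(0, 24, 6)) +
    ggplot2::labs(x = "Clock time (h)", y = "Mean activity (counts/epoch)",
                  title = "Average 24 h activity profile") +
    ggplot2::theme_minimal()
}
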