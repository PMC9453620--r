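# Nonparametric rest-activity rhythm metrics. All functions accept one
# subject's epoch-level recording: a data frame with `time` (hours since the
# recording start, assumed to begin at midnight) and `counts`, or -- for the
# IS/IV statistics -- a numeric vector that is already a binned series.

infer_epoch_minutes <- function(time) {
  d <- diff(sort(unique(round(time * 3600))))
  if (length(d) == 0) abort("Cannot infer epoch length from one epoch.")
  min(d) / 60
}

# Mean counts per consecutive chronological bin.
bin_epochs <- function(epochs, bin_minutes) {
  if (nrow(epochs) == 0) abort("Empty activity series.")
  idx <- floor(epochs$time * 60 / bin_minutes)
  means <- tapply(epochs$counts, idx, mean)
  ord <- order(as.numeric(names(means)))
  tibble::tibble(bin = as.numeric(names(means))[ord],
                 value = as.numeric(means)[ord])
}

#' Average 24 h activity profile
#'
#' Bins one subject's epochs by clock time and averages each bin across
#' recording days. Days with less than `min_coverage` of their expected epochs
#' are excluded before averaging (a missing-data guard; complete synthetic
#' recordings are unaffected).
#'
#' @param epochs Tibble with `time` (hours since recording start at midnight)
#'   and `counts`.
#' @param bin_minutes Clock-time bin width; must divide 1440.
#' @param min_coverage Minimum fraction of expected epochs for a day to count.
#' @return Tibble: `bin_start` (clock hours, `0, ..., 24 - bin`) and
#'   `mean_counts`.
#' @export
average_profile <- function(epochs, bin_minutes = 60, min_coverage = 0.8) {
  if (nrow(epochs) == 0) abort("Empty activity series.")
  if (1440 %% bin_minutes != 0) abort("`bin_minutes` must divide 1440.")
  ep_min <- infer_epoch_minutes(epochs$time)
  expected <- 1440 / ep_min
  day <- floor(epochs$time / 24)
  keep_days <- names(which(table(day) >= min_coverage * expected))
  kept <- epochs[as.character(day) %in% keep_days, ]
  if (nrow(kept) == 0) {
    abort("No day reaches the required epoch coverage.",
          class = "circphen_coverage_error")
  }
  kept |>
    dplyr::mutate(bin_start = floor((.data$time %% 24) * 60 / bin_minutes) *
                    bin_minutes / 60,
                  day = floor(.data$time / 24)) |>
    dplyr::summarise(day_mean = mean(.data$counts),
                     .by = c("day", "bin_start")) |>
    dplyr::summarise(mean_counts = mean(.data$day_mean), .by = "bin_start") |>
    dplyr::arrange(.data$bin_start)
}

# Circular moving-window means over a 24 h profile; earliest start wins ties.
window_extreme <- function(x, width_bins, which = c("max", "min")) {
  which <- match.arg(which)
  p <- length(x)
  cs <- cumsum(c(x, x))
  means <- (cs[seq_len(p) + width_bins - 1] -
              c(0, cs)[seq_len(p)]) / width_bins
  i <- if (which == "max") which.max(means) else which.min(means)
  list(start_bin = i - 1L, mean = means[i])
}

#' M10, L5, and rhythm amplitude from an average profile
#'
#' M10 is the contiguous (circularly wrapping) 10 h window of the average
#' 24 h profile with the highest mean activity; L5 the 5 h window with the
#' lowest. Amplitude is `m10_mean - l5_mean` on the raw count scale; relative
#' amplitude divides by their sum. Ties resolve to the earliest start after
#' 00:00.
#'
#' @param profile Output of [average_profile()].
#' @return One-row tibble: `m10_start`, `m10_mean`, `l5_start`, `l5_mean`,
#'   `amplitude`, `relative_amplitude` (clock hours / counts).
#' @export
m10_l5_amplitude <- function(profile) {
  p <- nrow(profile)
  bin_minutes <- 1440 / p
  if (600 %% bin_minutes != 0 || 300 %% bin_minutes != 0) {
    abort("Profile resolution must divide the 10 h and 5 h windows evenly.")
  }
  x <- profile$mean_counts[order(profile$bin_start)]
  m10 <- window_extreme(x, as.integer(600 / bin_minutes), "max")
  l5 <- window_extreme(x, as.integer(300 / bin_minutes), "min")
  tibble::tibble(
    m10_start = m10$start_bin * bin_minutes / 60,
    m10_mean = m10$mean,
    l5_start = l5$start_bin * bin_minutes / 60,
    l5_mean = l5$mean,
    amplitude = m10$mean - l5$mean,
    relative_amplitude = if (m10$mean + l5$mean > 0) {
      (m10$mean - l5$mean) / (m10$mean + l5$mean)
    } else 0
  )
}

as_binned_series <- function(series, bin_minutes) {
  if (is.data.frame(series)) {
    bin_epochs(series, bin_minutes)$value
  } else if (is.numeric(series)) {
    series
  } else {
    abort("`series` must be an epochs data frame or a binned numeric vector.")
  }
}

#' Interdaily stability (IS)
#'
#' The Van Someren nonparametric measure of day-to-day regularity: the
#' variance of the clock-time-locked average profile relative to the total
#' variance, `IS = (n * sum((xbar_h - xbar)^2)) / (p * sum((x_i - xbar)^2))`
#' with `p` bins per day and `n` total bins. 1 = perfectly repeated days;
#' values near `1/n_days` indicate no daily structure. Complete days only;
#' trailing partial days are dropped.
#'
#' @param series Epoch data frame (`time`, `counts`) or an already-binned
#'   numeric vector at `bin_minutes` resolution.
#' @param bin_minutes Bin width, minutes.
#' @return IS in `[0, 1]`.
#' @export
interdaily_stability <- function(series, bin_minutes = 60) {
  x <- as_binned_series(series, bin_minutes)
  p <- as.integer(1440 / bin_minutes)
  n_days <- length(x) %/% p
  if (n_days < 2) abort("Interdaily stability needs at least 2 complete days.")
  x <- x[seq_len(n_days * p)]
  if (stats::var(x) == 0) {
    abort("Constant series: interdaily stability undefined (zero variance).",
          class = "circphen_undefined_metric")
  }
  n <- length(x)
  xbar <- mean(x)
  hourly <- colMeans(matrix(x, nrow = n_days, ncol = p, byrow = TRUE))
  (n * sum((hourly - xbar)^2)) / (p * sum((x - xbar)^2))
}

#' Intradaily variability (IV)
#'
#' The Van Someren fragmentation measure: the mean squared first difference of
#' the binned series relative to its variance,
#' `IV = (n * sum(diff(x)^2)) / ((n - 1) * sum((x - xbar)^2))`. Near 0 for a
#' smooth sinusoid (the hourly-sampled 24 h sinusoid limit is
#' `2 * (1 - cos(2*pi/24))` ~ 0.068), 2 for white noise, up to 4 for a
#' strictly alternating series.
#'
#' @inheritParams interdaily_stability
#' @return IV >= 0.
#' @export
intradaily_variability <- function(series, bin_minutes = 60) {
  x <- as_binned_series(series, bin_minutes)
  if (length(x) < 2) abort("Intradaily variability needs at least 2 bins.")
  if (stats::var(x) == 0) {
    abort("Constant series: intradaily variability undefined (zero variance).",
          class = "circphen_undefined_metric")
  }
  n <- length(x)
  (n * sum(diff(x)^2)) / ((n - 1) * sum((x - mean(x))^2))
}

#' All nonparametric rhythm metrics for one subject
#'
#' @inheritParams average_profile
#' @param bin_minutes Bin width for the profile and the IS/IV statistics.
#' @return One-row tibble combining [m10_l5_amplitude()] with
#'   `interdaily_stability` and `intradaily_variability`.
#' @export
rhythm_metrics <- function(epochs, bin_minutes = 60) {
  dplyr::bind_cols(
    m10_l5_amplitude(average_profile(epochs, bin_minutes)),
    tibble::tibble(
      interdaily_stability = interdaily_stability(epochs, bin_minutes),
      intradaily_variability = intradaily_variability(epochs, bin_minutes)
    )
  )
}

#' Diary-anchored sleep summary
#'
#' Scores each diary rest interval epoch by epoch: an epoch is asleep when its
#' counts fall below `wake_threshold`. Per night, total sleep time is the
#' asleep time, wake after sleep onset (WASO) the awake minutes after the
#' first asleep epoch, and sleep efficiency the asleep percentage of the
#' interval. Nights are then averaged -- circular means for clock times
#' (bedtime, waketime, midsleep), arithmetic means otherwise. Rest intervals
#' falling outside the recording are skipped with a warning.
#'
#' @param epochs Tibble with `time` (hours since recording start) and
#'   `counts`.
#' @param rest_intervals Tibble with `bedtime` and `waketime` as absolute
#'   hours on the same axis as `epochs$time`.
#' @param wake_threshold Counts at/above which an epoch scores awake.
#' @return One-row tibble: `bedtime`, `waketime`, `midsleep` (clock hours),
#'   `total_sleep_time` (hours), `sleep_efficiency` (percent), `waso`
#'   (minutes), `n_nights`.
#' @export
sleep_summary <- function(epochs, rest_intervals, wake_threshold = 40) {
  if (nrow(rest_intervals) == 0) abort("Need at least one rest interval.")
  ep_min <- infer_epoch_minutes(epochs$time)
  span <- range(epochs$time)
  nights <- purrr::pmap(
    list(rest_intervals$bedtime, rest_intervals$waketime),
    function(bed, wake) {
      if (bed < span[1] || wake > span[2] + ep_min / 60) {
        warn(sprintf("Rest interval %.2f-%.2f outside recording; skipped.",
                     bed, wake))
        return(NULL)
      }
      sel <- epochs$time >= bed & epochs$time < wake
      asleep <- epochs$counts[sel] < wake_threshold
      tst <- sum(asleep) * ep_min / 60
      onset <- which(asleep)[1]
      waso <- if (is.na(onset)) 0 else {
        sum(!asleep[seq_along(asleep) > onset]) * ep_min
      }
      tibble::tibble(bedtime = bed %% 24, waketime = wake %% 24,
                     midsleep = (bed + (wake - bed) / 2) %% 24,
                     total_sleep_time = tst,
                     sleep_efficiency = 100 * tst / (wake - bed),
                     waso = waso)
    }
  ) |> purrr::compact() |> purrr::list_rbind()
  if (nrow(nights) == 0) abort("No rest interval overlaps the recording.")
  tibble::tibble(
    bedtime = circular_mean_hours(nights$bedtime),
    waketime = circular_mean_hours(nights$waketime),
    midsleep = circular_mean_hours(nights$midsleep),
    total_sleep_time = mean(nights$total_sleep_time),
    sleep_efficiency = mean(nights$sleep_efficiency),
    waso = mean(nights$waso),
    n_nights = nrow(nights)
  )
}
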