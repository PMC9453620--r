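# Circular (clock-time) helpers. Clock hours live on a 24 h circle; evening
# series are kept on a monotone session axis (24.5 = 00:30 the next morning)
# so interpolation and regression never span a wrap.

#' Circular mean of clock hours
#'
#' Maps hours onto the unit circle, averages, and maps back. Use for clock-time
#' summaries (bedtime, waketime, DLMO) where arithmetic means break across
#' midnight.
#'
#' @param hours Numeric vector of clock hours (any real values; interpreted
#'   modulo 24).
#' @param na.rm Drop missing values first?
#' @return Mean clock hour in `[0, 24)`.
#' @examples
#' circular_mean_hours(c(23.5, 0.5)) # 0, not 12
#' @export
circular_mean_hours <- function(hours, na.rm = FALSE) {
  if (na.rm) hours <- hours[!is.na(hours)]
  if (length(hours) == 0) return(NA_real_)
  a <- hours * pi / 12
  # double modulo: a tiny negative angle mods to exactly 24.0 in doubles
  ((atan2(mean(sin(a)), mean(cos(a))) * 12 / pi) %% 24) %% 24
}

#' Circular standard deviation of clock hours, in minutes
#'
#' The usual directional-statistics definition `sqrt(-2 log R)` where `R` is
#' the mean resultant length, converted from radians to minutes. Matches the
#' "time +/- min" presentation of clock-time variables in cohort summary
#' tables.
#'
#' @inheritParams circular_mean_hours
#' @return Circular SD in minutes (0 for a single observation).
#' @export
circular_sd_minutes <- function(hours, na.rm = FALSE) {
  if (na.rm) hours <- hours[!is.na(hours)]
  if (length(hours) == 0) return(NA_real_)
  a <- hours * pi / 12
  r <- sqrt(mean(sin(a))^2 + mean(cos(a))^2)
  r <- min(r, 1) # guard rounding
  sqrt(-2 * log(r)) * (12 / pi) * 60
}

#' Unwrap clock hours around a reference hour
#'
#' Adds the multiple of 24 that brings each value into `(center - 12,
#' center + 12]`. Turns circular clock times into a linear scale for
#' correlation and t-tests when all observations cluster around a known part
#' of the day (e.g. bedtimes around midnight).
#'
#' @param hours Numeric clock hours.
#' @param center Reference hour the values cluster around.
#' @return Unwrapped hours on a linear scale.
#' @examples
#' unwrap_hours(c(23.5, 0.5), center = 24) # 23.5, 24.5
#' @export
unwrap_hours <- function(hours, center) {
  hours + 24 * round((center - hours) / 24)
}

# Stable per-subject RNG sub-stream seed. Hashing the subject id (rather than
# its index) keeps earlier subjects' draws fixed when the cohort grows.
subject_seed <- function(seed, subject_id, stream = 0L) {
  h <- 0
  for (ch in utf8ToInt(as.character(subject_id))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer((h + as.numeric(seed) * 7919 + as.numeric(stream) * 104729) %%
               2147483647)
}
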