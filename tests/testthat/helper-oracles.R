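# Independent brute-force oracles; deliberately naive and separate from the
# package implementations they check.

naive_is <- function(x, bins_per_day) {
  n_days <- length(x) %/% bins_per_day
  x <- x[seq_len(n_days * bins_per_day)]
  xbar <- mean(x)
  hourly <- vapply(seq_len(bins_per_day), function(h) {
    mean(x[seq(h, length(x), by = bins_per_day)])
  }, numeric(1))
  (length(x) * sum((hourly - xbar)^2)) / (bins_per_day * sum((x - xbar)^2))
}

naive_iv <- function(x) {
  n <- length(x)
  num <- 0
  for (i in 2:n) num <- num + (x[i] - x[i - 1])^2
  (n * num) / ((n - 1) * sum((x - mean(x))^2))
}

# Exhaustive scan over every circular window start.
brute_window <- function(x, width, which = "max") {
  p <- length(x)
  best_mean <- if (which == "max") -Inf else Inf
  best_start <- NA_integer_
  for (s in seq_len(p)) {
    idx <- ((s - 1 + seq_len(width) - 1) %% p) + 1
    m <- mean(x[idx])
    better <- if (which == "max") m > best_mean else m < best_mean
    if (better) {
      best_mean <- m
      best_start <- s - 1L
    }
  }
  list(start_bin = best_start, mean = best_mean)
}

# Partial correlation via explicit normal equations.
naive_partial_r <- function(x, y, Z) {
  Z1 <- cbind(1, Z)
  beta_x <- solve(t(Z1) %*% Z1, t(Z1) %*% x)
  beta_y <- solve(t(Z1) %*% Z1, t(Z1) %*% y)
  rx <- x - Z1 %*% beta_x
  ry <- y - Z1 %*% beta_y
  sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
}

# Small cohort configuration for fast tests; dots override the defaults.
quick_config <- function(...) {
  args <- utils::modifyList(
    list(n_subjects = 6, n_days = 3, n_genes = 12, seed = 42L), list(...))
  do.call(cohort_config, args)
}

one_subject <- function(delta = 0, id = "S001") {
  tibble::tibble(subject_id = id, phase_offset_delta = delta)
}

# Zero-mean phase offsets (reference-population conditions).
zero_mean_types <- c(morning = 0, intermediate = 0, evening = 0)
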