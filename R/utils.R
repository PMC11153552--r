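# Internal helpers shared across modules.

#' Validate a luminescence series data frame
#'
#' A luminescence series is any data frame with a numeric `time_h` column
#' (hours since the start of the recording, strictly increasing) and a numeric
#' `value` column (counts or normalized units; `NA` marks a missing reading).
#' All per-well operations in the package accept this shape.
#'
#' @param ts A data frame with columns `time_h` and `value`.
#' @param arg Name used in error messages.
#' @return The input as a tibble, invisibly validated.
#' @keywords internal
check_series <- function(ts, arg = "ts") {
  if (!is.data.frame(ts)) {
    abort(sprintf("`%s` must be a data frame with columns `time_h` and `value`.", arg))
  }
  if (!all(c("time_h", "value") %in% names(ts))) {
    abort(sprintf("`%s` must have columns `time_h` and `value`.", arg))
  }
  t <- ts$time_h
  if (anyNA(t)) abort(sprintf("`%s$time_h` must not contain missing values.", arg))
  if (is.unsorted(t, strictly = TRUE)) {
    abort(sprintf("`%s$time_h` must be strictly increasing.", arg))
  }
  tibble::as_tibble(ts)
}

# Drop missing readings; error if fewer than `min_points` remain.
drop_missing <- function(ts, min_points = 2L, what = "analysis") {
  keep <- !is.na(ts$value)
  out <- ts[keep, , drop = FALSE]
  if (nrow(out) < min_points) {
    abort(sprintf(
      "Fewer than %d non-missing points available for %s (got %d).",
      min_points, what, nrow(out)
    ))
  }
  out
}

# Centered moving average on an irregular time grid.
#
# For each time t the window is [t - window_h/2, t + window_h/2], inclusive at
# both edges; the window shrinks near the series boundaries. Missing values do
# not contribute to any window mean, and positions that are missing in the
# input stay missing in the output (gaps are preserved, never imputed).
windowed_mean <- function(times, values, window_h) {
  stopifnot(window_h > 0)
  half <- window_h / 2
  ok <- !is.na(values)
  t_ok <- times[ok]
  v_ok <- values[ok]
  out <- rep(NA_real_, length(times))
  if (length(t_ok) == 0L) return(out)
  cs <- c(0, cumsum(v_ok))
  # first index j with t_ok[j] >= t - half, last index with t_ok[j] <= t + half
  i1 <- findInterval(times - half, t_ok, left.open = TRUE) + 1L
  i2 <- findInterval(times + half, t_ok)
  n_in <- i2 - i1 + 1L
  has <- n_in > 0L
  out[has] <- (cs[i2[has] + 1L] - cs[i1[has]]) / n_in[has]
  out[!ok] <- NA_real_
  out
}

# Centered trapezoidal (integral) windowed mean on an irregular time grid.
#
# Averages the piecewise-linear interpolant of the non-missing points over the
# nodes falling in [t - window_h/2, t + window_h/2]. Unlike the point mean,
# the integral mean of a sinusoid over a full matched-period window is exactly
# zero, which is what makes a one-cycle detrend window transparent to the
# circadian component. With a single in-window point the mean is that value.
windowed_mean_trapz <- function(times, values, window_h) {
  stopifnot(window_h > 0)
  half <- window_h / 2
  ok <- !is.na(values)
  t_ok <- times[ok]
  v_ok <- values[ok]
  out <- rep(NA_real_, length(times))
  if (length(t_ok) == 0L) return(out)
  # cumulative trapezoid integral over consecutive nodes
  seg <- if (length(t_ok) > 1L) {
    (v_ok[-1L] + v_ok[-length(v_ok)]) / 2 * diff(t_ok)
  } else {
    numeric(0)
  }
  csI <- c(0, cumsum(seg))
  i1 <- findInterval(times - half, t_ok, left.open = TRUE) + 1L
  i2 <- findInterval(times + half, t_ok)
  has <- i2 >= i1
  width <- t_ok[pmax(i2, 1L)] - t_ok[pmin(i1, length(t_ok))]
  single <- has & (i2 == i1 | width <= 0)
  out[single] <- v_ok[i1[single]]
  multi <- has & !single
  out[multi] <- (csI[i2[multi]] - csI[i1[multi]]) / width[multi]
  out[!ok] <- NA_real_
  out
}

# Positive modulus: result always in [0, m).
mod_pos <- function(x, m) {
  r <- x %% m
  r[r >= m] <- 0 # guard against x %% m == m from rounding
  r
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
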