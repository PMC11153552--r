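#' Preprocessing configuration
#'
#' Settings for the raw-counts-to-normalized-signal transform applied to each
#' well before any rhythm analysis. The fixed stage order is: background
#' subtraction, truncation of the initial luciferase-accumulation transient,
#' moving-average detrending, moving-average smoothing, and normalization to
#' the initial maximum.
#'
#' @param background Scalar background counts to subtract, or `"from_blanks"`
#'   to pool the median of all blank wells on the plate. When neither a scalar
#'   nor blank wells are available, 0 is used with a warning (detrending
#'   absorbs constant offsets).
#' @param truncate_h Hours removed from the start of the recording; default 24
#'   (the luciferase accumulation transient spans roughly the first 12-24 h).
#' @param detrend_window_h Width (hours) of the centered moving-average window
#'   subtracted to remove baseline drift; default 24, one full circadian
#'   cycle, which passes a 24-h sinusoid unattenuated over full windows.
#' @param smooth_window_h Width (hours) of the centered moving-average
#'   smoother; default 2.5 (5 samples at 30-min sampling).
#' @param norm_window_h Window (hours) after truncation over which the
#'   "initial maximum" used for normalization is taken; default 24.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(background = "from_blanks", truncate_h = 24,
                              detrend_window_h = 24, smooth_window_h = 2.5,
                              norm_window_h = 24) {
  if (!(identical(background, "from_blanks") || is_scalar_number(background))) {
    abort("`background` must be a finite scalar or \"from_blanks\".")
  }
  stopifnot(truncate_h >= 0, detrend_window_h > 0, smooth_window_h > 0,
            norm_window_h > 0)
  if (smooth_window_h >= detrend_window_h) {
    abort("`smooth_window_h` must be smaller than `detrend_window_h`.")
  }
  structure(
    list(background = background, truncate_h = truncate_h,
         detrend_window_h = detrend_window_h, smooth_window_h = smooth_window_h,
         norm_window_h = norm_window_h),
    class = "preprocess_config"
  )
}

#' Preprocessing stages
#'
#' Individual stages of the per-well preprocessing pipeline. Each takes and
#' returns a series data frame (columns `time_h`, `value`); missing readings
#' are preserved as gaps, never interpolated.
#'
#' @param ts A series data frame with columns `time_h`, `value`.
#' @param background Finite scalar counts; subtracted from every value
#'   (negative results are kept, not clamped).
#' @return A tibble with the same `time_h` axis (truncation excepted).
#' @name preprocess_stages
NULL

#' @rdname preprocess_stages
#' @export
subtract_background <- function(ts, background) {
  ts <- check_series(ts)
  if (!is_scalar_number(background)) abort("`background` must be a finite scalar.")
  ts$value <- ts$value - background
  ts
}

#' Estimate plate background from blank wells
#'
#' Pools every reading of every blank well on the plate and returns the
#' median, a robust estimate of the instrument + medium background level.
#'
#' @param rec A [plate_recording()] with at least one well flagged
#'   `is_blank = TRUE`.
#' @return Scalar background counts.
#' @export
estimate_background <- function(rec) {
  stopifnot(inherits(rec, "plate_recording"))
  blanks <- rec$meta$well[rec$meta$is_blank]
  if (length(blanks) == 0L) {
    abort(paste0(
      "No blank wells on this plate; pass a scalar `background` ",
      "(counts) to subtract instead."
    ))
  }
  v <- rec$data$value[rec$data$well %in% blanks]
  v <- v[!is.na(v)]
  if (length(v) == 0L) abort("Blank wells contain no non-missing readings.")
  stats::median(v)
}

#' @rdname preprocess_stages
#' @param truncate_h Hours removed from the start of the series. Times are not
#'   re-zeroed: the absolute axis is preserved so the schedule stays aligned.
#' @export
truncate_initial <- function(ts, truncate_h) {
  ts <- check_series(ts)
  stopifnot(truncate_h >= 0)
  out <- ts[ts$time_h >= truncate_h, , drop = FALSE]
  if (nrow(out) == 0L) {
    abort(sprintf("Truncating %g h removed every point of the series.", truncate_h))
  }
  out
}

#' @rdname preprocess_stages
#' @param window_h Moving-average window width in hours. The window is
#'   centered, `[t - window_h/2, t + window_h/2]`, and shrinks at the series
#'   edges. Detrending subtracts the *integral* (trapezoidal) mean over the
#'   window: the integral mean of a sinusoid over a full matched-period
#'   window is exactly zero, so a one-cycle window removes baseline drift
#'   while leaving the circadian component untouched (a discrete point mean
#'   would leak a small fraction of it). Smoothing uses the discrete point
#'   mean (a plain boxcar over the samples in the window).
#' @export
detrend_moving_average <- function(ts, window_h) {
  ts <- check_series(ts)
  stopifnot(window_h > 0)
  span <- max(ts$time_h) - min(ts$time_h)
  if (span < window_h) {
    abort(sprintf("Series span (%.3g h) is shorter than the detrend window (%g h).",
                  span, window_h))
  }
  ts$value <- ts$value - windowed_mean_trapz(ts$time_h, ts$value, window_h)
  ts
}

#' @rdname preprocess_stages
#' @export
smooth_moving_average <- function(ts, window_h) {
  ts <- check_series(ts)
  stopifnot(window_h > 0)
  ts$value <- windowed_mean(ts$time_h, ts$value, window_h)
  ts
}

#' @rdname preprocess_stages
#' @param norm_window_h Hours after the series start over which the maximum is
#'   taken; every value is divided by that maximum, so the initial-window
#'   maximum becomes exactly 1.
#' @export
normalize_initial_max <- function(ts, norm_window_h) {
  ts <- check_series(ts)
  stopifnot(norm_window_h > 0)
  t0 <- min(ts$time_h)
  w <- ts$value[ts$time_h <= t0 + norm_window_h]
  w <- w[!is.na(w)]
  if (length(w) == 0L) abort("No non-missing values in the normalization window.")
  m <- max(w)
  if (!is.finite(m) || abs(m) <= 100 * .Machine$double.eps) {
    abort("Initial-window maximum is (numerically) zero: dead or blank well.")
  }
  ts$value <- ts$value / m
  ts
}

#' Preprocess one well
#'
#' Applies the full fixed-order pipeline
#' `subtract_background()` -> `truncate_initial()` ->
#' `detrend_moving_average()` -> `smooth_moving_average()` ->
#' `normalize_initial_max()`.
#'
#' @param ts A series data frame with columns `time_h`, `value` (raw counts).
#' @param cfg A [preprocess_config()]. If `cfg$background` is
#'   `"from_blanks"`, pass the pooled estimate via `background`; here a bare
#'   series has no plate context, so `"from_blanks"` falls back to 0 with a
#'   warning unless `background` is supplied.
#' @param background Optional scalar overriding `cfg$background`.
#' @return The preprocessed series tibble (normalized units).
#' @export
preprocess_well <- function(ts, cfg = preprocess_config(), background = NULL) {
  stopifnot(inherits(cfg, "preprocess_config"))
  bg <- background %||% cfg$background
  if (identical(bg, "from_blanks")) {
    warn("No plate context for background = \"from_blanks\"; using 0.")
    bg <- 0
  }
  ts |>
    subtract_background(bg) |>
    truncate_initial(cfg$truncate_h) |>
    detrend_moving_average(cfg$detrend_window_h) |>
    smooth_moving_average(cfg$smooth_window_h) |>
    normalize_initial_max(cfg$norm_window_h)
}

#' Preprocess every non-blank well of a plate
#'
#' Resolves the background (scalar, or pooled blank-well median when
#' `cfg$background == "from_blanks"` and blank wells exist, else 0 with a
#' warning) and maps [preprocess_well()] over all non-blank wells.
#'
#' @param rec A [plate_recording()].
#' @param cfg A [preprocess_config()].
#' @return A new [plate_recording()] whose `data` holds the preprocessed
#'   series of the non-blank wells.
#' @export
preprocess_plate <- function(rec, cfg = preprocess_config()) {
  stopifnot(inherits(rec, "plate_recording"))
  bg <- cfg$background
  if (identical(bg, "from_blanks")) {
    if (any(rec$meta$is_blank)) {
      bg <- estimate_background(rec)
    } else {
      warn("No blank wells for background = \"from_blanks\"; using 0.")
      bg <- 0
    }
  }
  wells <- rec$meta$well[!rec$meta$is_blank]
  out <- purrr::map(wells, function(w) {
    pre <- preprocess_well(well_series(rec, w), cfg, background = bg)
    pre$well <- w
    pre
  })
  dat <- dplyr::bind_rows(out)[c("well", "time_h", "value")]
  plate_recording(dat, rec$schedule, meta = rec$meta[!rec$meta$is_blank, ])
}
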