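# Preprocessing stages and their fixed-order composition.

test_that("background subtraction is exact, signed, and identity at zero", {
  ts <- series_tbl(c(0, 0.5), c(10, 12))
  expect_equal(subtract_background(ts, 2)$value, c(8, 10))
  expect_equal(subtract_background(ts, 0)$value, ts$value)
  expect_equal(subtract_background(series_tbl(0:1, c(1, 1)), 5)$value, c(-4, -4))
})

test_that("estimate_background pools the median of blank wells", {
  sched <- standard_schedule()
  mk <- function(vals_by_well, blanks) {
    d <- dplyr::bind_rows(purrr::imap(vals_by_well, function(v, w) {
      tibble::tibble(well = w, time_h = seq_along(v) / 2, value = v)
    }))
    meta <- tibble::tibble(well = names(vals_by_well),
                           is_blank = names(vals_by_well) %in% blanks)
    plate_recording(d, sched, meta = meta)
  }
  expect_equal(estimate_background(mk(list(B1 = c(2, 2, 4), A1 = c(9, 9, 9)), "B1")), 2)
  expect_equal(estimate_background(mk(list(B1 = c(1, 1), B2 = c(3, 3)), c("B1", "B2"))), 2)
  expect_error(estimate_background(mk(list(A1 = c(1, 2)), character())), "scalar")
})

test_that("truncation keeps t >= truncate_h without re-zeroing times", {
  ts <- series_tbl(seq(0, 48, 0.5), rnorm(97))
  out <- truncate_initial(ts, 24)
  expect_equal(nrow(out), 49L)
  expect_equal(out$time_h[1], 24.0)
  expect_equal(truncate_initial(ts, 0), ts)
  expect_error(truncate_initial(ts, 100), "removed every point")
})

test_that("detrending matches the direct windowed-mean oracle", {
  set.seed(11)
  t <- seq(0, 96, 0.5)
  y <- 5 + 0.2 * t + 3 * cos(2 * pi * t / 24) + rnorm(length(t), 0, 0.3)
  out <- detrend_moving_average(series_tbl(t, y), 24)
  expect_equal(out$value, y - oracle_trapz_mean(t, y, 24), tolerance = 1e-12)
})

test_that("detrending removes constants and linear ramps, passes 24-h cosines", {
  t <- seq(0, 96, 0.5)
  expect_true(all(abs(detrend_moving_average(series_tbl(t, rep(7, length(t))), 24)$value) < 1e-12))
  # linear ramp: symmetric-window mean equals the center value -> zero residual
  ramp <- detrend_moving_average(series_tbl(t, 0.7 * t), 24)
  interior <- t >= 12 & t <= 84
  expect_true(all(abs(ramp$value[interior]) < 1e-9))
  # pure 24-h cosine: full-cycle window mean is 0, so interior points unchanged
  y <- cos(2 * pi * t / 24)
  det <- detrend_moving_average(series_tbl(t, y), 24)
  expect_equal(det$value[interior], y[interior], tolerance = 1e-6)
})

test_that("detrend of signal plus any constant equals detrend of signal", {
  set.seed(12)
  t <- sort(runif(150, 0, 80))
  y <- cos(2 * pi * t / 25) + rnorm(150, 0, 0.5)
  a <- detrend_moving_average(series_tbl(t, y), 24)$value
  b <- detrend_moving_average(series_tbl(t, y + 123.4), 24)$value
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("smoothing is a shrinking centered boxcar preserving length and times", {
  ts <- series_tbl(seq(0, 2, 0.5), c(0, 0, 5, 0, 0))
  out <- smooth_moving_average(ts, 2.5)
  expect_equal(out$value[3], 1)
  expect_equal(out$time_h, ts$time_h)
  # window narrower than the sampling interval: identity
  expect_equal(smooth_moving_average(ts, 0.4)$value, ts$value)
  # constants are invariant
  const <- series_tbl(seq(0, 10, 0.5), rep(3, 21))
  expect_equal(smooth_moving_average(const, 2.5)$value, const$value)
  # matches the direct oracle on an uneven grid with gaps
  set.seed(13)
  t <- sort(runif(80, 0, 40))
  v <- rnorm(80)
  v[c(5, 20)] <- NA
  sm <- smooth_moving_average(series_tbl(t, v), 3)
  expect_equal(sm$value, ifelse(is.na(v), NA, oracle_windowed_mean(t, v, 3)))
})

test_that("normalization scales by the initial-window max and is idempotent", {
  t <- seq(0, 48, 0.5)
  v <- 50 * cos(2 * pi * t / 24)
  out <- normalize_initial_max(series_tbl(t, v), 24)
  expect_equal(max(out$value[out$time_h <= 24]), 1.0)
  expect_equal(out$value, v / 50)
  expect_equal(normalize_initial_max(out, 24)$value, out$value)
  expect_error(normalize_initial_max(series_tbl(t, rep(0, length(t))), 24), "dead")
})

test_that("preprocess_well applies the five stages in order", {
  t <- seq(0, 168, 0.5)
  y <- 100 + (5000 * exp(-t / 120)) * (1 + 0.3 * cos(2 * pi * (t - 15) / 24))
  cfg <- preprocess_config(background = 100)
  out <- preprocess_well(series_tbl(t, y), cfg)
  # oracle: the same stages applied one by one
  manual <- series_tbl(t, y) |>
    subtract_background(100) |>
    truncate_initial(24) |>
    detrend_moving_average(24) |>
    smooth_moving_average(2.5) |>
    normalize_initial_max(24)
  expect_equal(out, manual)
  expect_equal(max(out$value[out$time_h <= min(out$time_h) + 24]), 1.0)
  interior <- out$time_h >= 36 & out$time_h <= 156
  expect_lt(abs(mean(out$value[interior])), 0.05)
})

test_that("stage bypass settings reduce preprocess_well to normalization", {
  t <- seq(0, 48, 0.5)
  y <- 10 + 4 * cos(2 * pi * t / 24)
  cfg <- preprocess_config(background = 0, truncate_h = 0,
                           detrend_window_h = 48, smooth_window_h = 0.4)
  out <- preprocess_well(series_tbl(t, y), cfg)
  detr <- y - oracle_trapz_mean(t, y, 48)
  expect_equal(out$value, detr / max(detr[t <= 24]))
})

test_that("preprocessing commutes with time translation", {
  set.seed(14)
  t <- seq(0, 120, 0.5)
  y <- (3000 * exp(-t / 100)) * (1 + 0.3 * cos(2 * pi * t / 25)) + rnorm(length(t), 0, 20)
  cfg <- preprocess_config(background = 0)
  a <- preprocess_well(series_tbl(t, y), cfg)
  b <- preprocess_well(series_tbl(t + 13.25, y),
                       preprocess_config(background = 0, truncate_h = 24 + 13.25))
  expect_equal(b$time_h, a$time_h + 13.25)
  expect_equal(b$value, a$value, tolerance = 1e-9)
})

test_that("preprocess_well preserves timestamps after truncation", {
  set.seed(15)
  t <- seq(0, 96, 0.5)
  v <- 1000 + 200 * cos(2 * pi * t / 24) + rnorm(length(t), 0, 10)
  v[c(30, 31, 100)] <- NA
  out <- preprocess_well(series_tbl(t, v), preprocess_config(background = 0))
  expect_equal(out$time_h, t[t >= 24])
  expect_equal(is.na(out$value), is.na(v[t >= 24]))
})
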