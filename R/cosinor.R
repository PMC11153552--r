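#' Cosinor fit at a fixed period
#'
#' Fits the single-component cosinor model
#' `y(t) = M + A * cos(2*pi*(t - phi)/tau)` with the period `tau` held fixed.
#' With `tau` fixed the model is linear in `(M, beta_c, beta_s)` through
#' `y = M + beta_c*cos(w*t) + beta_s*sin(w*t)`, so the least-squares optimum
#' is found exactly by ordinary least squares -- identical to the optimum an
#' iterative nonlinear fit would converge to, without initialization or
#' convergence concerns. Amplitude and acrophase follow as
#' `A = sqrt(beta_c^2 + beta_s^2)` and
#' `phi = (tau/(2*pi)) * atan2(beta_s, beta_c) mod tau`.
#'
#' @param ts A series data frame with columns `time_h`, `value`; at least 4
#'   non-missing points spanning at least one period.
#' @param period_h The fixed period `tau` in hours.
#' @return A `cosinor_fit` object with elements `mesor`, `amplitude`
#'   (`>= 0`), `acrophase_h` (in `[0, period_h)`), `period_h`, `r_squared`
#'   (`1 - ss_res/ss_tot`; negative values are possible for fits worse than
#'   the mean), `ss_res`, `ss_tot`, `n`.
#' @examples
#' t <- seq(0, 72, 0.5)
#' fit <- cosinor_fit(data.frame(time_h = t,
#'                               value = 10 + 3 * cos(2 * pi * (t - 5) / 24)), 24)
#' glance(fit)
#' @export
cosinor_fit <- function(ts, period_h) {
  ts <- check_series(ts)
  stopifnot(is_scalar_number(period_h), period_h > 0)
  ts <- drop_missing(ts, min_points = 4L, what = "a cosinor fit")
  t <- ts$time_h
  y <- ts$value
  if (max(t) - min(t) < period_h) {
    abort(sprintf("Series span (%.3g h) must cover at least one period (%g h).",
                  max(t) - min(t), period_h))
  }
  ph <- sort(mod_pos(t, period_h))
  n_phases <- 1L + sum(diff(ph) > 1e-9 * period_h)
  if (n_phases < 3L) {
    abort("Degenerate cosinor design: times collapse to fewer than 3 distinct phases.")
  }
  w <- 2 * pi / period_h
  X <- cbind(1, cos(w * t), sin(w * t))
  q <- qr(X)
  if (q$rank < 3L) {
    abort("Degenerate cosinor design: times collapse to fewer than 3 distinct phases.")
  }
  beta <- qr.coef(q, y)
  res <- y - X %*% beta
  ss_res <- sum(res^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(
    list(
      mesor = unname(beta[1L]),
      amplitude = sqrt(beta[2L]^2 + beta[3L]^2),
      acrophase_h = mod_pos(period_h / (2 * pi) * atan2(beta[3L], beta[2L]), period_h),
      period_h = period_h,
      r_squared = 1 - ss_res / ss_tot,
      ss_res = ss_res,
      ss_tot = ss_tot,
      n = length(y)
    ),
    class = "cosinor_fit"
  )
}

#' @export
print.cosinor_fit <- function(x, ...) {
  cat(sprintf(
    "<cosinor_fit> tau = %.4g h | mesor %.4g, amplitude %.4g, acrophase %.4g h, R^2 = %.4f (n = %d)\n",
    x$period_h, x$mesor, x$amplitude, x$acrophase_h, x$r_squared, x$n
  ))
  invisible(x)
}

#' @export
#' @method tidy cosinor_fit
tidy.cosinor_fit <- function(x, ...) {
  tibble::tibble(
    term = c("mesor", "amplitude", "acrophase_h"),
    estimate = c(x$mesor, x$amplitude, x$acrophase_h)
  )
}

#' @export
#' @method glance cosinor_fit
glance.cosinor_fit <- function(x, ...) {
  tibble::tibble(
    period_h = x$period_h, mesor = x$mesor, amplitude = x$amplitude,
    acrophase_h = x$acrophase_h, r_squared = x$r_squared,
    ss_res = x$ss_res, ss_tot = x$ss_tot, n = x$n
  )
}

#' Cosinor fit with the period free within a band
#'
#' Profile search over the period: [cosinor_fit()] (exact for each fixed
#' period) is evaluated on a 0.05-h grid across the band, and the grid optimum
#' is refined by golden-section search on the residual sum of squares to a
#' tolerance of 1e-3 h. Deterministic; no starting value is needed.
#'
#' @param ts A series data frame with columns `time_h`, `value`.
#' @param period_band Search band in hours, default `c(18, 35)`.
#' @param grid_step_h Period grid step for the profile scan (hours).
#' @return A `cosinor_fit` at the residual-minimizing period.
#' @export
cosinor_fit_free <- function(ts, period_band = c(18, 35), grid_step_h = 0.05) {
  stopifnot(length(period_band) == 2L, period_band[1L] < period_band[2L],
            period_band[1L] > 0)
  grid <- seq(period_band[1L], period_band[2L], by = grid_step_h)
  if (tail(grid, 1L) < period_band[2L]) grid <- c(grid, period_band[2L])
  ssr <- vapply(grid, function(p) cosinor_fit(ts, p)$ss_res, numeric(1))
  i <- which.min(ssr)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  ssr_at <- function(p) cosinor_fit(ts, p)$ss_res
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c_ <- b - gr * (b - a); d_ <- a + gr * (b - a)
  fc <- ssr_at(c_); fd <- ssr_at(d_)
  while (b - a > 1e-3) {
    if (fc < fd) {
      b <- d_; d_ <- c_; fd <- fc
      c_ <- b - gr * (b - a); fc <- ssr_at(c_)
    } else {
      a <- c_; c_ <- d_; fc <- fd
      d_ <- a + gr * (b - a); fd <- ssr_at(d_)
    }
  }
  cosinor_fit(ts, (a + b) / 2)
}

rhythm_call <- function(category, period_h, r_squared) {
  tibble::tibble(category = category, period_h = period_h, r_squared = r_squared)
}

#' Rhythmicity classification
#'
#' `classify_synchronized()` applies the entrained-epoch rule: a cosinor fit
#' at a fixed 24-h period on the cyclic-conditions segment is called
#' `"SYNCHRONIZED"` when its R-squared is at least 0.5, else `"ARRHYTHMIC"`.
#'
#' `classify_circadian()` applies the free-run rule: the well's period is
#' taken from the Lomb-Scargle peak, a cosinor is fit at that fixed period,
#' and the well is called `"CIRCADIAN"` when the period lies in the closed
#' band `[18, 35]` h and the R-squared is at least 0.5, else `"ARRHYTHMIC"`.
#' Both thresholds are inclusive. Fixing the cosinor period at the
#' Lomb-Scargle estimate keeps the reported period and the reported
#' R-squared/acrophase/amplitude mutually consistent.
#'
#' @param ts The preprocessed series restricted to the relevant epoch.
#' @param r2_threshold Classification threshold on R-squared (default 0.5).
#' @return A one-row tibble (`category`, `period_h`, `r_squared`); for
#'   `"ARRHYTHMIC"` calls `period_h` is `NA`.
#' @export
classify_synchronized <- function(ts, r2_threshold = 0.5) {
  fit <- cosinor_fit(ts, 24)
  if (fit$r_squared >= r2_threshold) {
    rhythm_call("SYNCHRONIZED", 24, fit$r_squared)
  } else {
    rhythm_call("ARRHYTHMIC", NA_real_, fit$r_squared)
  }
}

#' @rdname classify_synchronized
#' @param period_h The Lomb-Scargle period estimate (hours) for the same
#'   epoch, either a scalar or the one-row tibble from [best_period()].
#' @param period_band Closed period band (hours) for a `"CIRCADIAN"` call.
#' @export
classify_circadian <- function(ts, period_h, period_band = c(18, 35),
                               r2_threshold = 0.5) {
  if (is.data.frame(period_h)) period_h <- period_h$period_h[1L]
  stopifnot(is_scalar_number(period_h))
  fit <- cosinor_fit(ts, period_h)
  in_band <- period_h >= period_band[1L] && period_h <= period_band[2L]
  if (in_band && fit$r_squared >= r2_threshold) {
    rhythm_call("CIRCADIAN", period_h, fit$r_squared)
  } else {
    rhythm_call("ARRHYTHMIC", NA_real_, fit$r_squared)
  }
}
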