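# Fixtures and independent oracles used across the test files.
# Oracles are deliberately brute-force / closed-form and share no code with
# the implementation paths they check.

series_tbl <- function(t, v) tibble::tibble(time_h = t, value = v)

# Cosine convenience: peak at `acrophase` hours, period tau.
cosine_series <- function(t, mesor = 0, amplitude = 1, tau = 24, acrophase = 0) {
  series_tbl(t, mesor + amplitude * cos(2 * pi * (t - acrophase) / tau))
}

# Direct (quadratic-time) centered windowed mean, inclusive edges.
oracle_windowed_mean <- function(t, v, window_h) {
  half <- window_h / 2
  vapply(seq_along(t), function(i) {
    sel <- t >= t[i] - half & t <= t[i] + half & !is.na(v)
    if (!any(sel)) return(NA_real_)
    mean(v[sel])
  }, numeric(1))
}

# Direct trapezoidal windowed mean: integrate the piecewise-linear
# interpolant over the in-window nodes and divide by their span.
oracle_trapz_mean <- function(t, v, window_h) {
  half <- window_h / 2
  vapply(seq_along(t), function(i) {
    sel <- which(t >= t[i] - half & t <= t[i] + half & !is.na(v))
    if (length(sel) == 0L) return(NA_real_)
    if (length(sel) == 1L) return(v[sel])
    tt <- t[sel]
    vv <- v[sel]
    sum((vv[-1] + vv[-length(vv)]) / 2 * diff(tt)) / (tt[length(tt)] - tt[1])
  }, numeric(1))
}

# Least-squares sinusoid sweep: explicit per-frequency regression of the
# mean-centered values on cos(w t), sin(w t) (no intercept); power in the
# Horne-Baliunas convention is the explained sum of squares over 2 * var(y).
oracle_ls_power <- function(t, y, periods) {
  yc <- y - mean(y)
  s2 <- stats::var(y)
  vapply(periods, function(p) {
    w <- 2 * pi / p
    fit <- stats::lm(yc ~ 0 + cos(w * t) + sin(w * t))
    ess <- sum(yc^2) - sum(stats::residuals(fit)^2)
    ess / (2 * s2)
  }, numeric(1))
}

# Classical DFT periodogram, valid at Fourier frequencies of an even grid,
# in the same normalization.
oracle_dft_power <- function(t, y, freqs) {
  yc <- y - mean(y)
  n <- length(y)
  s2 <- stats::var(y)
  vapply(freqs, function(f) {
    w <- 2 * pi * f
    (sum(yc * cos(w * t))^2 + sum(yc * sin(w * t))^2) / (n / 2) / (2 * s2)
  }, numeric(1))
}

# Closed-form cosinor via lm on the cos/sin design (the normal equations).
oracle_cosinor <- function(t, y, tau) {
  w <- 2 * pi / tau
  fit <- stats::lm(y ~ cos(w * t) + sin(w * t))
  b <- unname(stats::coef(fit))
  list(
    mesor = b[1],
    amplitude = sqrt(b[2]^2 + b[3]^2),
    acrophase_h = ((tau / (2 * pi)) * atan2(b[3], b[2])) %% tau,
    r_squared = summary(fit)$r.squared
  )
}

# Monte-Carlo null tail of the Rayleigh resultant length.
oracle_rayleigh_mc <- function(n, R_obs, draws, chunk = 1e5L) {
  hits <- 0L
  done <- 0L
  while (done < draws) {
    m <- min(chunk, draws - done)
    th <- matrix(runif(n * m, 0, 2 * pi), nrow = n)
    R <- sqrt(colMeans(cos(th))^2 + colMeans(sin(th))^2)
    hits <- hits + sum(R >= R_obs)
    done <- done + m
  }
  hits / draws
}

# A small two-group noiseless config for fast deterministic pipeline tests.
noiseless_config <- function(seed = 7L, n_wells = 4L) {
  sim_config(
    seed = seed,
    groups = list(
      group_sim_spec("g1", n_wells, 24, 0, rhythmic_fraction = 1,
                     masking_rel = 0),
      group_sim_spec("g2", n_wells, 26, 0, rhythmic_fraction = 1,
                     masking_rel = 0)
    ),
    noise_model = "NONE", n_blank_wells = 0
  )
}
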