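# Cosinor fitting and rhythmicity classification.

test_that("noiseless model parameters are recovered exactly at fixed period", {
  t <- seq(0, 72, 0.5)
  fit <- cosinor_fit(cosine_series(t, mesor = 10, amplitude = 3,
                                   tau = 24, acrophase = 5), 24)
  expect_equal(fit$mesor, 10, tolerance = 1e-9)
  expect_equal(fit$amplitude, 3, tolerance = 1e-9)
  expect_equal(fit$acrophase_h, 5, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1 - fit$ss_res / fit$ss_tot)
})

test_that("fixed-period fit equals the closed-form OLS oracle under noise", {
  set.seed(31)
  t <- seq(0, 72, 0.5)
  y <- 10 + 3 * cos(2 * pi * (t - 5) / 24) + rnorm(length(t), 0, 0.5)
  fit <- cosinor_fit(series_tbl(t, y), 24)
  orc <- oracle_cosinor(t, y, 24)
  expect_equal(fit$mesor, orc$mesor, tolerance = 1e-10)
  expect_equal(fit$amplitude, orc$amplitude, tolerance = 1e-10)
  expect_equal(fit$acrophase_h, orc$acrophase_h, tolerance = 1e-10)
  expect_equal(fit$r_squared, orc$r_squared, tolerance = 1e-10)
  # sd of the amplitude estimate ~ sigma * sqrt(2/n); 3 sds around truth
  expect_lt(abs(fit$amplitude - 3), 3 * 0.5 * sqrt(2 / length(t)))
  expect_gt(fit$r_squared, 0.9)
})

test_that("white noise yields near-zero R-squared", {
  set.seed(32)
  t <- seq(0, 95.5, 0.5) # n = 192
  r2 <- replicate(20, cosinor_fit(series_tbl(t, rnorm(length(t))), 24)$r_squared)
  expect_true(all(r2 < 0.1))
  # expected value for a 2-regressor fit on noise is about 2/(n-1)
  expect_lt(mean(r2), 5 * 2 / (length(t) - 1))
})

test_that("tidy and glance expose the fit in broom shape", {
  t <- seq(0, 72, 0.5)
  fit <- cosinor_fit(cosine_series(t, 1, 2, 24, 7), 24)
  td <- tidy(fit)
  expect_equal(td$term, c("mesor", "amplitude", "acrophase_h"))
  expect_equal(td$estimate[2], 2, tolerance = 1e-9)
  gl <- glance(fit)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$r_squared, 1, tolerance = 1e-9)
})

test_that("acrophase shifts with the series; amplitude and R2 are invariant", {
  set.seed(33)
  t <- seq(0, 96, 0.5)
  y <- 2 + cos(2 * pi * (t - 8) / 26) + rnorm(length(t), 0, 0.2)
  base <- cosinor_fit(series_tbl(t, y), 26)
  shifted <- cosinor_fit(series_tbl(t + 5, y), 26)
  expect_equal(shifted$acrophase_h, (base$acrophase_h + 5) %% 26, tolerance = 1e-9)
  expect_equal(shifted$amplitude, base$amplitude, tolerance = 1e-9)
  # affine transform of y: R2 invariant, amplitude scales
  aff <- cosinor_fit(series_tbl(t, 4 * y - 7), 26)
  expect_equal(aff$r_squared, base$r_squared, tolerance = 1e-12)
  expect_equal(aff$amplitude, 4 * base$amplitude, tolerance = 1e-9)
  expect_equal(aff$mesor, 4 * base$mesor - 7, tolerance = 1e-9)
})

test_that("free-period profile search recovers noiseless periods to 0.01 h", {
  t <- seq(0, 96, 0.5)
  f26 <- cosinor_fit_free(cosine_series(t, 0, 1, 26, 3))
  expect_lt(abs(f26$period_h - 26), 0.01)
  expect_gte(f26$r_squared, 0.999)
  f24 <- cosinor_fit_free(cosine_series(seq(0, 72, 0.5), 10, 3, 24, 5))
  expect_lt(abs(f24$period_h - 24), 0.01)
})

test_that("free fit never beats the fixed fit at its own period", {
  set.seed(34)
  t <- seq(0, 96, 0.5)
  y <- cos(2 * pi * t / 25.3) + rnorm(length(t), 0, 1)
  free <- cosinor_fit_free(series_tbl(t, y))
  for (tau in c(20, 24, 25.3, 30)) {
    expect_lte(free$ss_res, cosinor_fit(series_tbl(t, y), tau)$ss_res + 1e-9)
  }
})

test_that("free-period recovery under heavy noise matches the CRLB scale", {
  # at noise sd = amplitude, n = 193 and span 96 h the CRLB on the period is
  # about 0.4 h, so most but not all replicates land within 0.5 h
  errs <- vapply(seq_len(50L), function(s) {
    set.seed(300 + s)
    t <- seq(0, 96, 0.5)
    y <- cos(2 * pi * t / 26) + rnorm(length(t), 0, 1)
    abs(cosinor_fit_free(series_tbl(t, y))$period_h - 26)
  }, numeric(1))
  expect_gte(sum(errs <= 0.5), 35L)
  expect_gte(sum(errs <= 1.0), 46L)
})

test_that("degenerate designs are rejected", {
  # all observations at two distinct phases of the fitted period
  t <- c(0, 24, 48, 72, 12, 36)
  expect_error(cosinor_fit(series_tbl(sort(t), rnorm(6)), 24), "[Dd]egenerate")
  expect_error(cosinor_fit(series_tbl(c(0, 1, 2, 3), rnorm(4)), 24), "span")
})

test_that("synchronized classification applies the inclusive 0.5 threshold", {
  t <- seq(0, 71.5, 0.5) # exact Fourier grid: 3 full cycles of 24 h
  clean <- classify_synchronized(cosine_series(t, 0, 1, 24, 15))
  expect_equal(clean$category, "SYNCHRONIZED")
  expect_equal(clean$period_h, 24)

  # mixture of a 24-h cosine and an orthogonal 12-h one whose weights set the
  # fitted R2 exactly (both are Fourier frequencies of the 72-h grid)
  mix <- function(r2) {
    s <- cos(2 * pi * t / 24)
    n <- cos(2 * pi * t / 12)
    sa <- s / sqrt(sum((s - mean(s))^2))
    nb <- n / sqrt(sum((n - mean(n))^2))
    series_tbl(t, sqrt(r2) * sa + sqrt(1 - r2) * nb)
  }
  low <- classify_synchronized(mix(0.49))
  expect_equal(low$category, "ARRHYTHMIC")
  expect_equal(low$r_squared, 0.49, tolerance = 1e-9)
  expect_equal(classify_synchronized(mix(0.52))$category, "SYNCHRONIZED")
  # threshold is inclusive: a fit whose R2 equals the threshold passes
  achieved <- cosinor_fit(mix(0.49), 24)$r_squared
  expect_equal(classify_synchronized(mix(0.49), r2_threshold = achieved)$category,
               "SYNCHRONIZED")
})

test_that("circadian classification needs both in-band period and R2 >= 0.5", {
  t <- seq(72, 168, 0.5)
  rhythmic <- cosine_series(t, 0, 1, 26, 3)
  pg <- lomb_scargle(rhythmic)
  call <- classify_circadian(rhythmic, best_period(pg))
  expect_equal(call$category, "CIRCADIAN")
  expect_lt(abs(call$period_h - 26), 0.5)

  # amplitude-zero well: flat + tiny noise, never circadian
  set.seed(35)
  flat <- series_tbl(t, rnorm(length(t)))
  call2 <- classify_circadian(flat, best_period(lomb_scargle(flat)))
  expect_equal(call2$category, "ARRHYTHMIC")
  expect_true(is.na(call2$period_h))

  # good R2 but period outside the band -> arrhythmic
  call3 <- classify_circadian(rhythmic, 36)
  expect_equal(call3$category, "ARRHYTHMIC")
})
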