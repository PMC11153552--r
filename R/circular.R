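#' Peak phase of a signal within a window
#'
#' Locates the global maximum of the (preprocessed) signal within a time
#' window and expresses it as a phase in hours within the cycle:
#' `(t_peak - anchor) mod cycle_h`. For entrained epochs the natural anchor
#' is ZT0 of the containing cycle (so the phase is the peak's ZT); for the
#' first free-run peak it is the release time. Exact ties go to the earliest
#' peak; a maximum on the first or last available point of the window
#' triggers a boundary warning, since the true peak may lie outside.
#'
#' @param ts A series data frame with columns `time_h`, `value`.
#' @param window Length-2 numeric, `c(start_h, end_h)` of the search window
#'   on the recording axis.
#' @param cycle_h Cycle length in hours (default 24).
#' @param anchor Recording time mapped to phase 0; defaults to
#'   `window[1]`.
#' @return Scalar phase in `[0, cycle_h)`.
#' @export
peak_phase <- function(ts, window, cycle_h = 24, anchor = window[1L]) {
  ts <- check_series(ts)
  stopifnot(length(window) == 2L, window[1L] < window[2L], cycle_h > 0)
  d <- ts[ts$time_h >= window[1L] & ts$time_h <= window[2L] & !is.na(ts$value), ]
  if (nrow(d) == 0L) {
    abort(sprintf("No data in window [%g, %g] h.", window[1L], window[2L]))
  }
  i <- which(d$value == max(d$value))[1L] # tie -> earliest
  if (i == 1L || i == nrow(d)) {
    warn(sprintf("Peak at the window boundary (t = %g h); true maximum may lie outside.",
                 d$time_h[i]))
  }
  mod_pos(d$time_h[i] - anchor, cycle_h)
}

#' Circular mean and resultant length of a set of phases
#'
#' Each phase (hours within a cycle of length `cycle_h`) is mapped to an
#' angle `theta = 2*pi*phase/cycle_h`; the mean resultant vector has length
#' `R = sqrt(C^2 + S^2)` with `C = mean(cos(theta))`, `S = mean(sin(theta))`,
#' and direction `atan2(S, C)`, converted back to hours. `R` runs from 0
#' (uniform / antipodal) to 1 (all phases identical). When `R` is numerically
#' zero the mean direction is undefined and reported as `NA`.
#'
#' @param phases_h Numeric vector of phases in hours.
#' @param cycle_h Cycle length in hours (default 24).
#' @return A one-row tibble: `mean_phase_h`, `resultant_R`, `n`.
#' @export
circular_mean <- function(phases_h, cycle_h = 24) {
  phases_h <- phases_h[!is.na(phases_h)]
  n <- length(phases_h)
  if (n == 0L) abort("Need at least one phase.")
  theta <- 2 * pi * phases_h / cycle_h
  C <- mean(cos(theta))
  S <- mean(sin(theta))
  R <- sqrt(C^2 + S^2)
  mean_phase <- if (R < 1e-9) NA_real_ else mod_pos(cycle_h / (2 * pi) * atan2(S, C), cycle_h)
  tibble::tibble(mean_phase_h = mean_phase, resultant_R = R, n = n)
}

#' Rayleigh test of phase uniformity
#'
#' Tests the null hypothesis that phases are uniform on the circle against
#' unimodal clustering, from the sample size and mean resultant length. Uses
#' Zar's approximation to the null tail probability of `Z = n * R^2`:
#' `p = exp(sqrt(1 + 4n + 4(n^2 - (nR)^2)) - (1 + 2n))`, clipped to
#' `(0, 1]`. The approximation is standard in chronobiology toolkits and is
#' accurate except very near `R = 1` at tiny `n`.
#'
#' @param n Number of phases (`>= 2`).
#' @param R Mean resultant length in `[0, 1]`.
#' @return The p-value.
#' @examples
#' rayleigh_test(37, 0.90) # strong clustering
#' rayleigh_test(100, 0.05) # indistinguishable from uniform
#' @export
rayleigh_test <- function(n, R) {
  stopifnot(n >= 2L, R >= 0, R <= 1)
  Z <- n * R^2
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - (n * R)^2)) - (1 + 2 * n))
  min(max(p, .Machine$double.xmin), 1)
}

#' Critical resultant length for the Rayleigh test
#'
#' Smallest `R` at which the Rayleigh test rejects at level `alpha` for a
#' given sample size (the radius of the significance circle on a Rayleigh
#' plot). Found by bisection on [rayleigh_test()] to 1e-6; for large `n` it
#' approaches `sqrt(-log(alpha)/n)`.
#'
#' @param n Number of phases (`>= 2`).
#' @param alpha Significance level in `(0, 1)` (default 0.05).
#' @return The critical `R` in `(0, 1)`.
#' @export
rayleigh_critical_R <- function(n, alpha = 0.05) {
  stopifnot(n >= 2L, alpha > 0, alpha < 1)
  lo <- 0
  hi <- 1
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (rayleigh_test(n, mid) <= alpha) hi <- mid else lo <- mid
  }
  hi
}

#' Circular summary of a phase set
#'
#' Convenience wrapper combining [circular_mean()] and [rayleigh_test()]:
#' the one-stop summary behind Rayleigh plots (mean vector angle, vector
#' length, and the p = `alpha` significance circle).
#'
#' @inheritParams circular_mean
#' @return One-row tibble: `mean_phase_h`, `resultant_R`, `n`, `rayleigh_p`
#'   (`NA` when `n < 2`).
#' @export
circular_summary <- function(phases_h, cycle_h = 24) {
  cm <- circular_mean(phases_h, cycle_h)
  cm$rayleigh_p <- if (cm$n >= 2L) rayleigh_test(cm$n, cm$resultant_R) else NA_real_
  cm
}

#' Rayleigh plot of a phase set
#'
#' Polar scatter of individual phases with the group mean vector and the
#' critical circle for the Rayleigh test at level `alpha`.
#'
#' @param phases A data frame with columns `phase_h` and optionally `group`.
#' @param cycle_h Cycle length in hours.
#' @param alpha Level of the significance circle.
#' @return A ggplot object.
#' @export
plot_rayleigh <- function(phases, cycle_h = 24, alpha = 0.05) {
  stopifnot(is.data.frame(phases), "phase_h" %in% names(phases))
  phases <- tibble::as_tibble(phases)
  if (!"group" %in% names(phases)) phases$group <- "all"
  phases <- phases[!is.na(phases$phase_h), ]
  summ <- phases |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(circular_summary(.data$phase_h, cycle_h), .groups = "drop")
  crit <- rayleigh_critical_R(max(2L, nrow(phases)), alpha)
  ggplot2::ggplot(phases, ggplot2::aes(x = .data$phase_h, colour = .data$group)) +
    ggplot2::geom_point(ggplot2::aes(y = 1.05), alpha = 0.8) +
    ggplot2::geom_segment(
      data = summ,
      ggplot2::aes(x = .data$mean_phase_h, xend = .data$mean_phase_h,
                   y = 0, yend = .data$resultant_R, colour = .data$group),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.15, "in"))
    ) +
    ggplot2::geom_hline(yintercept = crit, linetype = 2) +
    ggplot2::coord_polar(start = 0, direction = 1) +
    ggplot2::scale_x_continuous(limits = c(0, cycle_h),
                                breaks = seq(0, cycle_h, by = cycle_h / 4)) +
    ggplot2::scale_y_continuous(limits = c(0, 1.1)) +
    ggplot2::labs(x = "Phase (h)", y = "Resultant length R") +
    ggplot2::theme_minimal()
}
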