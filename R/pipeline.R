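#' End-to-end analysis of a plate recording
#'
#' Runs the full per-well analysis of the study design: preprocessing of the
#' whole trace (the detrend window may straddle the release boundary), then
#' epoch-wise analysis. On the cyclic (entrained) segment, if any, the well
#' is classified Synchronized/Arrhythmic by a fixed 24-h cosinor; on the
#' free-run segment the period is estimated by the Lomb-Scargle peak within
#' the circadian band and the well is classified Circadian/Arrhythmic by a
#' cosinor at that period. Peak phases are extracted for the last full cyclic
#' day (anchored at ZT0, i.e. the phase is the peak's ZT) and for the first
#' 26 h after release (anchored at the release time; the extra 2 h beyond
#' one cycle catches late first peaks of long-period genotypes).
#'
#' Blank wells are excluded. Wells whose preprocessing or fitting fails are
#' reported with `status = "error"` and the message, never dropped silently.
#'
#' @param rec A [plate_recording()]. Its schedule must contain a free-run
#'   epoch spanning at least 2 days.
#' @param pre_cfg A [preprocess_config()].
#' @param period_min_h,period_max_h,ofac Periodogram band and oversampling,
#'   see [lomb_scargle()].
#' @param r2_threshold Classification threshold on cosinor R-squared.
#' @param keep_periodograms If `TRUE`, attach the per-well periodograms as
#'   attribute `"periodograms"` (a named list) to the result.
#' @return A tibble with one row per non-blank well: `well`, `group`,
#'   `status`, `message`, `sync_category`, `sync_r_squared`,
#'   `circadian_category`, `circadian_r_squared`, `fr_period_h` (the
#'   Lomb-Scargle estimate, present only for `"CIRCADIAN"` wells),
#'   `ls_peak_power`, `fr_amplitude`, `fr_acrophase_h`, `phase_ldcw_h`,
#'   `phase_fr_h`.
#' @examples
#' sim <- simulate_plate(default_study_config(seed = 1))
#' res <- analyze_recording(sim$recording)
#' summarize_groups(res)
#' @export
analyze_recording <- function(rec, pre_cfg = preprocess_config(),
                              period_min_h = 18, period_max_h = 35, ofac = 30,
                              r2_threshold = 0.5, keep_periodograms = FALSE) {
  stopifnot(inherits(rec, "plate_recording"))
  sched <- rec$schedule
  fr <- schedule_freerun_epoch(sched)
  if (is.null(fr)) abort("Schedule must contain a FREE_RUN epoch.")
  if (fr$end_h - fr$start_h < 48) {
    abort("FREE_RUN epoch must span at least 2 days for period estimation.")
  }
  series_span <- range(rec$data$time_h)
  if (fr$start_h >= series_span[2L]) {
    abort("Schedule/series mismatch: the free-run epoch starts after the data end.")
  }
  cyc <- schedule_cyclic_epoch(sched)

  bg <- pre_cfg$background
  if (identical(bg, "from_blanks")) {
    if (any(rec$meta$is_blank)) {
      bg <- estimate_background(rec)
    } else {
      warn("No blank wells for background = \"from_blanks\"; using 0.")
      bg <- 0
    }
  }

  wells <- rec$meta$well[!rec$meta$is_blank]
  groups <- rec$meta$group[!rec$meta$is_blank]
  pgs <- list()

  one_well <- function(w, grp) {
    row <- tibble::tibble(
      well = w, group = grp, status = "ok", message = NA_character_,
      sync_category = NA_character_, sync_r_squared = NA_real_,
      circadian_category = NA_character_, circadian_r_squared = NA_real_,
      fr_period_h = NA_real_, ls_peak_power = NA_real_,
      fr_amplitude = NA_real_, fr_acrophase_h = NA_real_,
      phase_ldcw_h = NA_real_, phase_fr_h = NA_real_
    )
    tryCatch({
      pre <- preprocess_well(well_series(rec, w), pre_cfg, background = bg)
      if (!is.null(cyc)) {
        cyc_seg <- pre[pre$time_h >= cyc$start_h & pre$time_h < cyc$end_h, ]
        sync <- classify_synchronized(cyc_seg, r2_threshold = r2_threshold)
        row$sync_category <- sync$category
        row$sync_r_squared <- sync$r_squared
        # peak phase on the last full cyclic day, as ZT
        wnd <- c(cyc$end_h - cyc$zeitgeber_period, cyc$end_h)
        anchor <- sched$zt0_recording_offset +
          cyc$zeitgeber_period * floor((wnd[1L] - sched$zt0_recording_offset) /
                                         cyc$zeitgeber_period)
        row$phase_ldcw_h <- suppressWarnings(
          peak_phase(pre, wnd, cycle_h = cyc$zeitgeber_period, anchor = anchor)
        )
      }
      fr_seg <- pre[pre$time_h >= fr$start_h & pre$time_h <= fr$end_h, ]
      pg <- lomb_scargle(fr_seg, period_min_h = period_min_h,
                         period_max_h = period_max_h, ofac = ofac)
      if (keep_periodograms) pgs[[w]] <<- pg
      est <- best_period(pg)
      circ <- classify_circadian(fr_seg, est, period_band = c(period_min_h, period_max_h),
                                 r2_threshold = r2_threshold)
      row$circadian_category <- circ$category
      row$circadian_r_squared <- circ$r_squared
      row$ls_peak_power <- est$peak_power
      if (circ$category == "CIRCADIAN") {
        row$fr_period_h <- circ$period_h
        fit <- cosinor_fit(fr_seg, circ$period_h)
        row$fr_amplitude <- fit$amplitude
        row$fr_acrophase_h <- fit$acrophase_h
      }
      row$phase_fr_h <- suppressWarnings(
        peak_phase(pre, c(fr$start_h, min(fr$start_h + 26, fr$end_h)),
                   cycle_h = 24, anchor = fr$start_h)
      )
      row
    }, error = function(e) {
      row$status <- "error"
      row$message <- conditionMessage(e)
      row
    })
  }

  res <- purrr::map2(wells, groups, one_well) |> dplyr::bind_rows()
  if (keep_periodograms) attr(res, "periodograms") <- pgs
  res
}

#' Group-level summaries
#'
#' Aggregates per-well results into the descriptive statistics reported for
#' luminescence experiments: number of analyzable wells, number and
#' percentage rhythmic (Circadian in free run), mean +/- SEM of the free-run
#' period over rhythmic wells only (SEM = sample SD / sqrt(n), undefined at
#' n = 1), and circular summaries (mean phase, resultant length, Rayleigh p)
#' of the entrained-epoch and first-free-run peak phases. Phase summaries,
#' like period statistics, cover rhythmic wells only: a peak time read off an
#' arrhythmic trace is noise, and Rayleigh plots in luminescence studies are
#' drawn for rhythmic populations.
#'
#' @param results Tibble from [analyze_recording()].
#' @param cycle_h Cycle length for the circular phase summaries.
#' @return A tibble with one row per group: `group`, `n_total`,
#'   `n_rhythmic`, `percent_rhythmic`, `period_mean_h`, `period_sem_h`,
#'   `ldcw_n`, `ldcw_mean_phase_h`, `ldcw_R`, `ldcw_p`, `fr_n`,
#'   `fr_mean_phase_h`, `fr_R`, `fr_p`.
#' @export
summarize_groups <- function(results, cycle_h = 24) {
  stopifnot(is.data.frame(results), nrow(results) >= 1L)
  phase_block <- function(ph, prefix) {
    ph <- ph[!is.na(ph)]
    out <- tibble::tibble(n = length(ph), mean_phase_h = NA_real_,
                          R = NA_real_, p = NA_real_)
    if (length(ph) >= 1L) {
      cs <- circular_summary(ph, cycle_h)
      out$mean_phase_h <- cs$mean_phase_h
      out$R <- cs$resultant_R
      out$p <- cs$rayleigh_p
    }
    names(out) <- paste0(prefix, "_", c("n", "mean_phase_h", "R", "p"))
    out
  }
  results |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(function(d, key) {
      ok <- d[d$status == "ok", ]
      rhythmic_rows <- ok[ok$circadian_category %in% "CIRCADIAN", ]
      rhythmic <- rhythmic_rows$fr_period_h
      n_r <- length(rhythmic)
      dplyr::bind_cols(
        tibble::tibble(
          n_total = nrow(ok),
          n_rhythmic = n_r,
          percent_rhythmic = if (nrow(ok) > 0L) 100 * n_r / nrow(ok) else NA_real_,
          period_mean_h = if (n_r >= 1L) mean(rhythmic) else NA_real_,
          period_sem_h = if (n_r >= 2L) stats::sd(rhythmic) / sqrt(n_r) else NA_real_
        ),
        phase_block(rhythmic_rows$phase_ldcw_h, "ldcw"),
        phase_block(rhythmic_rows$phase_fr_h, "fr")
      )
    }) |>
    dplyr::ungroup()
}

#' Plot preprocessed or raw well traces
#'
#' Faceted time-series plot of selected wells with the free-run release
#' marked, for quick visual QC of traces and classifications.
#'
#' @param rec A [plate_recording()].
#' @param wells Character vector of wells to show (default: first 6
#'   non-blank).
#' @return A ggplot object.
#' @export
plot_well_traces <- function(rec, wells = NULL) {
  stopifnot(inherits(rec, "plate_recording"))
  if (is.null(wells)) wells <- head(rec$meta$well[!rec$meta$is_blank], 6L)
  d <- rec$data[rec$data$well %in% wells, ]
  fr <- schedule_freerun_epoch(rec$schedule)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$time_h, y = .data$value)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(~well, scales = "free_y") +
    ggplot2::labs(x = "Time (h since recording start)", y = "Luminescence") +
    ggplot2::theme_minimal()
  if (!is.null(fr) && fr$start_h > min(d$time_h)) {
    p <- p + ggplot2::geom_vline(xintercept = fr$start_h, linetype = 2)
  }
  p
}
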