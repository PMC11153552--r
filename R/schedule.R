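#' Protocol schedules: zeitgeber epochs and the ZT coordinate system
#'
#' A protocol schedule describes the experimental light/temperature program of
#' a recording as an ordered sequence of epochs, each either `"CYCLIC"` (a
#' zeitgeber cycle is imposed, e.g. 12:12 h light-dark plus cold-warm) or
#' `"FREE_RUN"` (constant darkness and temperature). The schedule, not the
#' data, anchors Zeitgeber Time: `zt0_recording_offset` is the recording time
#' (hours) at which ZT0 -- lights-on and cold-phase onset -- of the first cycle
#' falls. All analysis functions take time in decimal hours since the start of
#' the recording; the schedule converts between that axis and ZT.
#'
#' @param epochs A data frame with one row per epoch and columns `start_h`,
#'   `end_h`, `regime` (`"CYCLIC"` or `"FREE_RUN"`), and optionally
#'   `zeitgeber_period` (default 24), `lights_on_zt` (default 0) and
#'   `lights_off_zt` (default 12).
#' @param zt0_recording_offset Recording time (hours) of ZT0 of the first
#'   cycle. Default 0: the recording starts at lights-on.
#' @return A `protocol_schedule` object: a list with elements
#'   `zt0_recording_offset` (scalar hours) and `epochs` (a tibble).
#' @examples
#' sched <- standard_schedule(cyclic_days = 3, freerun_days = 4)
#' recording_time_to_zt(c(0, 36, 75.5), sched)
#' @export
protocol_schedule <- function(epochs, zt0_recording_offset = 0) {
  if (!is.data.frame(epochs) || !all(c("start_h", "end_h", "regime") %in% names(epochs))) {
    abort("`epochs` must be a data frame with columns `start_h`, `end_h`, `regime`.")
  }
  ep <- tibble::as_tibble(epochs)
  if (!"zeitgeber_period" %in% names(ep)) ep$zeitgeber_period <- 24
  if (!"lights_on_zt" %in% names(ep)) ep$lights_on_zt <- 0
  if (!"lights_off_zt" %in% names(ep)) ep$lights_off_zt <- 12
  ep <- ep[order(ep$start_h), c("start_h", "end_h", "regime", "zeitgeber_period",
                                "lights_on_zt", "lights_off_zt")]
  if (!all(ep$regime %in% c("CYCLIC", "FREE_RUN"))) {
    abort("Epoch `regime` must be \"CYCLIC\" or \"FREE_RUN\".")
  }
  if (any(ep$start_h >= ep$end_h)) abort("Each epoch needs `start_h` < `end_h`.")
  if (nrow(ep) > 1L && any(ep$start_h[-1L] < ep$end_h[-nrow(ep)])) {
    abort("Epochs must not overlap.")
  }
  if (nrow(ep) > 1L && any(abs(ep$start_h[-1L] - ep$end_h[-nrow(ep)]) > 1e-9)) {
    abort("Epochs must cover a contiguous span (no gaps).")
  }
  if (any(ep$zeitgeber_period <= 0)) abort("`zeitgeber_period` must be positive.")
  bad <- ep$lights_on_zt < 0 | ep$lights_on_zt >= ep$lights_off_zt |
    ep$lights_off_zt > ep$zeitgeber_period
  if (any(bad)) abort("Need 0 <= lights_on_zt < lights_off_zt <= zeitgeber_period.")
  if (!is_scalar_number(zt0_recording_offset)) {
    abort("`zt0_recording_offset` must be a single finite number.")
  }
  structure(
    list(zt0_recording_offset = zt0_recording_offset, epochs = ep),
    class = "protocol_schedule"
  )
}

#' @rdname protocol_schedule
#' @param cyclic_days Days of entrainment (12:12 zeitgeber cycles) at the start
#'   of the recording; 0 for a constant-conditions-only protocol.
#' @param freerun_days Days of constant conditions after release.
#' @param zeitgeber_period Zeitgeber cycle length in hours.
#' @export
standard_schedule <- function(cyclic_days = 3, freerun_days = 4,
                              zeitgeber_period = 24, zt0_recording_offset = 0) {
  stopifnot(cyclic_days >= 0, freerun_days > 0)
  t_release <- cyclic_days * zeitgeber_period
  ep <- list()
  if (cyclic_days > 0) {
    ep[[1L]] <- tibble::tibble(start_h = 0, end_h = t_release, regime = "CYCLIC")
  }
  ep[[length(ep) + 1L]] <- tibble::tibble(
    start_h = t_release, end_h = t_release + freerun_days * 24, regime = "FREE_RUN"
  )
  protocol_schedule(dplyr::bind_rows(ep), zt0_recording_offset = zt0_recording_offset)
}

#' @export
print.protocol_schedule <- function(x, ...) {
  cat("<protocol_schedule> ZT0 at recording hour", x$zt0_recording_offset, "\n")
  print(x$epochs, ...)
  invisible(x)
}

#' Convert recording time to Zeitgeber Time
#'
#' ZT is the hour within the imposed zeitgeber cycle, with ZT0 at lights-on /
#' cold-phase onset: `ZT = (t - zt0_recording_offset) mod zeitgeber_period`.
#' During free-run epochs the same formula gives the *projected* ZT (useful for
#' plotting against the prior cycle); it does not reflect the endogenous phase.
#'
#' @param t Recording time(s), hours since start of recording.
#' @param schedule A [protocol_schedule()].
#' @return ZT hours in `[0, zeitgeber_period)`, same length as `t`.
#' @export
recording_time_to_zt <- function(t, schedule) {
  stopifnot(inherits(schedule, "protocol_schedule"))
  period <- schedule$epochs$zeitgeber_period[1L]
  mod_pos(t - schedule$zt0_recording_offset, period)
}

# First CYCLIC epoch (or NULL) and first FREE_RUN epoch (or NULL).
schedule_cyclic_epoch <- function(schedule) {
  ep <- schedule$epochs[schedule$epochs$regime == "CYCLIC", ]
  if (nrow(ep) == 0L) NULL else ep[1L, ]
}

schedule_freerun_epoch <- function(schedule) {
  ep <- schedule$epochs[schedule$epochs$regime == "FREE_RUN", ]
  if (nrow(ep) == 0L) NULL else ep[1L, ]
}

#' Read or write a protocol schedule as JSON
#'
#' The on-disk format is a JSON object with keys `zt0_recording_offset` and
#' `epochs`, the latter an array of objects with keys `start_h`, `end_h`,
#' `regime`, `zeitgeber_period`, `lights_on_zt`, `lights_off_zt`.
#'
#' @param path File path.
#' @return `read_schedule_json()` returns a [protocol_schedule()];
#'   `write_schedule_json()` returns `path` invisibly.
#' @export
read_schedule_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$epochs)) abort("Schedule JSON must contain an `epochs` array.")
  protocol_schedule(
    tibble::as_tibble(x$epochs),
    zt0_recording_offset = x$zt0_recording_offset %||% 0
  )
}

#' @rdname read_schedule_json
#' @param schedule A [protocol_schedule()].
#' @export
write_schedule_json <- function(schedule, path) {
  stopifnot(inherits(schedule, "protocol_schedule"))
  jsonlite::write_json(
    list(
      zt0_recording_offset = schedule$zt0_recording_offset,
      epochs = schedule$epochs
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
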