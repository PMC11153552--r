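#' Plate recordings
#'
#' A plate recording bundles the per-well luminescence series of one
#' luminometer run with per-well metadata and the protocol schedule. The data
#' live in a long tibble (`well`, `time_h`, `value`); metadata is one row per
#' well (`well`, `plate_id`, `group`, `n_worms`, `is_blank`). Blank wells
#' (`is_blank = TRUE`) carry background signal only and are excluded from
#' rhythm analysis.
#'
#' @param data A data frame with columns `well`, `time_h`, `value`. `NA`
#'   values mark missing readings; times must be strictly increasing within
#'   each well and duplicates are an error.
#' @param schedule A [protocol_schedule()].
#' @param meta Optional data frame with column `well` and any of `plate_id`,
#'   `group`, `n_worms`, `is_blank`; missing columns are filled with defaults.
#' @return A `plate_recording` object: list with elements `data` (tibble),
#'   `meta` (tibble) and `schedule`, plus attribute-like element
#'   `nominal_interval` (hours, the median sampling step).
#' @examples
#' sched <- standard_schedule()
#' dat <- tidyr::expand_grid(well = c("A1", "A2"), time_h = seq(0, 168, 0.5))
#' dat$value <- 5000 + 100 * cos(2 * pi * dat$time_h / 24)
#' rec <- plate_recording(dat, sched)
#' rec
#' @export
plate_recording <- function(data, schedule, meta = NULL) {
  stopifnot(inherits(schedule, "protocol_schedule"))
  if (!is.data.frame(data) || !all(c("well", "time_h", "value") %in% names(data))) {
    abort("`data` must have columns `well`, `time_h`, `value`.")
  }
  data <- tibble::as_tibble(data)[c("well", "time_h", "value")]
  data$well <- as.character(data$well)
  data$time_h <- as.numeric(data$time_h)
  data$value <- as.numeric(data$value)
  data <- dplyr::arrange(data, .data$well, .data$time_h)
  dup <- duplicated(data[c("well", "time_h")])
  if (any(dup)) {
    d <- data[dup, ][1L, ]
    abort(sprintf(
      "Duplicate timestamp within a well: well \"%s\" at time_h = %g.",
      d$well, d$time_h
    ))
  }
  wells <- unique(data$well)
  base_meta <- tibble::tibble(
    well = wells, plate_id = "plate1", group = NA_character_,
    n_worms = NA_integer_, is_blank = FALSE
  )
  if (!is.null(meta)) {
    meta <- tibble::as_tibble(meta)
    if (!"well" %in% names(meta)) abort("`meta` must have a `well` column.")
    meta$well <- as.character(meta$well)
    extra <- setdiff(meta$well, wells)
    if (length(extra) > 0L) {
      warn(sprintf("Dropping meta rows for wells absent from data: %s",
                   paste(extra, collapse = ", ")))
    }
    for (col in intersect(c("plate_id", "group", "n_worms", "is_blank"), names(meta))) {
      idx <- match(base_meta$well, meta$well)
      filled <- meta[[col]][idx]
      base_meta[[col]][!is.na(idx)] <- filled[!is.na(idx)]
    }
  }
  base_meta$is_blank <- !is.na(base_meta$is_blank) & as.logical(base_meta$is_blank)
  if (any(!is.na(base_meta$n_worms) & base_meta$n_worms < 0)) {
    abort("`n_worms` must be non-negative.")
  }
  dt <- diff(data$time_h[data$well == wells[1L]])
  nominal <- if (length(dt) > 0L) stats::median(dt) else 0.5
  structure(
    list(data = data, meta = base_meta, schedule = schedule,
         nominal_interval = nominal),
    class = "plate_recording"
  )
}

#' @export
print.plate_recording <- function(x, ...) {
  nb <- sum(x$meta$is_blank)
  cat(sprintf(
    "<plate_recording> %d wells (%d blank), %d timepoints each on average, %.2g-h sampling\n",
    nrow(x$meta), nb, round(nrow(x$data) / max(1L, nrow(x$meta))), x$nominal_interval
  ))
  print(x$schedule)
  invisible(x)
}

# Extract one well's series as a tibble(time_h, value).
well_series <- function(rec, well) {
  d <- rec$data[rec$data$well == well, c("time_h", "value")]
  if (nrow(d) == 0L) abort(sprintf("Well \"%s\" not present in recording.", well))
  d
}

#' Read a plate-luminometer CSV
#'
#' Two dialects are auto-detected from the header. Long format has columns
#' `time_h`, `well`, `value` and optionally `group`, `n_worms`, `is_blank`;
#' wide format has a first column `time_h` and one column per well. Cells that
#' do not parse as numbers become missing readings (`NA`) without changing the
#' series length.
#'
#' @param path CSV file path.
#' @param schedule The [protocol_schedule()] of the recording (zeitgeber
#'   timing is experimental metadata and is supplied, never inferred).
#' @return A [plate_recording()].
#' @export
read_plate_csv <- function(path, schedule) {
  hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  if (all(c("time_h", "well", "value") %in% hdr)) {
    raw <- readr::read_csv(
      path,
      col_types = readr::cols(
        time_h = readr::col_double(), well = readr::col_character(),
        .default = readr::col_character()
      ),
      show_col_types = FALSE
    )
    raw$value <- suppressWarnings(as.numeric(raw$value))
    meta_cols <- intersect(c("plate_id", "group", "n_worms", "is_blank"), hdr)
    meta <- NULL
    if (length(meta_cols) > 0L) {
      meta <- dplyr::distinct(raw[c("well", meta_cols)])
      if (anyDuplicated(meta$well)) {
        abort("Per-well metadata columns must be constant within each well.")
      }
      if ("n_worms" %in% names(meta)) meta$n_worms <- as.integer(meta$n_worms)
      if ("is_blank" %in% names(meta)) {
        meta$is_blank <- tolower(meta$is_blank) %in% c("true", "t", "1", "yes")
      }
    }
    plate_recording(raw[c("well", "time_h", "value")], schedule, meta = meta)
  } else if (hdr[1L] == "time_h" && length(hdr) >= 2L) {
    raw <- readr::read_csv(
      path,
      col_types = readr::cols(time_h = readr::col_double(),
                              .default = readr::col_character()),
      show_col_types = FALSE
    )
    long <- tidyr::pivot_longer(raw, -"time_h", names_to = "well", values_to = "value")
    long$value <- suppressWarnings(as.numeric(long$value))
    plate_recording(long[c("well", "time_h", "value")], schedule)
  } else {
    abort(paste0(
      "Unrecognized plate CSV layout. Accepted layouts:\n",
      "  long: header time_h,well,value[,group,n_worms,is_blank]\n",
      "  wide: header time_h,<well1>,<well2>,..."
    ))
  }
}

#' Write a plate recording to CSV
#'
#' Writes the long dialect (with metadata columns) so that
#' `read_plate_csv(write_plate_csv(rec, path), schedule)` reproduces the
#' recording bit-exactly on times, values, and metadata. Missing readings are
#' written as `NA`.
#'
#' @param rec A [plate_recording()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_plate_csv <- function(rec, path) {
  stopifnot(inherits(rec, "plate_recording"))
  out <- dplyr::left_join(rec$data, rec$meta, by = "well")
  out <- out[c("time_h", "well", "value", "plate_id", "group", "n_worms", "is_blank")]
  readr::write_csv(out, path, na = "NA")
  invisible(path)
}
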