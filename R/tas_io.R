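#' Construct a minute-resolution TAC series
#'
#' The canonical container for one participant's sensor stream: transdermal
#' alcohol concentration (TAC, ug/L) and skin temperature (degrees C) at a
#' 1-minute cadence. Timestamps are timezone-naive local clock time,
#' truncated (floored) to whole minutes; gaps are permitted and represent
#' minutes the device did not report.
#'
#' @param timestamp POSIXct (or coercible) sample times; seconds are floored
#'   to the minute.
#' @param tac_raw TAC in ug/L as recorded; negative values are allowed here
#'   and handled by [clamp_negative()].
#' @param temp Skin temperature in degrees C.
#' @param participant_id,device_id Opaque identifiers.
#' @return A `tac_series`: a tibble with columns `timestamp`, `minute`
#'   (integer epoch minute), `tac_raw`, `temp`, ordered and unique in time,
#'   carrying `participant_id` and `device_id` attributes.
#' @export
#' @examples
#' t0 <- as.POSIXct("2023-07-03 10:00:00", tz = "UTC")
#' tac_series(t0 + 60 * (0:2), c(-1, 0, 12), c(33, 33, 33))
tac_series <- function(timestamp, tac_raw, temp,
                       participant_id = "P1", device_id = NA_character_) {
  timestamp <- as.POSIXct(timestamp, tz = .TZ)
  n <- length(timestamp)
  if (length(tac_raw) != n || length(temp) != n) {
    .stopf("timestamp, tac_raw and temp must have equal length")
  }
  if (n > 0 && (anyNA(timestamp) || anyNA(tac_raw) || anyNA(temp) ||
                any(!is.finite(tac_raw)) || any(!is.finite(temp)))) {
    .stopf("tac_series values must be finite and non-missing")
  }
  minute <- .epoch_min(timestamp)
  if (anyDuplicated(minute)) {
    .stopf("duplicate minute timestamps; collapse them before construction")
  }
  ord <- order(minute)
  out <- tibble::tibble(
    timestamp = .min_to_time(minute[ord]),
    minute = minute[ord],
    tac_raw = as.numeric(tac_raw)[ord],
    temp = as.numeric(temp)[ord]
  )
  attr(out, "participant_id") <- participant_id
  attr(out, "device_id") <- device_id
  class(out) <- c("tac_series", class(out))
  out
}

#' @export
print.tac_series <- function(x, ...) {
  cat(sprintf("<tac_series> participant %s, %d samples\n",
              attr(x, "participant_id"), nrow(x)))
  NextMethod()
}

#' Default CSV column dialect for TAC exports
#'
#' The vendor export schema is not standardized, so readers take a
#' column-name mapping. This is the package's canonical dialect.
#'
#' @param timestamp,tac,temp Column names in the file.
#' @param time_format strptime format for the timestamp column.
#' @return A named list usable as the `dialect` argument of [read_tac_csv()].
#' @export
tac_dialect <- function(timestamp = "timestamp", tac = "tac_ug_L",
                        temp = "temp_C", time_format = "%Y-%m-%d %H:%M:%S") {
  list(timestamp = timestamp, tac = tac, temp = temp,
       time_format = time_format)
}

#' Read a TAC series from delimited text
#'
#' Rows are sorted by time and timestamps truncated to minute resolution.
#' When two rows share a minute the last one is kept and a warning reports
#' how many were collapsed; no other data are ever dropped silently.
#'
#' @param path File path.
#' @param dialect Column mapping from [tac_dialect()].
#' @param participant_id,device_id Identifiers attached to the result.
#' @return A [tac_series()].
#' @export
read_tac_csv <- function(path, dialect = tac_dialect(),
                         participant_id = "P1", device_id = NA_character_) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L) .stopf("empty TAC file: %s", path)
  need <- c(dialect$timestamp, dialect$tac, dialect$temp)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    .stopf("missing columns in %s: %s", path,
           paste(missing_cols, collapse = ", "))
  }
  ts <- as.POSIXct(df[[dialect$timestamp]], tz = .TZ,
                   format = dialect$time_format)
  tac <- suppressWarnings(as.numeric(df[[dialect$tac]]))
  temp <- suppressWarnings(as.numeric(df[[dialect$temp]]))
  bad <- which(is.na(ts) | is.na(tac) | is.na(temp))
  if (length(bad)) {
    .stopf("unparseable rows in %s (data lines %s)", path,
           paste(bad, collapse = ", "))
  }
  minute <- .epoch_min(ts)
  ord <- order(minute, seq_along(minute))  # stable: later file rows win ties
  minute <- minute[ord]; tac <- tac[ord]; temp <- temp[ord]
  dup <- duplicated(minute, fromLast = TRUE)
  if (any(dup)) {
    warning(sprintf("%d duplicate-minute row(s) collapsed (kept last) in %s",
                    sum(dup), path), call. = FALSE)
    minute <- minute[!dup]; tac <- tac[!dup]; temp <- temp[!dup]
  }
  tac_series(.min_to_time(minute), tac, temp,
             participant_id = participant_id, device_id = device_id)
}

#' Write a TAC series as CSV in the canonical dialect
#'
#' @param series A [tac_series()].
#' @param path Output path.
#' @param dialect Column mapping, as for [read_tac_csv()].
#' @return `path`, invisibly.
#' @export
write_tac_csv <- function(series, path, dialect = tac_dialect()) {
  stopifnot(inherits(series, "tac_series"))
  df <- data.frame(
    format(series$timestamp, dialect$time_format, tz = .TZ),
    series$tac_raw,
    series$temp,
    check.names = FALSE
  )
  names(df) <- c(dialect$timestamp, dialect$tac, dialect$temp)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Construct TLFB day records
#'
#' Timeline-followback self-report: one row per calendar day with the UK
#' alcohol units consumed (1 unit = 8 g ethanol). A day counts as a TLFB
#' drinking day exactly when `units > 0`.
#'
#' @param date Dates (coercible with `as.Date`).
#' @param units Non-negative units per day.
#' @return A tibble with columns `date`, `units`, `drinking` (logical).
#' @export
tlfb_days <- function(date, units) {
  date <- as.Date(date)
  units <- as.numeric(units)
  if (length(date) != length(units)) .stopf("date and units lengths differ")
  if (anyNA(date) || anyNA(units)) .stopf("TLFB records must be complete")
  if (any(units < 0)) .stopf("TLFB units must be non-negative")
  if (anyDuplicated(date)) {
    .stopf("duplicate TLFB dates: %s",
           paste(unique(date[duplicated(date)]), collapse = ", "))
  }
  ord <- order(date)
  tibble::tibble(date = date[ord], units = units[ord],
                 drinking = units[ord] > 0)
}

#' Read TLFB records from CSV
#'
#' Expects `date` and `units` columns; empty or unparseable cells and
#' negative units are errors naming the offending data row.
#'
#' @param path File path.
#' @return A tibble as from [tlfb_days()].
#' @export
read_tlfb_csv <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("date", "units") %in% names(df))) {
    .stopf("TLFB file must have 'date' and 'units' columns")
  }
  date <- as.Date(df$date)
  units <- suppressWarnings(as.numeric(df$units))
  bad <- which(is.na(date) | is.na(units))
  if (length(bad)) {
    .stopf("invalid TLFB rows in %s (data lines %s)", path,
           paste(bad, collapse = ", "))
  }
  neg <- which(units < 0)
  if (length(neg)) {
    .stopf("negative units in %s (data lines %s)", path,
           paste(neg, collapse = ", "))
  }
  tlfb_days(date, units)
}

#' Write TLFB records as CSV
#' @param tlfb A tibble from [tlfb_days()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tlfb_csv <- function(tlfb, path) {
  utils::write.csv(
    data.frame(date = format(tlfb$date), units = tlfb$units),
    path, row.names = FALSE
  )
  invisible(path)
}

#' Construct a meeting schedule
#'
#' Seven research meetings across the participation window; attendance flags
#' mark which meetings (data syncs) actually happened. The first meeting
#' defines the window start.
#'
#' @param meeting_datetimes Seven strictly increasing datetimes.
#' @param attended Logical vector of length 7 (default all attended).
#' @return A `meeting_schedule` list with `meeting_datetimes`, `attended`,
#'   and integer `minute` sync times.
#' @export
meeting_schedule <- function(meeting_datetimes, attended = rep(TRUE, 7L)) {
  meeting_datetimes <- as.POSIXct(meeting_datetimes, tz = .TZ)
  if (length(meeting_datetimes) != 7L) {
    .stopf("exactly 7 meeting datetimes required, got %d",
           length(meeting_datetimes))
  }
  if (length(attended) != 7L || anyNA(attended)) {
    .stopf("attended must be 7 non-missing logicals")
  }
  m <- .epoch_min(meeting_datetimes)
  if (any(diff(m) <= 0L)) .stopf("meeting datetimes must be strictly increasing")
  structure(
    list(meeting_datetimes = .min_to_time(m), attended = as.logical(attended),
         minute = m),
    class = "meeting_schedule"
  )
}

#' Canonical Monday-start schedule
#'
#' Meetings on days 1, 3, 5, 8, 10, 12 and 15 of the window
#' (Mon/Wed/Fri/Mon/Wed/Fri/Mon for a Monday start), so no inter-meeting gap
#' exceeds the 72-hour device storage when all are attended.
#'
#' @param start First meeting datetime (default a Monday at 10:00).
#' @param attended Length-7 logical.
#' @param meeting_time_of_day Minutes after midnight for meetings 2-7.
#' @return A [meeting_schedule()].
#' @export
canonical_schedule <- function(start = as.POSIXct("2023-07-03 10:00:00", tz = "UTC"),
                               attended = rep(TRUE, 7L),
                               meeting_time_of_day = 10L * 60L) {
  start <- as.POSIXct(start, tz = .TZ)
  day0 <- .date_to_min(as.Date(start))
  offs <- c(0L, 2L, 4L, 7L, 9L, 11L, 14L)  # day indices 1,3,5,8,10,12,15
  mins <- day0 + offs * 1440L + meeting_time_of_day
  mins[1] <- .epoch_min(start)
  meeting_schedule(.min_to_time(mins), attended = attended)
}

#' Read a meeting schedule from CSV
#'
#' Expects `datetime` and `attended` columns (7 rows).
#'
#' @param path File path.
#' @param time_format strptime format for the datetime column.
#' @return A [meeting_schedule()].
#' @export
read_schedule <- function(path, time_format = "%Y-%m-%d %H:%M:%S") {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("datetime", "attended") %in% names(df))) {
    .stopf("schedule file must have 'datetime' and 'attended' columns")
  }
  ts <- as.POSIXct(df$datetime, tz = .TZ, format = time_format)
  if (anyNA(ts)) .stopf("unparseable schedule datetimes in %s", path)
  meeting_schedule(ts, attended = as.logical(df$attended))
}

#' Write a meeting schedule as CSV
#' @param schedule A [meeting_schedule()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(schedule, path) {
  utils::write.csv(
    data.frame(
      datetime = format(schedule$meeting_datetimes, "%Y-%m-%d %H:%M:%S",
                        tz = .TZ),
      attended = schedule$attended
    ),
    path, row.names = FALSE
  )
  invisible(path)
}

#' Construct a participation window
#'
#' The analysis window runs from the first meeting to the end (23:59) of the
#' last scheduled calendar day; days are whole calendar days midnight to
#' 11:59 PM, so the minute grid has `n_days * 1440` cells starting at
#' midnight of the first day.
#'
#' @param start First meeting datetime.
#' @param n_days Number of calendar days (15 in the study design).
#' @return A `participation_window` list with `start`, `end`, `n_days`,
#'   `dates`, and the integer minute grid bounds `grid_start`, `grid_end`.
#' @export
participation_window <- function(start, n_days = 15L) {
  start <- as.POSIXct(start, tz = .TZ)
  if (!.is_count(n_days) || n_days < 1) .stopf("n_days must be a positive integer")
  n_days <- as.integer(n_days)
  day0 <- .date_to_min(as.Date(start))
  grid_start <- day0
  grid_end <- day0 + n_days * 1440L - 1L
  structure(
    list(start = start, end = .min_to_time(grid_end), n_days = n_days,
         dates = as.Date(as.Date(start) + 0:(n_days - 1L)),
         grid_start = grid_start, grid_end = grid_end),
    class = "participation_window"
  )
}

#' Assemble a run configuration
#'
#' One object holding every tunable the pipeline consumes: the
#' drinking-event criteria, the CM plan parameters, the removal definition,
#' the device storage horizon, and reporting conventions. Defaults are the
#' study's operating values.
#'
#' @param criteria List of [drinking_criterion()] objects.
#' @param cm A [cm_plan()].
#' @param removal_temp_threshold Degrees C below which a recorded minute
#'   counts as off-body (default 30).
#' @param removal_min_duration Minutes a cold run must strictly exceed to be
#'   a removal (default 2).
#' @param storage_horizon Device rolling-storage depth in minutes
#'   (default 4320 = 72 h).
#' @param dialect CSV dialect from [tac_dialect()].
#' @param report_digits Decimal places for reported percentages.
#' @return A `run_config` list.
#' @export
run_config <- function(criteria = default_criteria(),
                       cm = cm_plan(),
                       removal_temp_threshold = 30,
                       removal_min_duration = 2L,
                       storage_horizon = 4320L,
                       dialect = tac_dialect(),
                       report_digits = 2L) {
  if (removal_temp_threshold <= 0) .stopf("removal_temp_threshold must be > 0")
  if (!.is_count(removal_min_duration) || removal_min_duration < 1) {
    .stopf("removal_min_duration must be a positive integer")
  }
  if (!.is_count(storage_horizon) || storage_horizon <= 0) {
    .stopf("storage_horizon must be a positive integer")
  }
  structure(
    list(criteria = criteria, cm = cm,
         removal_temp_threshold = removal_temp_threshold,
         removal_min_duration = as.integer(removal_min_duration),
         storage_horizon = as.integer(storage_horizon),
         dialect = dialect, report_digits = as.integer(report_digits)),
    class = "run_config"
  )
}
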