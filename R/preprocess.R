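#' Clamp negative TAC readings to zero
#'
#' Sensor noise can drive recorded TAC below zero; analysis replaces any
#' negative value with 0. Adds (or refreshes) a `tac` column holding the
#' clamped signal; `tac_raw` is preserved untouched.
#'
#' @param series A [tac_series()].
#' @return The series with a `tac` column, `tac = max(tac_raw, 0)`.
#' @export
clamp_negative <- function(series) {
  stopifnot(inherits(series, "tac_series"))
  series$tac <- pmax(series$tac_raw, 0)
  series
}

#' Find device-removal episodes from skin temperature
#'
#' A removal is a maximal run of consecutive recorded minutes with skin
#' temperature strictly below the threshold (30 degrees C by default), whose
#' length strictly exceeds `min_duration` minutes (default 2, so 3+ minute
#' runs qualify). A missing minute or a single warm minute terminates a run;
#' removal is defined only on recorded temperature.
#'
#' @param series A [tac_series()].
#' @param temp_threshold Degrees C (default 30).
#' @param min_duration Minutes the run must strictly exceed (default 2).
#' @return Tibble of disjoint, ordered episodes: `start`, `end` (first and
#'   last minute, inclusive), `duration` in minutes.
#' @export
#' @examples
#' t0 <- as.POSIXct("2023-07-03 00:00:00", tz = "UTC")
#' s <- tac_series(t0 + 60 * (0:5), rep(0, 6), c(33, 29, 29, 29, 33, 33))
#' find_removal_episodes(s)  # one 3-minute episode
find_removal_episodes <- function(series, temp_threshold = 30,
                                  min_duration = 2L) {
  stopifnot(inherits(series, "tac_series"))
  runs <- .maximal_runs(series$minute, series$temp < temp_threshold,
                        as.integer(min_duration))
  tibble::tibble(
    start = .min_to_time(runs$start_min),
    end = .min_to_time(runs$end_min),
    duration = runs$n
  )
}

#' Attribute missing minutes to device-storage overwriting
#'
#' The device holds a rolling window of `storage_horizon` minutes (72 h by
#' default) and is only emptied at an attended meeting (a data sync). A
#' missing minute is attributed to overwriting exactly when the next
#' attended meeting after it came more than the horizon later -- the data
#' would have aged out of storage before anyone could download them. Missing
#' minutes with no later attended sync, or within the horizon of one, are
#' missing for unknown reasons.
#'
#' @param series A [tac_series()] (the observed, synced data).
#' @param schedule A [meeting_schedule()].
#' @param window A [participation_window()].
#' @param storage_horizon Minutes of device storage (default 4320).
#' @return Integer epoch minutes of the window flagged as overwritten.
#' @export
attribute_overwritten <- function(series, schedule, window,
                                  storage_horizon = 4320L) {
  stopifnot(inherits(series, "tac_series"),
            inherits(schedule, "meeting_schedule"),
            inherits(window, "participation_window"))
  grid <- window$grid_start:window$grid_end
  missing <- setdiff(grid, series$minute)
  syncs <- schedule$minute[schedule$attended]
  if (length(syncs) == 0L || length(missing) == 0L) return(integer())
  # next attended sync strictly after each missing minute
  nxt_idx <- findInterval(missing, syncs) + 1L
  has_next <- nxt_idx <= length(syncs)
  over <- missing[has_next & (syncs[pmin(nxt_idx, length(syncs))] - missing >
                                storage_horizon)]
  as.integer(over)
}

#' Classify every minute of the participation window
#'
#' Builds the wear map: each of the window's `n_days * 1440` minutes is
#' exactly one of `WORN`, `REMOVED` (recorded but inside a removal episode),
#' `MISSING_OVERWRITTEN`, or `MISSING_UNKNOWN`.
#'
#' @param series A clamped [tac_series()].
#' @param window A [participation_window()].
#' @param schedule A [meeting_schedule()].
#' @param temp_threshold,min_duration Removal definition, as in
#'   [find_removal_episodes()].
#' @param storage_horizon Device storage horizon in minutes.
#' @return A `wear_map`: list with `window`, `minute` (integer grid),
#'   `class` (factor over the four levels), `counts` (named totals), and the
#'   removal `episodes` tibble.
#' @export
build_wear_map <- function(series, window, schedule,
                           temp_threshold = 30, min_duration = 2L,
                           storage_horizon = 4320L) {
  stopifnot(inherits(series, "tac_series"),
            inherits(window, "participation_window"))
  grid <- window$grid_start:window$grid_end
  inside <- series$minute >= window$grid_start & series$minute <= window$grid_end
  if (nrow(series) > 0L && !any(inside)) {
    .stopf("series lies entirely outside the participation window")
  }
  sub <- series[inside, ]

  cls <- rep("MISSING_UNKNOWN", length(grid))
  pos <- sub$minute - window$grid_start + 1L
  cls[pos] <- "WORN"

  eps <- find_removal_episodes(sub, temp_threshold = temp_threshold,
                               min_duration = min_duration)
  if (nrow(eps) > 0L) {
    for (i in seq_len(nrow(eps))) {
      rng <- .epoch_min(eps$start[i]):.epoch_min(eps$end[i])
      cls[rng - window$grid_start + 1L] <- "REMOVED"
    }
  }

  over <- attribute_overwritten(sub, schedule, window,
                                storage_horizon = storage_horizon)
  if (length(over)) cls[over - window$grid_start + 1L] <- "MISSING_OVERWRITTEN"

  lv <- c("WORN", "REMOVED", "MISSING_OVERWRITTEN", "MISSING_UNKNOWN")
  cls <- factor(cls, levels = lv)
  structure(
    list(window = window, minute = grid, class = cls,
         counts = stats::setNames(as.integer(table(cls)), lv),
         episodes = eps,
         participant_id = attr(series, "participant_id")),
    class = "wear_map"
  )
}

#' @export
print.wear_map <- function(x, ...) {
  cat(sprintf("<wear_map> %s: %d days, %d minutes\n",
              x$participant_id, x$window$n_days, length(x$minute)))
  print(x$counts)
  invisible(x)
}

#' Per-participant minute-classification summary
#'
#' One row per wear map: counts and percentages (2 dp) of worn, removed,
#' overwritten and unknown-missing minutes. Removal percentage is reported
#' out of recorded minutes (worn + removed), the denominator used for
#' removal shares; missing percentages are out of the window total.
#'
#' @param wear_maps A list of `wear_map` objects.
#' @return A tibble, one row per participant plus the counts needed to audit
#'   conservation (columns sum to `total`).
#' @export
minute_summary <- function(wear_maps) {
  if (inherits(wear_maps, "wear_map")) wear_maps <- list(wear_maps)
  rows <- lapply(wear_maps, function(w) {
    ct <- w$counts
    total <- sum(ct)
    recorded <- ct[["WORN"]] + ct[["REMOVED"]]
    tibble::tibble(
      participant_id = w$participant_id,
      worn = ct[["WORN"]], removed = ct[["REMOVED"]],
      overwritten = ct[["MISSING_OVERWRITTEN"]],
      unknown = ct[["MISSING_UNKNOWN"]],
      recorded = recorded, total = total,
      pct_recorded = round_half_up(100 * recorded / total, 2),
      pct_removed_of_recorded =
        if (recorded > 0) round_half_up(100 * ct[["REMOVED"]] / recorded, 2)
        else NA_real_,
      pct_overwritten = round_half_up(100 * ct[["MISSING_OVERWRITTEN"]] / total, 2),
      pct_unknown = round_half_up(100 * ct[["MISSING_UNKNOWN"]] / total, 2)
    )
  })
  do.call(rbind, rows)
}
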