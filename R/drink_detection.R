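#' Define a threshold-duration drinking criterion
#'
#' An alcohol event is TAC strictly above `threshold` ug/L for strictly more
#' than `min_duration` consecutive recorded minutes.
#'
#' @param name Label (used as the flag column name in day records).
#' @param threshold TAC in ug/L (> 0).
#' @param min_duration Minutes the event must strictly exceed (>= 1).
#' @return A `drinking_criterion` list.
#' @export
drinking_criterion <- function(name, threshold, min_duration) {
  if (threshold <= 0) .stopf("threshold must be > 0")
  if (!.is_count(min_duration) || min_duration < 1) {
    .stopf("min_duration must be a positive integer")
  }
  structure(list(name = name, threshold = threshold,
                 min_duration = as.integer(min_duration)),
            class = "drinking_criterion")
}

#' The three standard day-classification criteria
#'
#' TAS15, TAS60 and TAS90: TAC > 15 ug/L sustained for more than 15, 60 and
#' 90 minutes respectively. Longer-duration criteria are strictly nested
#' within shorter ones at the same threshold.
#'
#' @return Named list of three [drinking_criterion()] objects.
#' @export
default_criteria <- function() {
  list(
    TAS15 = drinking_criterion("TAS15", 15, 15L),
    TAS60 = drinking_criterion("TAS60", 15, 60L),
    TAS90 = drinking_criterion("TAS90", 15, 90L)
  )
}

#' Detect drinking events in a clamped TAC series
#'
#' Maximal runs of consecutive recorded minutes with clamped TAC strictly
#' above the criterion threshold, kept when the run length strictly exceeds
#' the criterion duration. Any recorded minute at or below threshold, and
#' any missing minute, breaks a run (`gap_tolerance = 0`); a non-zero
#' `gap_tolerance` allows runs to bridge up to that many consecutive missing
#' minutes (missing minutes never count toward the duration).
#'
#' @param series A [tac_series()] passed through [clamp_negative()].
#' @param criterion A [drinking_criterion()].
#' @param gap_tolerance Maximum bridged gap in minutes (default 0).
#' @return Tibble of disjoint ordered events: `start`, `end`, `duration`
#'   (minutes strictly above threshold), `peak_tac`, `criterion`.
#' @export
detect_events <- function(series, criterion, gap_tolerance = 0L) {
  stopifnot(inherits(series, "tac_series"),
            inherits(criterion, "drinking_criterion"))
  if (is.null(series$tac)) .stopf("series must be clamped first (no 'tac' column)")
  minutes <- series$minute
  above <- series$tac > criterion$threshold
  if (gap_tolerance > 0L && length(minutes) > 1L) {
    # merge across short gaps by remapping minute adjacency: a gap of g
    # missing minutes (g <= tolerance) between two above-threshold samples
    # is treated as adjacency for run-forming purposes only.
    runs <- .maximal_runs(minutes, above, 0L)
    if (nrow(runs) > 1L) {
      gap <- runs$start_min[-1L] - runs$end_min[-nrow(runs)] - 1L
      # gaps of recorded below-threshold minutes must not be bridged
      rec_between <- vapply(seq_len(nrow(runs) - 1L), function(i) {
        any(minutes > runs$end_min[i] & minutes < runs$start_min[i + 1L])
      }, logical(1))
      merge_next <- gap <= gap_tolerance & !rec_between
      grp <- cumsum(c(TRUE, !merge_next))
      agg <- lapply(split(seq_len(nrow(runs)), grp), function(ix) {
        dur <- sum(runs$n[ix])
        idx <- unlist(lapply(ix, function(i) runs$first_idx[i]:runs$last_idx[i]))
        list(start = runs$start_min[ix[1L]], end = runs$end_min[ix[length(ix)]],
             dur = dur, peak = max(series$tac[idx]))
      })
      out <- tibble::tibble(
        start = .min_to_time(vapply(agg, `[[`, numeric(1), "start")),
        end = .min_to_time(vapply(agg, `[[`, numeric(1), "end")),
        duration = as.integer(vapply(agg, `[[`, numeric(1), "dur")),
        peak_tac = vapply(agg, `[[`, numeric(1), "peak"),
        criterion = criterion$name
      )
      return(out[out$duration > criterion$min_duration, ])
    }
  }
  runs <- .maximal_runs(minutes, above, criterion$min_duration)
  peak <- vapply(seq_len(nrow(runs)), function(i) {
    max(series$tac[runs$first_idx[i]:runs$last_idx[i]])
  }, numeric(1))
  tibble::tibble(
    start = .min_to_time(runs$start_min),
    end = .min_to_time(runs$end_min),
    duration = runs$n,
    peak_tac = peak,
    criterion = criterion$name
  )
}

#' Aggregate a series and its events to calendar-day records
#'
#' A day runs midnight to 11:59 PM. For each window date: the peak clamped
#' TAC over recorded in-day minutes (0 when none recorded); one logical flag
#' per criterion, true when at least one qualifying event has a constituent
#' minute within the date (an event spanning midnight flags both days);
#' removal totals and the longest single removal episode overlapping the
#' day; and per-class coverage counts from the wear map.
#'
#' @param series A clamped [tac_series()].
#' @param wear_map A [build_wear_map()] result for the same series/window.
#' @param criteria Named list of [drinking_criterion()] objects.
#' @param gap_tolerance Passed to [detect_events()].
#' @return A tibble with one row per window date: `date`, `peak_tac`, one
#'   logical column per criterion name, `removal_total`,
#'   `removal_max_episode`, `overwritten_minutes`, `unknown_missing_minutes`,
#'   `recorded_minutes`.
#' @export
classify_days <- function(series, wear_map, criteria = default_criteria(),
                          gap_tolerance = 0L) {
  stopifnot(inherits(wear_map, "wear_map"))
  window <- wear_map$window
  dates <- window$dates
  nd <- length(dates)
  day_of <- function(m) floor(m / 1440) - floor(window$grid_start / 1440) + 1L

  inside <- series$minute >= window$grid_start & series$minute <= window$grid_end
  sub <- series[inside, ]

  peak <- numeric(nd)
  if (nrow(sub) > 0L) {
    d <- day_of(sub$minute)
    agg <- tapply(sub$tac, d, max)
    peak[as.integer(names(agg))] <- as.numeric(agg)
  }

  flags <- matrix(FALSE, nrow = nd, ncol = length(criteria),
                  dimnames = list(NULL, vapply(criteria, `[[`, "", "name")))
  for (cr in criteria) {
    ev <- detect_events(sub, cr, gap_tolerance = gap_tolerance)
    for (i in seq_len(nrow(ev))) {
      dd <- day_of(.epoch_min(ev$start[i])):day_of(.epoch_min(ev$end[i]))
      dd <- dd[dd >= 1L & dd <= nd]
      flags[dd, cr$name] <- TRUE
    }
  }

  removal_total <- integer(nd)
  removal_max <- integer(nd)
  eps <- wear_map$episodes
  for (i in seq_len(nrow(eps))) {
    rng <- .epoch_min(eps$start[i]):.epoch_min(eps$end[i])
    dd <- day_of(rng)
    per_day <- table(dd)
    for (k in names(per_day)) {
      j <- as.integer(k)
      if (j >= 1L && j <= nd) {
        removal_total[j] <- removal_total[j] + per_day[[k]]
        removal_max[j] <- max(removal_max[j], per_day[[k]])
      }
    }
  }

  cls_day <- day_of(wear_map$minute)
  overw <- as.integer(tapply(wear_map$class == "MISSING_OVERWRITTEN", cls_day, sum))
  unknown <- as.integer(tapply(wear_map$class == "MISSING_UNKNOWN", cls_day, sum))
  recorded <- as.integer(tapply(wear_map$class %in% c("WORN", "REMOVED"),
                                cls_day, sum))

  out <- tibble::tibble(date = dates, peak_tac = peak)
  for (nm in colnames(flags)) out[[nm]] <- flags[, nm]
  out$removal_total <- removal_total
  out$removal_max_episode <- removal_max
  out$overwritten_minutes <- overw
  out$unknown_missing_minutes <- unknown
  out$recorded_minutes <- recorded
  out
}

#' Check duration nesting of drinking-day sets
#'
#' For criteria sharing a threshold, a longer minimum duration can only
#' remove drinking days: the day set under a longer duration must be a
#' subset of that under any shorter one. Returns TRUE when nesting holds for
#' every ordered pair of criterion columns.
#'
#' @param day_records Output of [classify_days()].
#' @param criteria Named list of criteria ordered as in the records.
#' @return Logical scalar.
#' @export
criterion_nesting_check <- function(day_records, criteria = default_criteria()) {
  crit <- criteria[order(vapply(criteria, `[[`, integer(1), "min_duration"))]
  nms <- vapply(crit, `[[`, "", "name")
  for (i in seq_along(nms)[-1L]) {
    longer <- day_records[[nms[i]]]
    shorter <- day_records[[nms[i - 1L]]]
    if (any(longer & !shorter)) return(FALSE)
  }
  TRUE
}
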