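#' Configuration for the synthetic cohort generator
#'
#' Describes a two-arm wearable-sensor study: 15-day participation windows
#' with seven research meetings (days 1, 3, 5, 8, 10, 12, 15, synced at the
#' end of the meeting day so that no attended inter-sync gap exceeds the
#' 72-hour device storage), minute-cadence TAC and skin-temperature streams,
#' drinking episodes with lag/linear-rise/exponential-decay kinetics,
#' removals (daily baths plus sporadic longer removals), ambient-alcohol
#' spike artifacts, negative sensor noise, device-storage overwriting driven
#' by missed meetings, and imperfect self-report.
#'
#' Defaults emulate a treatment-seeking heavy-drinking cohort: drinking-day
#' probability 0.5 (control) / 0.3 (incentivized arm), median 12 UK units
#' per drinking day, ~91% meeting attendance. Kinetics are chosen so a
#' typical 4-unit episode stays above 15 ug/L for more than 90 minutes,
#' making all three day-classification criteria exercisable.
#'
#' @param n_participants Cohort size.
#' @param n_days Window length in calendar days.
#' @param start First window date (a Monday in the canonical design).
#' @param allocation_ratio Two non-negative weights, control:incentive arm.
#' @param p_drink Named per-arm daily drinking probability.
#' @param units_meanlog,units_sdlog Log-normal units per drinking day.
#' @param lag_min,rise_rate,decay_rate,peak_scale,peak_cap Episode kinetics:
#'   onset lag (min), linear rise (ug/L per min), exponential decay (per
#'   min), peak ug/L per UK unit, and peak cap (ug/L).
#' @param episode_start_range Minutes after midnight in which episodes begin.
#' @param baseline_tac_sd Gaussian sensor noise SD (ug/L); negative raw
#'   readings arise from this noise.
#' @param negative_noise_prob Per-minute probability of an extra negative
#'   dip (uniform 0-5 ug/L), exercising the clamping rule.
#' @param temp_baseline_mean,temp_baseline_sd Between-participant skin
#'   temperature baseline (degrees C).
#' @param temp_noise_sd Per-minute temperature noise SD.
#' @param low_temp_baseline_prob,low_temp_baseline_mean Fraction of wearers
#'   whose skin runs below the 30 C decision threshold, and their baseline:
#'   the known cold-skin failure class.
#' @param ambient_temp_mean,ambient_temp_sd Off-body (ambient) temperature.
#' @param bath_prob,bath_duration_range,bath_start_range Daily bathing
#'   removal: probability, duration (min), start window (min after
#'   midnight).
#' @param extra_removal_rate Additional removals per day (Poisson).
#' @param removal_duration_meanlog,removal_duration_sdlog Log-normal extra
#'   removal durations, truncated to 3-600 min.
#' @param ambient_spike_rate Spikes per day from alcohol-containing products
#'   (Poisson); short (1-8 min) so they do not mimic sustained drinking.
#' @param spike_magnitude_range,spike_duration_range Spike size (ug/L) and
#'   length (min).
#' @param missing_segment_rate Unexplained recording gaps per day (Poisson).
#' @param missing_duration_meanlog,missing_duration_sdlog Log-normal gap
#'   durations, truncated to 5-720 min.
#' @param meeting_miss_prob Probability a meeting (2-7) is missed.
#' @param misreport_prob Probability self-report omits a true drinking day.
#' @param storage_horizon Device rolling storage in minutes (4320 = 72 h).
#' @param meeting_time_of_day Minutes after midnight at which meetings sync.
#' @param seed Integer seed (mandatory).
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_participants = 29L,
                             n_days = 15L,
                             start = "2023-07-03",
                             allocation_ratio = c(control = 1, cm = 1),
                             p_drink = c(control = 0.5, cm = 0.3),
                             units_meanlog = log(12), units_sdlog = 0.5,
                             lag_min = 30L, rise_rate = 1.5,
                             decay_rate = 0.02, peak_scale = 25,
                             peak_cap = 250,
                             episode_start_range = c(960L, 1080L),
                             baseline_tac_sd = 1,
                             negative_noise_prob = 0.05,
                             temp_baseline_mean = 33, temp_baseline_sd = 1,
                             temp_noise_sd = 0.3,
                             low_temp_baseline_prob = 0.05,
                             low_temp_baseline_mean = 29.5,
                             ambient_temp_mean = 22, ambient_temp_sd = 2,
                             bath_prob = 0.8,
                             bath_duration_range = c(20L, 50L),
                             bath_start_range = c(420L, 540L),
                             extra_removal_rate = 1.0,
                             removal_duration_meanlog = log(120),
                             removal_duration_sdlog = 1,
                             ambient_spike_rate = 0.1,
                             spike_magnitude_range = c(50, 300),
                             spike_duration_range = c(1L, 8L),
                             missing_segment_rate = 0.3,
                             missing_duration_meanlog = log(60),
                             missing_duration_sdlog = 0.7,
                             meeting_miss_prob = 0.089,
                             misreport_prob = 0.08,
                             storage_horizon = 4320L,
                             meeting_time_of_day = 1439L,
                             seed) {
  if (missing(seed)) .stopf("synthetic_config: seed is mandatory")
  cfg <- as.list(environment())
  probs <- c("negative_noise_prob", "low_temp_baseline_prob", "bath_prob",
             "meeting_miss_prob", "misreport_prob")
  for (p in probs) {
    v <- cfg[[p]]
    if (!is.numeric(v) || v < 0 || v > 1) .stopf("invalid field: %s", p)
  }
  for (pp in names(cfg$p_drink)) {
    if (cfg$p_drink[[pp]] < 0 || cfg$p_drink[[pp]] > 1) {
      .stopf("invalid field: p_drink[%s]", pp)
    }
  }
  rates <- c("extra_removal_rate", "ambient_spike_rate",
             "missing_segment_rate", "decay_rate", "rise_rate")
  for (r in rates) {
    if (!is.numeric(cfg[[r]]) || cfg[[r]] < 0) .stopf("invalid field: %s", r)
  }
  if (!.is_count(cfg$n_participants) || cfg$n_participants < 1) {
    .stopf("invalid field: n_participants")
  }
  if (!.is_count(cfg$storage_horizon) || cfg$storage_horizon <= 0) {
    .stopf("invalid field: storage_horizon")
  }
  structure(cfg, class = "synthetic_config")
}

#' A zero-noise variant of a synthetic configuration
#'
#' All stochastic nuisance processes (sensor noise, artifacts, recording
#' gaps, missed meetings, misreport, temperature noise, cold-skin wearers)
#' are switched off; drinking, removals and device behavior remain. Under
#' such a config the pipeline must recover the generator's ground truth
#' exactly.
#'
#' @param ... Overrides passed to [synthetic_config()].
#' @return A `synthetic_config`.
#' @export
noise_free_config <- function(...) {
  args <- list(
    baseline_tac_sd = 0, negative_noise_prob = 0,
    temp_noise_sd = 0, temp_baseline_sd = 0,
    low_temp_baseline_prob = 0, ambient_temp_sd = 0,
    ambient_spike_rate = 0, missing_segment_rate = 0,
    meeting_miss_prob = 0, misreport_prob = 0
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(synthetic_config, args)
}

#' Per-minute TAC contribution of one drinking episode
#'
#' Lag, then linear rise to a peak of `peak_scale * units` (capped), then
#' exponential decay, truncated once the curve falls below 1% of its peak.
#' The curve is the alcohol signal added to the sensor stream while the
#' device is worn.
#'
#' @param units UK units consumed (> 0).
#' @param lag_min,rise_rate,decay_rate,peak_scale,peak_cap Kinetic
#'   parameters as in [synthetic_config()].
#' @return Numeric vector of per-minute TAC contributions from episode
#'   onset; zero-length when `units == 0`.
#' @export
episode_tac_curve <- function(units, lag_min = 30L, rise_rate = 1.5,
                              decay_rate = 0.02, peak_scale = 25,
                              peak_cap = 250) {
  if (units <= 0) return(numeric())
  peak <- min(peak_scale * units, peak_cap)
  n_rise <- ceiling(peak / rise_rate)
  rise <- pmin(rise_rate * seq_len(n_rise), peak)
  n_decay <- ceiling(log(100) / decay_rate)  # below 1% of peak
  decay <- peak * exp(-decay_rate * seq_len(n_decay))
  c(rep(0, lag_min), rise, decay)
}

#' Emulate the device's 72-hour rolling storage
#'
#' The device keeps only the most recent `horizon` minutes; memory is
#' downloaded (synced) at each attended meeting. A recorded minute survives
#' exactly when the first attended sync at or after it comes within the
#' horizon; minutes that aged out before their first sync are overwritten
#' and logged, and minutes after the last attended sync are never
#' downloaded (dropped, but not overwritten).
#'
#' @param series The full [tac_series()] the device recorded.
#' @param schedule A [meeting_schedule()].
#' @param horizon Storage depth in minutes (default 4320).
#' @return List: `observed` (surviving `tac_series`), `overwritten_log`
#'   (integer minutes lost to storage aging), `never_synced` (integer
#'   minutes after the last attended sync).
#' @export
emulate_device <- function(series, schedule, horizon = 4320L) {
  stopifnot(inherits(series, "tac_series"),
            inherits(schedule, "meeting_schedule"))
  syncs <- schedule$minute[schedule$attended]
  m <- series$minute
  if (length(syncs) == 0L) {
    keep <- rep(FALSE, length(m))
    overwritten <- integer()
    never <- m
  } else {
    # first sync at or after each minute
    nxt <- findInterval(m - 1L, syncs) + 1L
    has <- nxt <= length(syncs)
    gap <- ifelse(has, syncs[pmin(nxt, length(syncs))] - m, NA_integer_)
    keep <- has & gap <= horizon
    overwritten <- m[has & gap > horizon]
    never <- m[!has]
  }
  obs <- series[keep, ]
  attr(obs, "participant_id") <- attr(series, "participant_id")
  attr(obs, "device_id") <- attr(series, "device_id")
  class(obs) <- class(series)
  list(observed = obs, overwritten_log = as.integer(overwritten),
       never_synced = as.integer(never))
}

# qualifying maximal runs (> min_len) of a logical grid vector, via rle --
# deliberately a different code path from the sample-based run finder.
.grid_runs <- function(mask, min_len) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths > min_len
  data.frame(start = starts[keep], end = ends[keep], n = r$lengths[keep])
}

.clip_interval <- function(start, len, n) {
  if (start > n || start + len - 1L < 1L) return(NULL)
  c(max(1L, start), min(n, start + len - 1L))
}

.generate_participant <- function(cfg, pid, group, window, schedule) {
  n_days <- cfg$n_days
  N <- n_days * 1440L
  grid0 <- window$grid_start  # epoch minute of grid cell 1

  # --- truth: drinking days, units, episode signal ----------------------
  drink <- stats::runif(n_days) < cfg$p_drink[[group]]
  units <- ifelse(drink,
                  stats::rlnorm(n_days, cfg$units_meanlog, cfg$units_sdlog), 0)
  signal <- numeric(N)
  ep_rows <- list()
  for (d in which(drink)) {
    off <- sample(seq.int(cfg$episode_start_range[1],
                          cfg$episode_start_range[2]), 1L)
    s_idx <- (d - 1L) * 1440L + off + 1L
    curve <- episode_tac_curve(units[d], cfg$lag_min, cfg$rise_rate,
                               cfg$decay_rate, cfg$peak_scale, cfg$peak_cap)
    iv <- .clip_interval(s_idx, length(curve), N)
    if (!is.null(iv)) {
      signal[iv[1]:iv[2]] <- signal[iv[1]:iv[2]] +
        curve[seq.int(iv[1] - s_idx + 1L, iv[2] - s_idx + 1L)]
      ep_rows[[length(ep_rows) + 1L]] <-
        data.frame(day = d, units = units[d], start_idx = iv[1],
                   end_idx = iv[2])
    }
  }

  # --- removals ---------------------------------------------------------
  removal <- rep(FALSE, N)
  for (d in seq_len(n_days)) {
    base <- (d - 1L) * 1440L
    if (stats::runif(1) < cfg$bath_prob) {
      st <- base + sample(seq.int(cfg$bath_start_range[1],
                                  cfg$bath_start_range[2]), 1L) + 1L
      dur <- sample(seq.int(cfg$bath_duration_range[1],
                            cfg$bath_duration_range[2]), 1L)
      iv <- .clip_interval(st, dur, N)
      if (!is.null(iv)) removal[iv[1]:iv[2]] <- TRUE
    }
    n_extra <- stats::rpois(1, cfg$extra_removal_rate)
    for (k in seq_len(n_extra)) {
      st <- base + sample.int(1440L, 1L)
      dur <- max(3L, min(600L, round(stats::rlnorm(
        1, cfg$removal_duration_meanlog, cfg$removal_duration_sdlog))))
      iv <- .clip_interval(st, dur, N)
      if (!is.null(iv)) removal[iv[1]:iv[2]] <- TRUE
    }
  }

  # --- temperature ------------------------------------------------------
  tb <- if (stats::runif(1) < cfg$low_temp_baseline_prob) {
    cfg$low_temp_baseline_mean
  } else {
    stats::rnorm(1, cfg$temp_baseline_mean, cfg$temp_baseline_sd)
  }
  temp <- tb + stats::rnorm(N, 0, cfg$temp_noise_sd)
  n_rm <- sum(removal)
  if (n_rm > 0L) {
    temp[removal] <- stats::rnorm(n_rm, cfg$ambient_temp_mean,
                                  cfg$ambient_temp_sd) +
      stats::rnorm(n_rm, 0, cfg$temp_noise_sd)
  }

  # --- raw TAC: worn signal + noise + artifacts -------------------------
  tac_raw <- signal * as.numeric(!removal) +
    stats::rnorm(N, 0, cfg$baseline_tac_sd)
  if (cfg$negative_noise_prob > 0) {
    dip <- stats::runif(N) < cfg$negative_noise_prob
    tac_raw[dip] <- tac_raw[dip] - stats::runif(sum(dip), 0, 5)
  }
  n_spk <- stats::rpois(1, cfg$ambient_spike_rate * n_days)
  for (k in seq_len(n_spk)) {
    st <- sample.int(N, 1L)
    dur <- sample(seq.int(cfg$spike_duration_range[1],
                          cfg$spike_duration_range[2]), 1L)
    iv <- .clip_interval(st, dur, N)
    if (!is.null(iv)) {
      tac_raw[iv[1]:iv[2]] <- tac_raw[iv[1]:iv[2]] +
        stats::runif(1, cfg$spike_magnitude_range[1],
                     cfg$spike_magnitude_range[2])
    }
  }

  # --- unexplained recording gaps --------------------------------------
  device_on <- rep(TRUE, N)
  n_gap <- stats::rpois(1, cfg$missing_segment_rate * n_days)
  for (k in seq_len(n_gap)) {
    st <- sample.int(N, 1L)
    dur <- max(5L, min(720L, round(stats::rlnorm(
      1, cfg$missing_duration_meanlog, cfg$missing_duration_sdlog))))
    iv <- .clip_interval(st, dur, N)
    if (!is.null(iv)) device_on[iv[1]:iv[2]] <- FALSE
  }

  # --- device storage emulation ----------------------------------------
  rec_idx <- which(device_on)
  full <- tac_series(.min_to_time(grid0 + rec_idx - 1L),
                     tac_raw[rec_idx], temp[rec_idx],
                     participant_id = pid,
                     device_id = sprintf("SKYN-%s", pid))
  emu <- emulate_device(full, schedule, horizon = cfg$storage_horizon)
  observed <- emu$observed

  obs_mask <- rep(FALSE, N)
  obs_mask[observed$minute - grid0 + 1L] <- TRUE

  # --- ground truth (interval arithmetic on construction masks) --------
  cold_obs <- removal & obs_mask
  rem_runs <- .grid_runs(cold_obs, 2L)
  removed_mask <- rep(FALSE, N)
  for (i in seq_len(nrow(rem_runs))) {
    removed_mask[rem_runs$start[i]:rem_runs$end[i]] <- TRUE
  }
  over_mask <- rep(FALSE, N)
  over_mask[emu$overwritten_log - grid0 + 1L] <- TRUE
  counts <- c(
    WORN = sum(obs_mask & !removed_mask),
    REMOVED = sum(removed_mask),
    MISSING_OVERWRITTEN = sum(over_mask),
    MISSING_UNKNOWN = sum(!obs_mask & !over_mask)
  )

  day_of_idx <- rep(seq_len(n_days), each = 1440L)
  tas_days <- lapply(default_criteria(), function(cr) {
    ab <- (signal * as.numeric(!removal) > cr$threshold) & obs_mask
    runs <- .grid_runs(ab, cr$min_duration)
    flagged <- rep(FALSE, n_days)
    for (i in seq_len(nrow(runs))) {
      flagged[unique(day_of_idx[runs$start[i]:runs$end[i]])] <- TRUE
    }
    flagged
  })

  # --- TLFB with misreporting ------------------------------------------
  reported <- units
  omit <- drink & (stats::runif(n_days) < cfg$misreport_prob)
  reported[omit] <- 0
  tlfb <- tlfb_days(window$dates, reported)

  list(
    participant_id = pid, group = group,
    series = observed, tlfb = tlfb, schedule = schedule,
    truth = list(
      days = tibble::tibble(date = window$dates, drinking = drink,
                            units = units, reported_units = reported,
                            misreported = omit),
      episodes = if (length(ep_rows)) {
        do.call(rbind, ep_rows)
      } else {
        data.frame(day = integer(), units = numeric(),
                   start_idx = integer(), end_idx = integer())
      },
      removal_minutes = sum(removed_mask),
      class_counts = counts,
      overwritten_minutes = as.integer(emu$overwritten_log),
      tas_day_flags = tas_days,
      temp_baseline = tb
    )
  )
}

#' Generate a complete synthetic study cohort
#'
#' Emits, for every participant: an observed [tac_series()] (after device
#' storage emulation), TLFB records, the meeting schedule actually attended,
#' an arm label, and a ground-truth block (drinking days and units, episode
#' intervals, removal and overwritten minute totals, per-class minute
#' counts, and the day flags each detection criterion should produce).
#' Reproducible: the same config yields identical output.
#'
#' @param config A [synthetic_config()].
#' @return A `synthetic_cohort` list: `participants` (list), `window`,
#'   `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  window <- participation_window(
    as.POSIXct(paste(config$start, "00:00:00"), tz = .TZ),
    n_days = config$n_days
  )
  n <- config$n_participants
  w <- config$allocation_ratio
  n_ctrl <- ceiling(n * w[[1]] / sum(w))
  groups <- c(rep("control", n_ctrl), rep("cm", n - n_ctrl))

  participants <- vector("list", n)
  for (i in seq_len(n)) {
    att <- c(TRUE, stats::runif(6) >= config$meeting_miss_prob)
    sched <- canonical_schedule(
      start = window$start, attended = att,
      meeting_time_of_day = config$meeting_time_of_day
    )
    participants[[i]] <- .generate_participant(
      config, sprintf("P%02d", i), groups[i], window, sched
    )
  }
  names(participants) <- vapply(participants, `[[`, "", "participant_id")
  structure(list(participants = participants, window = window,
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d participants x %d days (seed %d)\n",
              length(x$participants), x$window$n_days, x$config$seed))
  invisible(x)
}

#' Write a synthetic cohort to a directory of CSV files
#'
#' One TAC CSV and one TLFB CSV per participant, one schedule CSV per
#' participant, a cohort table of arm labels, and truth CSVs (per-day
#' drinking truth and per-participant minute-class counts). Everything is
#' plain text and round-trips through the package readers.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  arms <- data.frame(
    participant_id = names(cohort$participants),
    group = vapply(cohort$participants, `[[`, "", "group")
  )
  utils::write.csv(arms, file.path(dir, "participants.csv"),
                   row.names = FALSE)
  truth_days <- list()
  truth_counts <- list()
  for (p in cohort$participants) {
    id <- p$participant_id
    write_tac_csv(p$series, file.path(dir, sprintf("tac_%s.csv", id)))
    write_tlfb_csv(p$tlfb, file.path(dir, sprintf("tlfb_%s.csv", id)))
    write_schedule(p$schedule, file.path(dir, sprintf("schedule_%s.csv", id)))
    td <- p$truth$days
    td$participant_id <- id
    truth_days[[id]] <- td
    truth_counts[[id]] <- data.frame(participant_id = id,
                                     t(p$truth$class_counts))
  }
  utils::write.csv(do.call(rbind, truth_days),
                   file.path(dir, "truth_days.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, truth_counts),
                   file.path(dir, "truth_minutes.csv"), row.names = FALSE)
  invisible(dir)
}
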