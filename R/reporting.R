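#' Process one participant through the minute-level pipeline
#'
#' Clamp, classify minutes, detect events under every configured criterion,
#' and aggregate to day records: the per-participant core of the pipeline.
#'
#' @param series A raw [tac_series()].
#' @param schedule The participant's [meeting_schedule()].
#' @param window The [participation_window()].
#' @param config A [run_config()].
#' @return List: `series` (clamped), `wear_map`, `day_records`.
#' @export
process_participant <- function(series, schedule, window,
                                config = run_config()) {
  series <- clamp_negative(series)
  wm <- build_wear_map(series, window, schedule,
                       temp_threshold = config$removal_temp_threshold,
                       min_duration = config$removal_min_duration,
                       storage_horizon = config$storage_horizon)
  days <- classify_days(series, wm, criteria = config$criteria)
  list(series = series, wear_map = wm, day_records = days)
}

# pooled day-level confusion for one criterion across participants; days
# with no recorded sensor minutes are excluded and logged, mirroring the
# restriction of agreement analyses to sensor-covered days.
.cohort_confusion <- function(processed, tlfbs, criterion_name) {
  ref <- logical(0); test <- logical(0); excluded <- character(0)
  for (id in names(processed)) {
    dr <- processed[[id]]$day_records
    tl <- tlfbs[[id]]
    stopifnot(all(dr$date == tl$date))
    covered <- dr$recorded_minutes > 0L
    excluded <- c(excluded, paste(id, dr$date[!covered], sep = ":"))
    ref <- c(ref, tl$drinking[covered])
    test <- c(test, dr[[criterion_name]][covered])
  }
  cm <- confusion_matrix(tp = sum(ref & test), fn = sum(ref & !test),
                         fp = sum(!ref & test), tn = sum(!ref & !test))
  cm$excluded <- excluded
  cm
}

#' Run the full pipeline on a synthetic cohort
#'
#' simulate -> process -> CM ledger -> agreement, in one reproducible call.
#' Stages are plain function calls and can be re-run independently with
#' identical results given the same configuration.
#'
#' @param sim_config A [synthetic_config()], or the path of a YAML file
#'   whose keys are its arguments.
#' @param config A [run_config()] for the analysis stages.
#' @param out_dir Optional directory; when given, every table is written as
#'   CSV together with a `manifest.yaml` (seed, config hash, package
#'   version, file list).
#' @return A `tacwear_run` list: `cohort`, `processed`, `minute_summary`,
#'   `day_table`, `ledgers`, `audit`, `counts_table`, `stats_table`,
#'   `correlation`, `group_comparison`, `manifest`.
#' @export
run_pipeline <- function(sim_config, config = run_config(), out_dir = NULL) {
  if (is.character(sim_config)) {
    args <- yaml::read_yaml(sim_config)
    sim_config <- do.call(synthetic_config, args)
  }
  stopifnot(inherits(sim_config, "synthetic_config"))
  cohort <- generate_cohort(sim_config)
  window <- cohort$window

  processed <- lapply(cohort$participants, function(p) {
    process_participant(p$series, p$schedule, window, config)
  })
  tlfbs <- lapply(cohort$participants, `[[`, "tlfb")
  groups <- vapply(cohort$participants, `[[`, "", "group")

  msum <- minute_summary(lapply(processed, `[[`, "wear_map"))

  day_rows <- lapply(names(processed), function(id) {
    dr <- processed[[id]]$day_records
    dr$participant_id <- id
    dr
  })
  day_table <- do.call(rbind, day_rows)

  cm_ids <- names(processed)[groups == "cm"]
  ledgers <- lapply(cm_ids, function(id) {
    outcomes <- assess_days(processed[[id]]$day_records, config$cm)
    compute_ledger(outcomes, config$cm,
                   schedule = cohort$participants[[id]]$schedule,
                   window = window)
  })
  names(ledgers) <- cm_ids
  audit <- if (length(ledgers)) ledger_summary(ledgers) else NULL

  crit_names <- vapply(config$criteria, `[[`, "", "name")
  counts <- lapply(crit_names, function(nm) {
    cm <- .cohort_confusion(processed, tlfbs, nm)
    tibble::tibble(criterion = nm, tp = cm$tp, fn = cm$fn, fp = cm$fp,
                   tn = cm$tn, total = cm$total,
                   excluded_days = length(cm$excluded))
  })
  counts_table <- do.call(rbind, counts)
  stats_table <- do.call(rbind, lapply(seq_along(crit_names), function(i) {
    row <- counts_table[i, ]
    cm <- confusion_matrix(row$tp, row$fn, row$fp, row$tn)
    cbind(tibble::tibble(criterion = row$criterion),
          diagnostics(cm, digits = config$report_digits))
  }))

  # per-participant drinking-day counts: self-report vs first criterion
  tlfb_days_n <- vapply(tlfbs, function(t) sum(t$drinking), integer(1))
  tas_days_n <- vapply(processed, function(p) {
    sum(p$day_records[[crit_names[1]]])
  }, integer(1))
  correlation <- if (length(tlfb_days_n) >= 3) {
    spearman_bca(tlfb_days_n, tas_days_n, n_boot = 2000L,
                 seed = sim_config$seed)
  } else {
    NULL
  }

  group_cmp <- if (length(unique(groups)) == 2L &&
                   all(table(groups) >= 2L)) {
    group_summary(tlfb_days_n, groups)
  } else {
    NULL
  }

  manifest <- list(
    seed = sim_config$seed,
    n_participants = sim_config$n_participants,
    package_version = as.character(utils::packageVersion("tacwear")),
    generated_at = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
    tables = c("minute_summary", "day_table", "ledger", "audit",
               "counts_table", "stats_table")
  )

  run <- structure(
    list(cohort = cohort, processed = processed,
         minute_summary = msum, day_table = day_table,
         ledgers = ledgers, audit = audit,
         counts_table = counts_table, stats_table = stats_table,
         correlation = correlation, group_comparison = group_cmp,
         manifest = manifest),
    class = "tacwear_run"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(msum, file.path(out_dir, "minute_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(day_table, file.path(out_dir, "day_table.csv"),
                     row.names = FALSE)
    if (!is.null(audit)) {
      utils::write.csv(audit$participants, file.path(out_dir, "audit.csv"),
                       row.names = FALSE)
    }
    utils::write.csv(counts_table, file.path(out_dir, "counts.csv"),
                     row.names = FALSE)
    utils::write.csv(stats_table, file.path(out_dir, "stats.csv"),
                     row.names = FALSE)
    cfg_path <- file.path(out_dir, "config.yaml")
    yaml::write_yaml(unclass(sim_config), cfg_path)
    manifest$config_hash <- unname(tools::md5sum(cfg_path))
    run$manifest <- manifest
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  }
  run
}

#' Render a run as a human-readable report
#'
#' Per-criterion diagnostic statistics (percentages and PAC at 2 dp),
#' minute accounting, CM audit, and the drinking-day correlation, as
#' markdown text. Rounding is half-up at this layer only; upstream values
#' are full precision. An empty cohort produces an explicit no-data report.
#'
#' @param run A `tacwear_run` from [run_pipeline()], or a list with at
#'   least `stats_table` and `counts_table`.
#' @return Character vector of report lines, invisibly printed with `cat`.
#' @export
render_report <- function(run) {
  st <- run$stats_table
  if (is.null(st) || nrow(st) == 0L) {
    lines <- c("# Sensor vs self-report agreement", "", "No data.")
    return(invisible(structure(lines, class = "tacwear_report")))
  }
  fmt2 <- function(x) ifelse(is.na(x), "NA",
                             sprintf("%.2f", round_half_up(x, 2)))
  lines <- c(
    "# Sensor vs self-report agreement", "",
    "| criterion | sensitivity | specificity | PPV | NPV | PAC |",
    "|---|---|---|---|---|---|",
    vapply(seq_len(nrow(st)), function(i) {
      sprintf("| %s | %s | %s | %s | %s | %s |", st$criterion[i],
              fmt2(st$sensitivity[i]), fmt2(st$specificity[i]),
              fmt2(st$ppv[i]), fmt2(st$npv[i]), fmt2(st$pac[i]))
    }, character(1)),
    ""
  )
  ms <- run$minute_summary
  if (!is.null(ms) && nrow(ms) > 0L) {
    rec <- sum(ms$recorded); tot <- sum(ms$total); rem <- sum(ms$removed)
    lines <- c(lines, "# Minute accounting", "",
               sprintf("- Recorded: %d/%d minutes (%.2f%%)", rec, tot,
                       round_half_up(100 * rec / tot, 2)),
               sprintf("- Removal share of recorded: %d/%d minutes (%.2f%%)",
                       rem, rec, round_half_up(100 * rem / rec, 2)),
               "")
  }
  if (!is.null(run$audit)) {
    co <- run$audit$cohort
    lines <- c(lines, "# CM rewards", "",
               sprintf("- Days earned: %d/%d (%.1f%%)", co$days_earned,
                       co$days_total, co$pct_days_earned),
               sprintf("- Cohort total: GBP %g", co$total_gbp),
               "")
  }
  if (!is.null(run$correlation) && !is.na(run$correlation$rho)) {
    cr <- run$correlation
    lines <- c(lines, "# Drinking-day correlation", "",
               sprintf("- Spearman rho = %.3f (BCa 95%% CI %.3f to %.3f, n = %d)",
                       cr$rho, cr$ci_low, cr$ci_high, cr$n),
               "")
  }
  structure(lines, class = "tacwear_report")
}

#' @export
print.tacwear_report <- function(x, ...) {
  cat(paste(unclass(x), collapse = "\n"), "\n")
  invisible(x)
}
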