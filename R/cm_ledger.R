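#' Define a contingency-management reward plan
#'
#' Daily vouchers, inter-meeting block bonuses and a full-period bonus,
#' awarded for days whose peak TAC stays strictly below the plan threshold
#' and whose device removals stay within the daily allowance.
#'
#' @param daily_amount GBP per eligible day (default 5).
#' @param tac_threshold Peak-TAC eligibility bound in ug/L, strict
#'   (default 115.660).
#' @param max_removal_episode Longest single removal episode allowed per day
#'   in minutes, strict (default 60: a one-time one-hour removal is allowed).
#' @param max_removal_total Total removal minutes allowed per day, strict
#'   (default 60).
#' @param full_period_bonus GBP when every window day is eligible
#'   (default 35).
#' @param bonus_per_block_day GBP per day of a fully-eligible inter-meeting
#'   block (default 5).
#' @param missing_counts_as_removal Should unknown-missing minutes count
#'   toward the removal allowance (device off-body is indistinguishable from
#'   unrecorded)? Default TRUE.
#' @return A `cm_plan` list.
#' @export
cm_plan <- function(daily_amount = 5, tac_threshold = 115.660,
                    max_removal_episode = 60L, max_removal_total = 60L,
                    full_period_bonus = 35, bonus_per_block_day = 5,
                    missing_counts_as_removal = TRUE) {
  if (tac_threshold <= 0) .stopf("tac_threshold must be > 0")
  amts <- c(daily_amount, full_period_bonus, bonus_per_block_day)
  if (any(amts < 0)) .stopf("CM amounts must be non-negative")
  structure(
    list(daily_amount = daily_amount, tac_threshold = tac_threshold,
         max_removal_episode = as.integer(max_removal_episode),
         max_removal_total = as.integer(max_removal_total),
         full_period_bonus = full_period_bonus,
         bonus_per_block_day = bonus_per_block_day,
         missing_counts_as_removal = isTRUE(missing_counts_as_removal)),
    class = "cm_plan"
  )
}

#' Assess one day's CM eligibility
#'
#' A day is eligible when its peak TAC is strictly below the plan threshold
#' and no removal limb is exceeded: neither the longest single episode nor
#' the daily total may exceed the allowance (strictly more than 60 minutes
#' disqualifies; exactly 60 is allowed). Days with any overwritten minutes
#' are ineligible outright -- the data needed to verify the behavior no
#' longer exist. One reason is recorded per day with precedence
#' DATA_OVERWRITTEN > TAC_OVER > REMOVAL_OVER.
#'
#' @param day One row of [classify_days()] output (or a list with fields
#'   `date`, `peak_tac`, `removal_total`, `removal_max_episode`,
#'   `overwritten_minutes`, `unknown_missing_minutes`).
#' @param plan A [cm_plan()].
#' @return A one-row tibble: `date`, `eligible`, `reason`.
#' @export
assess_day <- function(day, plan = cm_plan()) {
  rt <- day$removal_total
  rm_max <- day$removal_max_episode
  if (plan$missing_counts_as_removal) {
    rt <- rt + day$unknown_missing_minutes
  }
  reason <- if (day$overwritten_minutes > 0) {
    "DATA_OVERWRITTEN"
  } else if (day$peak_tac >= plan$tac_threshold) {
    "TAC_OVER"
  } else if (rm_max > plan$max_removal_episode || rt > plan$max_removal_total) {
    "REMOVAL_OVER"
  } else {
    "ELIGIBLE"
  }
  tibble::tibble(date = as.Date(day$date), eligible = reason == "ELIGIBLE",
                 reason = reason)
}

#' Assess every day of a record table
#'
#' @param day_records Output of [classify_days()].
#' @param plan A [cm_plan()].
#' @return Tibble of per-day outcomes, one row per date.
#' @export
assess_days <- function(day_records, plan = cm_plan()) {
  rows <- lapply(seq_len(nrow(day_records)),
                 function(i) assess_day(day_records[i, ], plan))
  do.call(rbind, rows)
}

# day index (1-based within the window) of each meeting
.meeting_day_index <- function(schedule, window) {
  md <- as.Date(.min_to_date(schedule$minute))
  idx <- as.integer(md - window$dates[1L]) + 1L
  if (any(idx < 1L | idx > window$n_days)) {
    .stopf("schedule does not lie within the participation window")
  }
  idx
}

#' Compute the CM voucher ledger
#'
#' Daily award per eligible day; at each of meetings 2-7 a block bonus of
#' `bonus_per_block_day` times the block length, where a block is the run of
#' days after the previous meeting's day up to and including the meeting's
#' own day, paid only when every day of the block is eligible (for the
#' canonical Monday-start schedule the blocks have 2, 2, 3, 2, 2, 3 days,
#' giving bonuses of 10, 10, 15, 10, 10, 15 GBP); and the full-period bonus
#' when all window days are eligible. Maximum total under defaults: 75 + 70
#' + 35 = 180 GBP.
#'
#' @param outcomes Per-day outcome tibble from [assess_days()], covering
#'   every window day.
#' @param plan A [cm_plan()].
#' @param schedule A [meeting_schedule()].
#' @param window A [participation_window()].
#' @return A `cm_ledger` list: `day_outcomes` (with a `daily_award` column),
#'   `block_bonuses` (per meetings 2-7), `full_period_bonus_awarded`,
#'   `daily_total`, `bonus_total`, `total`.
#' @export
compute_ledger <- function(outcomes, plan = cm_plan(),
                           schedule = canonical_schedule(),
                           window = participation_window(schedule$meeting_datetimes[1])) {
  if (nrow(outcomes) != window$n_days ||
      !all(as.Date(outcomes$date) == window$dates)) {
    .stopf("outcomes must cover all %d window days exactly", window$n_days)
  }
  elig <- outcomes$eligible
  daily <- ifelse(elig, plan$daily_amount, 0)

  mday <- .meeting_day_index(schedule, window)
  blocks <- lapply(2:7, function(k) (mday[k - 1L] + 1L):mday[k])
  bonus <- vapply(blocks, function(b) {
    if (all(elig[b])) plan$bonus_per_block_day * length(b) else 0
  }, numeric(1))

  full <- all(elig)
  total <- sum(daily) + sum(bonus) + if (full) plan$full_period_bonus else 0

  out <- outcomes
  out$daily_award <- daily
  structure(
    list(day_outcomes = out,
         block_bonuses = tibble::tibble(meeting = 2:7,
                                        block_days = lengths(blocks),
                                        bonus = bonus),
         full_period_bonus_awarded = full,
         daily_total = sum(daily), bonus_total = sum(bonus),
         total = total,
         participant_id = attr(outcomes, "participant_id")),
    class = "cm_ledger"
  )
}

#' @export
print.cm_ledger <- function(x, ...) {
  cat(sprintf(
    "<cm_ledger> %d/%d days eligible; daily GBP %g + bonuses GBP %g%s = GBP %g\n",
    sum(x$day_outcomes$eligible), nrow(x$day_outcomes),
    x$daily_total, x$bonus_total,
    if (x$full_period_bonus_awarded) " + full-period bonus" else "",
    x$total))
  invisible(x)
}

#' Roll a cohort of ledgers up into an audit table
#'
#' Mirrors the per-participant audit report: days earned, total GBP, and
#' days not earned broken out by reason, with cohort totals and the
#' percentage of days earned at 1 decimal place.
#'
#' @param ledgers List of `cm_ledger` objects (optionally named by
#'   participant).
#' @return A list with `participants` (tibble, one row each) and `cohort`
#'   (days earned / total days, pct at 1 dp, GBP total, reason totals);
#'   see [audit_summary()] for the cohort roll-up from pre-tabulated counts.
#' @export
ledger_summary <- function(ledgers) {
  if (inherits(ledgers, "cm_ledger")) ledgers <- list(ledgers)
  ids <- names(ledgers)
  if (is.null(ids)) ids <- paste0("P", seq_along(ledgers))
  rows <- lapply(seq_along(ledgers), function(i) {
    l <- ledgers[[i]]
    rs <- l$day_outcomes$reason
    tibble::tibble(
      participant_id = ids[i],
      days_earned = sum(l$day_outcomes$eligible),
      days_not_earned = sum(!l$day_outcomes$eligible),
      total_gbp = l$total,
      tac_over = sum(rs == "TAC_OVER"),
      removal_over = sum(rs == "REMOVAL_OVER"),
      data_overwritten = sum(rs == "DATA_OVERWRITTEN")
    )
  })
  audit_summary(do.call(rbind, rows))
}

#' Cohort roll-up of a per-participant CM audit table
#'
#' Accepts a pre-tabulated audit table (as published study reports print
#' them: per-participant days earned / not earned, money totals, reason
#' counts) and computes the cohort summary: percentage of participant-days
#' earned at 1 dp and the cohort GBP total.
#'
#' @param audit Tibble/data.frame with columns `participant_id`,
#'   `days_earned`, `days_not_earned`, `total_gbp` and optionally per-reason
#'   counts (`tac_over`, `removal_over`, `data_overwritten`).
#' @return A list with `participants` (the input) and `cohort` (a one-row
#'   tibble: `days_earned`, `days_total`, `pct_days_earned`, `total_gbp`,
#'   and per-reason totals when present).
#' @export
audit_summary <- function(audit) {
  need <- c("participant_id", "days_earned", "days_not_earned", "total_gbp")
  if (!all(need %in% names(audit))) {
    .stopf("audit table must have columns: %s", paste(need, collapse = ", "))
  }
  days_earned <- sum(audit$days_earned)
  days_total <- sum(audit$days_earned + audit$days_not_earned)
  cohort <- tibble::tibble(
    days_earned = days_earned,
    days_total = days_total,
    pct_days_earned = round_half_up(100 * days_earned / days_total, 1),
    total_gbp = sum(audit$total_gbp)
  )
  for (r in c("tac_over", "removal_over", "data_overwritten")) {
    if (r %in% names(audit)) cohort[[r]] <- sum(audit[[r]])
  }
  list(participants = tibble::as_tibble(audit), cohort = cohort)
}
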