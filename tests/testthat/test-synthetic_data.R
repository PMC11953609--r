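test_that("cohort generation is deterministic under a fixed seed", {
  cfg <- synthetic_config(n_participants = 3, seed = 314)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(
    lapply(a$participants, function(p) list(p$series, p$tlfb, p$truth)),
    lapply(b$participants, function(p) list(p$series, p$tlfb, p$truth))
  )
})

test_that("episode curves have the configured shape", {
  expect_length(episode_tac_curve(0), 0L)

  c4 <- episode_tac_curve(4)
  expect_true(all(c4 >= 0))
  expect_equal(max(c4), 100)  # 25 ug/L per unit
  expect_lt(c4[length(c4)], 0.01 * max(c4) + 1e-9)
  # a typical 4-unit episode stays above 15 ug/L for more than 90 minutes
  expect_gt(sum(c4 > 15), 90)

  # doubling units doubles the peak below the cap; the cap binds above it
  expect_equal(max(episode_tac_curve(8)), 2 * max(c4))
  expect_equal(max(episode_tac_curve(100)), 250)

  # decay half-life recovered by log-linear fit within 1 minute
  peak_idx <- which.max(c4)
  tail_idx <- seq(peak_idx + 1, length(c4))
  fit <- lm(log(c4[tail_idx]) ~ tail_idx)
  half_life <- log(2) / -coef(fit)[[2]]
  expect_lt(abs(half_life - log(2) / 0.02), 1)
})

test_that("device emulation logs exactly the minutes that age out before a sync", {
  sched <- canonical_schedule(meeting_time_of_day = 1439L)
  n <- 15 * 1440
  full <- make_series(0:(n - 1), rep(0, n), rep(33, n))

  # all meetings attended with canonical spacing: nothing lost
  emu <- emulate_device(full, sched)
  expect_length(emu$overwritten_log, 0L)
  expect_length(emu$never_synced, 0L)
  expect_equal(nrow(emu$observed), n)

  # one missed mid-study meeting: the log is direct interval arithmetic
  att <- c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE)
  sched2 <- canonical_schedule(attended = att, meeting_time_of_day = 1439L)
  emu2 <- emulate_device(full, sched2)
  syncs <- sched2$minute[att]
  expected <- full$minute[vapply(full$minute, function(m) {
    nxt <- syncs[syncs >= m]
    length(nxt) > 0 && nxt[1] - m > 4320
  }, logical(1))]
  expect_equal(sort(emu2$overwritten_log), sort(expected))
  expect_gt(length(expected), 0L)

  # only meeting 1 attended: everything after it beyond the horizon is gone
  sched3 <- canonical_schedule(attended = c(TRUE, rep(FALSE, 6)),
                               meeting_time_of_day = 1439L)
  emu3 <- emulate_device(full, sched3)
  s1 <- sched3$minute[1]
  expect_equal(sort(emu3$never_synced), full$minute[full$minute > s1])
  expect_length(emu3$overwritten_log, 0L)
  expect_true(all(emu3$observed$minute <= s1))
})

test_that("true drinking prevalence falls in a 99% binomial band", {
  cfg <- synthetic_config(n_participants = 50, seed = 606,
                          p_drink = c(control = 0.4, cm = 0.4))
  co <- generate_cohort(cfg)
  drinks <- unlist(lapply(co$participants, function(p) p$truth$days$drinking))
  n <- length(drinks)
  expect_equal(n, 50 * 15)
  band <- qbinom(c(0.005, 0.995), n, 0.4)
  expect_gte(sum(drinks), band[1])
  expect_lte(sum(drinks), band[2])
})

test_that("emitted files parse back through the package readers unchanged", {
  cfg <- synthetic_config(n_participants = 2, seed = 11)
  co <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  expect_no_warning(write_cohort_csv(co, dir))
  p <- co$participants[[1]]
  id <- p$participant_id
  expect_no_warning({
    s2 <- read_tac_csv(file.path(dir, sprintf("tac_%s.csv", id)),
                       participant_id = id)
    t2 <- read_tlfb_csv(file.path(dir, sprintf("tlfb_%s.csv", id)))
    sc2 <- read_schedule(file.path(dir, sprintf("schedule_%s.csv", id)))
  })
  expect_equal(s2$minute, p$series$minute)
  expect_equal(s2$tac_raw, p$series$tac_raw, tolerance = 1e-10)
  expect_equal(t2$units, p$tlfb$units, tolerance = 1e-10)
  expect_equal(sc2$attended, p$schedule$attended)
})

test_that("without misreport or artifacts the sensor and self-report agree perfectly", {
  cfg <- noise_free_config(n_participants = 5, seed = 400,
                           bath_prob = 0, extra_removal_rate = 0)
  co <- generate_cohort(cfg)
  ref <- logical(0); test <- logical(0)
  for (p in co$participants) {
    pr <- process_participant(p$series, p$schedule, co$window)
    ref <- c(ref, p$tlfb$drinking)
    test <- c(test, pr$day_records$TAS15)
  }
  expect_equal(sum(ref & !test), 0L)
  expect_equal(sum(!ref & test), 0L)
  expect_gt(sum(ref), 0L)  # non-degenerate: some drinking days exist
})

test_that("invalid configurations name the offending field", {
  expect_error(synthetic_config(seed = 1, bath_prob = 1.5), "bath_prob")
  expect_error(synthetic_config(seed = 1, extra_removal_rate = -1),
               "extra_removal_rate")
  expect_error(synthetic_config(seed = 1, p_drink = c(control = 2, cm = 0.3)),
               "p_drink")
  expect_error(synthetic_config(n_participants = 0, seed = 1),
               "n_participants")
  expect_error(synthetic_config(n_participants = 2), "seed")
})

test_that("negative raw readings occur and clamping removes them end to end", {
  cfg <- synthetic_config(n_participants = 2, seed = 87)
  co <- generate_cohort(cfg)
  raw <- unlist(lapply(co$participants, function(p) p$series$tac_raw))
  expect_lt(min(raw), 0)
  clamped <- clamp_negative(co$participants[[1]]$series)
  expect_gte(min(clamped$tac), 0)
})
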