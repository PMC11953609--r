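test_that("negative TAC values clamp to zero and positives pass through", {
  s <- make_series(0:2, c(-5.2, 0, 10.1), rep(33, 3))
  expect_equal(clamp_negative(s)$tac, c(0, 0, 10.1))

  pos <- make_series(0:4, c(1, 2, 3, 4, 5), rep(33, 5))
  expect_equal(clamp_negative(pos)$tac, pos$tac_raw)

  set.seed(1)
  vals <- runif(1000, -50, 50)
  s2 <- make_series(0:999, vals, rep(33, 1000))
  out <- clamp_negative(s2)
  expect_true(min(out$tac) >= 0)
  expect_equal(out$tac, pmax(vals, 0))
  expect_equal(out$tac_raw, vals)  # raw values preserved
})

test_that("removal requires strictly more than two cold minutes", {
  three <- make_series(0:5, rep(0, 6), c(33, 29, 29, 29, 33, 33))
  eps <- find_removal_episodes(three)
  expect_equal(nrow(eps), 1L)
  expect_equal(eps$duration, 3L)

  two <- make_series(0:5, rep(0, 6), c(33, 29, 29, 33, 33, 33))
  expect_equal(nrow(find_removal_episodes(two)), 0L)

  # exactly 30 C is not below threshold
  border <- make_series(0:5, rep(0, 6), c(30, 30, 30, 30, 30, 30))
  expect_equal(nrow(find_removal_episodes(border)), 0L)
})

test_that("a warm minute or a gap terminates a cold run", {
  interrupted <- make_series(0:6, rep(0, 7), c(29, 29, 33, 29, 29, 29, 33))
  eps <- find_removal_episodes(interrupted)
  expect_equal(nrow(eps), 1L)  # only the 3-minute run after the warm minute
  expect_equal(eps$duration, 3L)

  gappy <- make_series(c(0, 1, 3, 4), rep(0, 4), rep(29, 4))
  expect_equal(nrow(find_removal_episodes(gappy)), 0L)  # two 2-min fragments
})

test_that("removal episodes match the brute-force run oracle on random traces", {
  set.seed(99)
  for (rep in 1:25) {
    tr <- random_trace(2000)
    s <- make_series(tr$minutes, tr$tac, tr$temp)
    eps <- find_removal_episodes(s)
    orc <- oracle_runs(tr$minutes, tr$temp < 30, 2L)
    expect_equal(nrow(eps), nrow(orc))
    if (nrow(orc) > 0) {
      expect_equal(tacwear:::.epoch_min(eps$start), orc$start + tacwear:::.epoch_min(t_origin))
      expect_equal(eps$duration, orc$n)
    }
  }
})

test_that("no minutes are attributed to overwriting when every sync gap is within 72 h", {
  sched <- canonical_schedule(meeting_time_of_day = 1439L)
  win <- participation_window(sched$meeting_datetimes[1])
  # sparse series with plenty of missing minutes
  offs <- seq(0, 15 * 1440 - 1, by = 7)
  s <- make_series(offs, rep(0, length(offs)), rep(33, length(offs)))
  expect_length(attribute_overwritten(s, sched, win), 0L)
})

test_that("a missed meeting creates an overwritten stretch older than 72 h before the next sync", {
  # meeting 4 missed: sync gap meeting 3 (day 5) -> meeting 5 (day 10)
  att <- c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE)
  sched <- canonical_schedule(attended = att, meeting_time_of_day = 1439L)
  win <- participation_window(sched$meeting_datetimes[1])
  grid <- win$grid_start:win$grid_end
  # nothing recorded at all: classification is purely interval arithmetic
  s <- make_series(0:10, rep(0, 11), rep(33, 11))
  over <- attribute_overwritten(s, sched, win)
  syncs <- sched$minute[att]
  # manual rule: minute overwritten iff next attended sync > 72 h away
  expected <- integer()
  for (m in setdiff(grid, s$minute)) {
    nxt <- syncs[syncs > m]
    if (length(nxt) && nxt[1] - m > 4320) expected <- c(expected, m)
  }
  expect_equal(sort(over), sort(expected))
  expect_gt(length(over), 0L)
  # the overwritten set must fall between meeting 3 and 72 h before meeting 5
  # (a missing minute at the sync time itself attributes to the later sync)
  expect_true(all(over >= syncs[3] & over <= syncs[4] - 4320))
})

test_that("wear map partitions the window and removal stays within recorded data", {
  sched <- canonical_schedule(meeting_time_of_day = 1439L)
  win <- participation_window(sched$meeting_datetimes[1])
  n <- 15 * 1440
  # full coverage, no removals
  full <- make_series(0:(n - 1), rep(0, n), rep(33, n))
  wm <- build_wear_map(clamp_negative(full), win, sched)
  expect_equal(unname(wm$counts[["WORN"]]), n)
  expect_equal(sum(wm$counts), n)

  # random coverage with removals and a missed meeting
  set.seed(5)
  att <- c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE)
  sched2 <- canonical_schedule(attended = att, meeting_time_of_day = 1439L)
  keep <- runif(n) > 0.2
  temp <- ifelse(runif(n) < 0.1, 27, 33)
  s2 <- make_series(which(keep) - 1L, rep(0, sum(keep)), temp[keep])
  wm2 <- build_wear_map(clamp_negative(s2), win, sched2)
  expect_equal(sum(wm2$counts), n)  # exact partition
  expect_lte(wm2$counts[["REMOVED"]], nrow(s2))  # removals are recorded minutes
  removed_minutes <- wm2$minute[wm2$class == "REMOVED"]
  expect_true(all(removed_minutes %in% s2$minute))

  # identical inputs give identical maps
  wm3 <- build_wear_map(clamp_negative(s2), win, sched2)
  expect_identical(wm2$class, wm3$class)
})

test_that("a series entirely outside the window is an error", {
  sched <- canonical_schedule()
  win <- participation_window(sched$meeting_datetimes[1])
  far <- make_series((20 * 1440):(20 * 1440 + 10), rep(0, 11), rep(33, 11))
  expect_error(build_wear_map(clamp_negative(far), win, sched), "outside")
})

test_that("minute summary reproduces percentages from counts", {
  wm <- structure(list(
    window = NULL, minute = NULL, class = NULL,
    counts = c(WORN = 373342L, REMOVED = 90982L,
               MISSING_OVERWRITTEN = 58986L, MISSING_UNKNOWN = 56730L),
    episodes = NULL, participant_id = "cohort"
  ), class = "wear_map")
  ms <- minute_summary(wm)
  expect_equal(ms$recorded, 464324L)
  expect_equal(ms$pct_recorded, 80.05)
  expect_equal(ms$pct_removed_of_recorded, 19.59)
})
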