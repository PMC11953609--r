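test_that("TAC reader parses, sorts and truncates to minute resolution", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "timestamp,tac_ug_L,temp_C",
    "2023-07-03 10:02:30,5.1,33.0",
    "2023-07-03 10:00:10,-2.0,33.1",
    "2023-07-03 10:01:59,0.0,32.9"
  ), path)
  s <- read_tac_csv(path)
  expect_s3_class(s, "tac_series")
  expect_equal(nrow(s), 3L)
  expect_true(all(diff(s$minute) > 0))
  expect_equal(s$tac_raw, c(-2.0, 0.0, 5.1))  # sorted ascending by time
  expect_equal(as.integer(format(s$timestamp, "%S")), rep(0L, 3))
})

test_that("duplicate minutes are collapsed to the last record with a warning", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "timestamp,tac_ug_L,temp_C",
    "2023-07-03 10:00:05,1.0,33.0",
    "2023-07-03 10:00:40,2.0,33.0",
    "2023-07-03 10:01:00,3.0,33.0"
  ), path)
  expect_warning(s <- read_tac_csv(path), "1 duplicate-minute")
  expect_equal(nrow(s), 2L)
  expect_equal(s$tac_raw, c(2.0, 3.0))
})

test_that("TAC reader rejects empty files and names unparseable rows", {
  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("timestamp,tac_ug_L,temp_C", empty)
  expect_error(read_tac_csv(empty), "empty")

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "timestamp,tac_ug_L,temp_C",
    "2023-07-03 10:00:00,1.0,33.0",
    "not-a-time,1.0,33.0",
    "2023-07-03 10:02:00,oops,33.0"
  ), bad)
  expect_error(read_tac_csv(bad), "lines 2, 3")
})

test_that("TAC series round-trips through CSV exactly", {
  set.seed(42)
  s <- make_series(sort(sample(0:5000, 300)),
                   round(runif(300, -5, 120), 3),
                   round(runif(300, 22, 36), 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_tac_csv(s, path)
  s2 <- read_tac_csv(path)
  expect_equal(s2$minute, s$minute)
  expect_equal(s2$tac_raw, s$tac_raw)
  expect_equal(s2$temp, s$temp)
})

test_that("TLFB reader validates and classifies drinking days", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("date,units", "2023-07-05,0.0", "2023-07-06,4.0"), path)
  tl <- read_tlfb_csv(path)
  expect_equal(nrow(tl), 2L)
  expect_equal(sum(tl$drinking), 1L)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("date,units", "2023-07-05,2.0", "2023-07-06,"), bad)
  expect_error(read_tlfb_csv(bad), "lines 2")

  neg <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("date,units", "2023-07-05,-1.0"), neg)
  expect_error(read_tlfb_csv(neg), "negative")

  expect_error(tlfb_days(rep(as.Date("2023-07-05"), 2), c(1, 2)), "duplicate")
})

test_that("a 15-day TLFB window round-trips", {
  dates <- as.Date("2023-07-03") + 0:14
  units <- c(0, 4, 0, 0, 12, 0, 8, 0, 0, 0, 6, 0, 0, 10, 0)
  tl <- tlfb_days(dates, units)
  path <- withr::local_tempfile(fileext = ".csv")
  write_tlfb_csv(tl, path)
  tl2 <- read_tlfb_csv(path)
  expect_equal(tl2$date, dates)
  expect_equal(tl2$units, units)
  expect_equal(nrow(tl2), 15L)
})

test_that("meeting schedules follow the Mon/Wed/Fri pattern over 15 days", {
  sched <- canonical_schedule(as.POSIXct("2023-07-03 10:00:00", tz = "UTC"))
  expect_length(sched$meeting_datetimes, 7L)
  expect_equal(format(sched$meeting_datetimes, "%a"),
               c("Mon", "Wed", "Fri", "Mon", "Wed", "Fri", "Mon"))
  expect_equal(as.integer(as.Date(sched$meeting_datetimes[7]) -
                            as.Date(sched$meeting_datetimes[1])), 14L)
  expect_true(all(diff(sched$minute) > 0))
  expect_equal(mean(sched$attended), 1)  # all attended: 100% attendance
})

test_that("schedule validation rejects wrong counts and ordering", {
  times <- as.POSIXct("2023-07-03 10:00:00", tz = "UTC") + 86400 * (0:5)
  expect_error(meeting_schedule(times), "7 meeting")
  times7 <- as.POSIXct("2023-07-03 10:00:00", tz = "UTC") + 86400 * c(0, 2, 1, 3, 4, 5, 6)
  expect_error(meeting_schedule(times7), "increasing")
})

test_that("schedule CSV round-trips including attendance flags", {
  sched <- canonical_schedule(attended = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE))
  path <- withr::local_tempfile(fileext = ".csv")
  write_schedule(sched, path)
  s2 <- read_schedule(path)
  expect_equal(s2$minute, sched$minute)
  expect_equal(s2$attended, sched$attended)
})

test_that("participation window spans whole calendar days", {
  w <- participation_window(as.POSIXct("2023-07-03 10:00:00", tz = "UTC"), 15L)
  expect_equal(w$n_days, 15L)
  expect_length(w$dates, 15L)
  expect_equal(w$grid_end - w$grid_start + 1L, 15L * 1440L)
  expect_true(w$end > w$start)
  expect_equal(format(w$end, "%H:%M"), "23:59")
})
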