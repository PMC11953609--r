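# Internal helpers shared across the pipeline. All time arithmetic is done on
# integer epoch minutes so that "consecutive minutes" is exact integer
# adjacency, never floating-point subtraction on POSIXct.

# Timestamps are timezone-naive local clock time; POSIXct in UTC is used as
# the carrier so day boundaries fall exactly at midnight of the stored clock.
.TZ <- "UTC"

.epoch_min <- function(t) {
  as.integer(floor(as.numeric(t) / 60))
}

.min_to_time <- function(m) {
  as.POSIXct(as.numeric(m) * 60, origin = "1970-01-01", tz = .TZ)
}

.min_to_date <- function(m) {
  as.Date(floor(m / 1440), origin = "1970-01-01")
}

.date_to_min <- function(d) {
  as.integer(as.numeric(as.Date(d)) * 1440L)
}

#' Round half away from zero
#'
#' Reporting-layer rounding. Unlike [base::round()], which rounds half to
#' even, ties are rounded up in magnitude (0.005 -> 0.01 at 2 digits),
#' matching the convention used for all printed percentages in this package.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(0.81959, 2)  # 0.82
#' round_half_up(2.5, 0)      # 3
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Maximal runs of consecutive minutes satisfying a condition.
#
# `minutes` is a strictly increasing integer vector (epoch minutes of the
# recorded samples); `cond` a parallel logical. A run is a maximal set of
# samples with cond TRUE whose minutes are pairwise adjacent (diff == 1):
# any missing minute or any FALSE sample breaks the run. Runs whose length
# is <= min_len (strict "greater than" on the minute count) are dropped.
#
# Returns a data.frame with columns start_min, end_min, n (run length in
# minutes), first_idx, last_idx into the input vectors.
.maximal_runs <- function(minutes, cond, min_len) {
  n <- length(minutes)
  if (n == 0L) {
    return(data.frame(start_min = integer(), end_min = integer(),
                      n = integer(), first_idx = integer(),
                      last_idx = integer()))
  }
  # a new run starts where cond turns TRUE or where a minute gap precedes
  brk <- c(TRUE, diff(minutes) != 1L)
  grp <- cumsum(brk | c(TRUE, cond[-n] != cond[-1L]))
  keep <- which(cond)
  if (length(keep) == 0L) {
    return(data.frame(start_min = integer(), end_min = integer(),
                      n = integer(), first_idx = integer(),
                      last_idx = integer()))
  }
  g <- grp[keep]
  first_idx <- keep[!duplicated(g)]
  last_idx <- keep[!duplicated(g, fromLast = TRUE)]
  out <- data.frame(
    start_min = minutes[first_idx],
    end_min = minutes[last_idx],
    first_idx = first_idx,
    last_idx = last_idx
  )
  out$n <- out$end_min - out$start_min + 1L
  out <- out[out$n > min_len, c("start_min", "end_min", "n",
                                "first_idx", "last_idx")]
  rownames(out) <- NULL
  out
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x == floor(x)
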