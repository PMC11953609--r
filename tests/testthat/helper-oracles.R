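# Independent oracles and fixture builders. Oracles are deliberately naive,
# loop-based, and share no code with the package implementations they check.

t_origin <- as.POSIXct("2023-07-03 00:00:00", tz = "UTC")

make_series <- function(minute_offsets, tac, temp, id = "P1") {
  tac_series(t_origin + 60 * minute_offsets, tac, temp, participant_id = id)
}

# brute-force maximal-run scan: walk the samples one by one, tracking the
# current run of consecutive minutes satisfying cond; emit runs with length
# strictly greater than min_len.
oracle_runs <- function(minutes, cond, min_len) {
  out <- list()
  run_start <- NA
  prev_min <- NA
  run_len <- 0
  for (i in seq_along(minutes)) {
    contiguous <- !is.na(prev_min) && minutes[i] == prev_min + 1
    if (cond[i]) {
      if (run_len > 0 && contiguous) {
        run_len <- run_len + 1
      } else {
        if (run_len > min_len) {
          out[[length(out) + 1]] <- c(run_start, prev_min, run_len)
        }
        run_start <- minutes[i]
        run_len <- 1
      }
    } else {
      if (run_len > min_len) {
        out[[length(out) + 1]] <- c(run_start, prev_min, run_len)
      }
      run_len <- 0
    }
    prev_min <- minutes[i]
  }
  if (run_len > min_len) {
    out[[length(out) + 1]] <- c(run_start, prev_min, run_len)
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(), end = integer(), n = integer()))
  }
  m <- do.call(rbind, out)
  data.frame(start = as.integer(m[, 1]), end = as.integer(m[, 2]),
             n = as.integer(m[, 3]))
}

# brute-force CM ledger total for the canonical meeting days 1,3,5,8,10,12,15
# and default amounts; enumerates every rule explicitly.
oracle_ledger_total <- function(elig) {
  stopifnot(length(elig) == 15)
  total <- 5 * sum(elig)
  blocks <- list(2:3, 4:5, 6:8, 9:10, 11:12, 13:15)
  for (b in blocks) if (all(elig[b])) total <- total + 5 * length(b)
  if (all(elig)) total <- total + 35
  total
}

# independent BCa implementation: same statistic, separately coded bias
# correction, jackknife acceleration and interval lookup.
oracle_bca <- function(x, y, indices, conf = 0.95) {
  spearman <- function(a, b) cor(rank(a), rank(b))
  theta <- spearman(x, y)
  boots <- apply(indices, 1, function(ix) spearman(x[ix], y[ix]))
  boots <- boots[!is.na(boots)]
  z0 <- qnorm(sum(boots < theta) / length(boots))
  n <- length(x)
  jack <- sapply(seq_len(n), function(i) spearman(x[-i], y[-i]))
  L <- mean(jack) - jack
  a <- sum(L^3) / (6 * sum(L^2)^1.5)
  zl <- qnorm((1 - conf) / 2); zu <- qnorm(1 - (1 - conf) / 2)
  p1 <- pnorm(z0 + (z0 + zl) / (1 - a * (z0 + zl)))
  p2 <- pnorm(z0 + (z0 + zu) / (1 - a * (z0 + zu)))
  quantile(boots, c(p1, p2), names = FALSE, type = 6)
}

# textbook pooled-variance two-sample t statistic
oracle_pooled_t <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# random TAC/temperature trace with gaps, for oracle comparisons
random_trace <- function(n, gap_prob = 0.1) {
  keep <- runif(n) > gap_prob
  minutes <- which(keep)
  list(
    minutes = minutes,
    tac = round(runif(length(minutes), 0, 40), 1),
    temp = round(runif(length(minutes), 25, 36), 1)
  )
}
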