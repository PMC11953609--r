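#' Build a day-level confusion matrix against self-report
#'
#' TLFB self-report is the reference standard; the sensor classification is
#' the test. `tp` counts days both call drinking, `tn` days both call
#' non-drinking, `fp` sensor-only drinking days, `fn` self-report-only
#' drinking days. Days present in only one source are excluded and returned
#' in the exclusion log, never silently dropped.
#'
#' @param tlfb_flags Named logical vector (names are dates) of reference
#'   drinking-day flags.
#' @param tas_flags Named logical vector over the same dates.
#' @param strict Error when the date sets differ (default TRUE); with
#'   `strict = FALSE` the intersection is used and exclusions logged.
#' @return A `confusion_matrix` list: `tp`, `fn`, `fp`, `tn`, `total`,
#'   `excluded` (character dates).
#' @export
build_confusion <- function(tlfb_flags, tas_flags, strict = TRUE) {
  if (is.null(names(tlfb_flags)) || is.null(names(tas_flags))) {
    .stopf("flag vectors must be named by date")
  }
  common <- intersect(names(tlfb_flags), names(tas_flags))
  excluded <- c(setdiff(names(tlfb_flags), common),
                setdiff(names(tas_flags), common))
  if (strict && length(excluded)) {
    .stopf("date sets differ: %s", paste(sort(excluded), collapse = ", "))
  }
  ref <- as.logical(tlfb_flags[common])
  test <- as.logical(tas_flags[common])
  structure(
    list(tp = sum(ref & test), fn = sum(ref & !test),
         fp = sum(!ref & test), tn = sum(!ref & !test),
         total = length(common), excluded = sort(excluded)),
    class = "confusion_matrix"
  )
}

#' Construct a confusion matrix from its four cells
#' @param tp,fn,fp,tn Non-negative integer counts (reference = self-report).
#' @return A `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fn, fp, tn) {
  cells <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(cells < 0) || any(cells != floor(cells))) {
    .stopf("confusion cells must be non-negative integers")
  }
  structure(c(as.list(cells), list(total = sum(cells), excluded = character())),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> n=%d  tp=%d fn=%d fp=%d tn=%d\n",
              x$total, x$tp, x$fn, x$fp, x$tn))
  invisible(x)
}

#' Diagnostic agreement statistics
#'
#' Sensitivity, specificity, positive and negative predictive value (as
#' percentages) and percentage accuracy in classification (PAC, a 0-1
#' proportion), with self-report as the reference. A statistic whose
#' denominator is zero is undefined and reported as `NA`, never as 0.
#' Internal values are full precision; `rounded = TRUE` applies the
#' reporting convention (percentages and PAC at `digits` dp, half up).
#'
#' @param cm A `confusion_matrix`.
#' @param digits Reporting decimal places (default 2).
#' @param rounded Round for reporting? Default TRUE.
#' @return A tibble row: `sensitivity`, `specificity`, `ppv`, `npv`
#'   (percent), `pac` (proportion).
#' @export
#' @examples
#' diagnostics(confusion_matrix(tp = 139, fn = 39, fp = 31, tn = 179))
diagnostics <- function(cm, digits = 2L, rounded = TRUE) {
  stopifnot(inherits(cm, "confusion_matrix"))
  frac <- function(num, den) if (den > 0) num / den else NA_real_
  out <- tibble::tibble(
    sensitivity = 100 * frac(cm$tp, cm$tp + cm$fn),
    specificity = 100 * frac(cm$tn, cm$tn + cm$fp),
    ppv = 100 * frac(cm$tp, cm$tp + cm$fp),
    npv = 100 * frac(cm$tn, cm$tn + cm$fn),
    pac = frac(cm$tp + cm$tn, cm$total)
  )
  if (rounded) out[] <- lapply(out, round_half_up, digits = digits)
  out
}

#' Spearman correlation with a BCa bootstrap interval
#'
#' The coefficient is the Pearson correlation of the average-ranked data
#' (ties receive average ranks). The 95% confidence interval is a
#' bias-corrected and accelerated (BCa) bootstrap: pairs are resampled,
#' the bias correction z0 comes from the fraction of bootstrap replicates
#' below the observed value, and the acceleration from the jackknife
#' skewness of the statistic.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @param n_boot Bootstrap replicates (default 10000).
#' @param seed Integer seed; required so results are reproducible.
#' @param conf Confidence level (default 0.95).
#' @param indices Optional precomputed `n_boot x length(x)` matrix of
#'   resample indices (advanced; used for cross-validation against other
#'   implementations).
#' @return A tibble row: `rho`, `ci_low`, `ci_high`, `n`, `n_boot`, `seed`.
#' @export
spearman_bca <- function(x, y, n_boot = 10000L, seed, conf = 0.95,
                         indices = NULL) {
  n <- length(x)
  if (length(y) != n) .stopf("x and y lengths differ")
  if (n < 3L) .stopf("need at least 3 pairs")
  if (missing(seed) && is.null(indices)) .stopf("seed is required")
  seed_out <- if (missing(seed)) NA_integer_ else as.integer(seed)

  rho_of <- function(xx, yy) {
    rx <- rank(xx, ties.method = "average")
    ry <- rank(yy, ties.method = "average")
    if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(NA_real_)
    sum((rx - mean(rx)) * (ry - mean(ry))) /
      sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  }
  rho <- rho_of(x, y)
  if (is.na(rho)) {
    return(tibble::tibble(rho = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, n = n,
                          n_boot = as.integer(n_boot), seed = seed_out))
  }

  if (is.null(indices)) {
    set.seed(as.integer(seed))
    indices <- matrix(sample.int(n, n_boot * n, replace = TRUE),
                      nrow = n_boot)
  } else {
    n_boot <- nrow(indices)
  }
  boots <- vapply(seq_len(nrow(indices)), function(b) {
    ix <- indices[b, ]
    rho_of(x[ix], y[ix])
  }, numeric(1))
  boots <- boots[!is.na(boots)]

  # bias correction: proportion of replicates below the point estimate
  z0 <- stats::qnorm(mean(boots < rho))
  # acceleration from jackknife values
  jack <- vapply(seq_len(n), function(i) rho_of(x[-i], y[-i]), numeric(1))
  jack <- jack[is.finite(jack)]
  a <- 0
  if (length(jack) >= 3) {
    jm <- mean(jack)
    num <- sum((jm - jack)^3)
    den <- 6 * (sum((jm - jack)^2))^1.5
    if (is.finite(den) && den > 0) a <- num / den
  }

  alpha <- (1 - conf) / 2
  adj <- function(p) {
    z <- z0 + stats::qnorm(p)
    stats::pnorm(z0 + z / (1 - a * z))
  }
  if (!is.finite(z0)) {
    ci <- stats::quantile(boots, c(alpha, 1 - alpha), names = FALSE, type = 6)
  } else {
    ci <- stats::quantile(boots, c(adj(alpha), adj(1 - alpha)),
                          names = FALSE, type = 6)
  }
  tibble::tibble(rho = rho, ci_low = ci[1], ci_high = ci[2], n = n,
                 n_boot = as.integer(n_boot), seed = seed_out)
}

#' Two-group comparison of per-participant metrics
#'
#' Pooled-variance two-sample t test (df = n1 + n2 - 2) with group means,
#' SDs and Cohen's d, matching the between-arm comparisons used for
#' attendance, abstinent-day and consumption summaries.
#'
#' @param values Numeric vector, one value per participant.
#' @param group Factor/vector with exactly two levels.
#' @return A tibble row: group ns, means, SDs, `t`, `df`, `p`, `cohens_d`.
#' @export
group_summary <- function(values, group) {
  group <- factor(group)
  if (nlevels(group) != 2L) .stopf("exactly two groups required")
  split_v <- split(values, group)
  n <- lengths(split_v)
  if (any(n < 2L)) .stopf("each group needs n >= 2")
  sp <- sqrt(((n[1] - 1) * stats::var(split_v[[1]]) +
                (n[2] - 1) * stats::var(split_v[[2]])) / (sum(n) - 2))
  if (sp > 0) {
    tt <- stats::t.test(split_v[[1]], split_v[[2]], var.equal = TRUE)
    t_stat <- unname(tt$statistic)
    df <- unname(tt$parameter)
    p <- tt$p.value
  } else {
    # degenerate: zero pooled variance; identical means give t = 0, p = 1
    t_stat <- if (mean(split_v[[1]]) == mean(split_v[[2]])) 0 else
      sign(mean(split_v[[1]]) - mean(split_v[[2]])) * Inf
    df <- sum(n) - 2
    p <- if (t_stat == 0) 1 else 0
  }
  d <- if (sp > 0) (mean(split_v[[1]]) - mean(split_v[[2]])) / sp else 0
  tibble::tibble(
    group1 = levels(group)[1], group2 = levels(group)[2],
    n1 = n[[1]], n2 = n[[2]],
    mean1 = mean(split_v[[1]]), mean2 = mean(split_v[[2]]),
    sd1 = stats::sd(split_v[[1]]), sd2 = stats::sd(split_v[[2]]),
    t = t_stat, df = df, p = p, cohens_d = d
  )
}
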