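---
title: "Methods: minute-level TAC analysis, CM accounting, and agreement statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: minute-level TAC analysis, CM accounting, and agreement statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tacwear)
```

This vignette documents the model, the numerical conventions, and the design
decisions behind `tacwear`. The package analyses minute-resolution transdermal
alcohol concentration (TAC, µg/L) and skin temperature (°C) series from a
wrist-worn sensor over a fixed multi-day participation window, applies a
contingency-management (CM) voucher schedule, and quantifies day-level
agreement with timeline-followback (TLFB) self-report.

## 1. Time model

All timestamps are UTC. A reading's timestamp is floored to its minute and
converted to an integer *epoch minute* `floor(unix_seconds / 60)`; all
adjacency, run, and gap logic is exact integer arithmetic on these minutes, so
there is no floating-point time anywhere in the pipeline. The participation
window (`participation_window()`) starts at midnight of the first meeting day
and spans `n_days × 1440` minutes (default 15 days = 21,600 minutes); a
calendar day is the half-open block of 1440 minutes starting at its midnight.

## 2. Wear classification

`build_wear_map()` assigns every window minute exactly one of four classes;
the classes always partition the window (asserted, and tested):

* **WORN** — recorded, and not part of a removal episode.
* **REMOVED** — recorded, skin temperature strictly below 30 °C, inside a
  maximal run of *consecutive recorded minutes* strictly longer than 2
  minutes. Two cold minutes are not a removal; a warm minute or a recording
  gap terminates a run. Runs are found with a vectorised cumulative-sum
  grouping (`.maximal_runs`), validated in tests against a brute-force loop
  oracle on random traces.
* **MISSING_OVERWRITTEN** — not recorded, and attributable to the device's
  finite rolling storage (default horizon 4320 minutes = 72 h): data are only
  persisted when the device is synced at an *attended* meeting, so a missing
  minute `m` is overwritten iff the next attended sync `s` satisfies
  `s − m > horizon` (strict), or no later sync exists. The boundary
  `s − m = horizon` survives: it is the oldest minute still in memory at the
  sync.
* **MISSING_UNKNOWN** — not recorded, not attributable to overwriting
  (device off, dead battery, Bluetooth loss — indistinguishable causes).

Negative raw TAC values (sensor noise) are clamped to zero by
`clamp_negative()` before any analysis; raw values are preserved in
`tac_raw`.

## 3. Drinking-event detection

A drinking event under criterion (T, D) is a maximal run of consecutive
recorded minutes with clamped TAC strictly above T lasting strictly more than
D minutes. The standard criteria (`default_criteria()`) are TAS15, TAS60 and
TAS90: T = 15 µg/L with D = 15, 60, 90 minutes. Missing minutes never count
toward an event's duration; by default a recording gap breaks a run
(`gap_tolerance = 0`), and an optional tolerance can bridge short gaps that
contain no recorded below-threshold minute.

Because the three criteria share a threshold and differ only in minimum
duration, every TAS90 event is a TAS60 event is a TAS15 event, so the
drinking-day sets nest (TAS90 ⊆ TAS60 ⊆ TAS15); `criterion_nesting_check()`
verifies this on any classified output and the test suite verifies it on
synthetic cohorts. An event spanning midnight flags *both* calendar days it
touches. For daily CM accounting, removal episodes that span midnight are
split at the boundary: each day is charged only the minutes falling inside
it, while the *episode* length test uses the day's longest (possibly
truncated) segment.

## 4. CM voucher ledger

`assess_days()` marks each day eligible or ineligible with a single audit
reason, applied in precedence order:

1. **DATA_OVERWRITTEN** — any minute of the day overwritten (unverifiable
   data can never earn).
2. **TAC_OVER** — daily peak clamped TAC ≥ 115.660 µg/L (eligibility
   requires strictly below the threshold).
3. **REMOVAL_OVER** — longest removal episode > 60 min *or* total removal
   minutes > 60 min (exactly 60 is allowed). By default, `MISSING_UNKNOWN`
   minutes also count toward the daily removal total
   (`missing_counts_as_removal = TRUE`): an unverifiable minute is treated
   conservatively as potential non-wear. This is a documented modelling
   choice, switchable in `cm_plan()`.
4. **ELIGIBLE** otherwise.

`compute_ledger()` then prices the window:

* £5 per eligible day (max £75 over 15 days).
* Block bonuses at meetings 2–7: a block is the run of days *after the
  previous meeting's day up to and including this meeting's day*; if every
  day in the block is eligible, the bonus is £5 × block length. On the
  canonical Monday-start schedule (meetings on days 1, 3, 5, 8, 10, 12, 15)
  the block lengths are 2, 2, 3, 2, 2, 3, giving £10, £10, £15, £10, £10,
  £15 = £70. We considered an alternative reading in which a block excludes
  the meeting day itself; that reading cannot reproduce the published £70
  bonus total, so the inclusive reading is implemented.
* £35 full-period bonus when all 15 days are eligible.

Maximum payout is therefore £75 + £70 + £35 = £180. The test suite
exhaustively enumerates all 2^15 eligibility patterns and checks the ledger
against an independent oracle, that £180 is attained only by the all-eligible
pattern, and that payout is monotone in eligibility.

## 5. Agreement statistics

Day-level agreement takes TLFB self-report as the reference standard.
`build_confusion()` aligns the two day sets strictly (mismatches are errors
unless explicitly relaxed, and exclusions are always logged); pipeline-level
pooling excludes days with zero recorded sensor minutes, since the sensor
cannot classify them. `diagnostics()` reports sensitivity, specificity, PPV
and NPV as percentages and PAC = (TP + TN)/N as a proportion; any statistic
with a zero denominator is `NA`, never 0.

`spearman_bca()` computes the Spearman coefficient as the Pearson correlation
of average-ranked data and a 95% bias-corrected and accelerated (BCa)
bootstrap interval: pairs are resampled `n_boot` times (default 10,000, with
a mandatory seed), the bias correction is `z0 = Φ⁻¹(fraction of replicates
below ρ̂)`, the acceleration comes from the jackknife skewness, and adjusted
quantiles use type-6 interpolation. Degenerate cases are handled explicitly:
constant ranks give `NA`; an infinite `z0` (all replicates on one side) falls
back to percentile quantiles; a degenerate jackknife sets the acceleration to
zero. A precomputed resample-index matrix can be supplied so the
implementation can be cross-validated replicate-by-replicate against an
independent one — the test suite does exactly that. `group_summary()` wraps
the pooled-variance two-sample t test (`stats::t.test(var.equal = TRUE)`)
with Cohen's d, with an explicit zero-pooled-variance branch.

## 6. Synthetic cohort generator

`generate_cohort(synthetic_config(...))` emulates a two-arm study so the
pipeline can run and be validated without participant data. Defaults describe
the study conditions being modelled and are not tuned to any analysis
outcome:

* **Cohort**: 29 participants, 15 days starting Monday 2023-07-03, 1:1
  allocation (control / CM); meetings on days 1, 3, 5, 8, 10, 12, 15 at
  end of day (minute 1439), each missed independently with probability
  0.089.
* **Drinking**: per-day drinking probability 0.5 (control) / 0.3 (CM);
  intake per episode lognormal (meanlog `log(12)`, sdlog 0.5) UK units;
  episode start uniform in 16:00–18:00.
* **Kinetics**: 30-min absorption lag, linear rise 1.5 µg/L/min to a peak of
  25 µg/L per unit capped at 250 µg/L, then exponential decay at 0.02/min.
  With these parameters the above-threshold portion of an episode never
  crosses midnight, which makes the ground-truth drinking-day labels exact.
* **Nuisance processes**: baseline sensor noise (SD 1 µg/L) with occasional
  negative dips (p = 0.05); skin temperature ~33 ± 1 °C with per-minute noise
  (SD 0.3) and a 5% chance of a cold-running baseline (29.5 °C); ambient
  temperature 22 ± 2 °C during removals; a daily bath/shower removal
  (p = 0.8, 20–50 min) plus extra removals (rate 1/day, lognormal lengths);
  ambient TAC spikes (rate 0.1/day, 50–300 µg/L, 1–8 min); device recording
  gaps (rate 0.3/day, lognormal lengths 5–720 min).
* **Device memory**: `emulate_device()` applies the same 72-h rolling-storage
  survival rule as the analysis side — a minute survives iff an attended
  sync occurs within the horizon — and logs what it discards.
* **Self-report**: TLFB omits a true drinking day with probability 0.08
  (misreporting).

Ground truth (per-day drinking flags per criterion, removal minutes,
overwritten minutes, wear-class counts) is computed during construction by a
separate run-length-encoding interval routine on the generating masks — an
independent code path from the analysis detectors — so recovery tests are
meaningful. `noise_free_config()` zeroes every nuisance process; under it the
test suite requires the pipeline to recover the ground truth *exactly*:
wear-class counts, removal minute sets, overwritten minute sets, and all
three criteria's drinking-day flags.

What the generator deliberately does **not** model: pharmacokinetic
individual variability beyond dose, diurnal temperature rhythms, sensor
drift, overlapping same-day episodes, or partial syncs.

## 7. Numerical conventions

* Rounding for reporting is half away from zero (`round_half_up()`), applied
  only at the reporting layer: percentages at 2 dp, cohort day-percentages at
  1 dp, PAC at 2 dp. All upstream values are full precision.
* All run/gap logic is integer; currency is exact in whole pounds times
  five, so no floating-point money issues arise.
* Randomness is confined to `synthetic_config(seed = ...)` and the bootstrap
  seed; identical configurations reproduce identical cohorts, ledgers and
  intervals.

## 8. Problem sizes exercised

The tests and the acceptance script run, among others: 1000 random traces of
50–2000 minutes against loop oracles; the full 2^15 ledger enumeration;
cohorts of 6–50 synthetic participants (up to 1.08 million window minutes);
bootstrap intervals with 2000–10,000 replicates; and an exact-recovery cohort
of 8 noise-free participants with forced missed meetings so overwriting is
actually exercised.

## 9. Limitations

The 30 °C/2-min removal rule and the TAS criteria are operating definitions,
not physiological truths; borderline skin temperatures (cold environments,
poor contact) can misclassify wear. Overwriting attribution assumes the
device syncs fully at every attended meeting. The conservative
`missing_counts_as_removal` default can mark genuinely worn-but-unrecorded
days ineligible. Day-level agreement inherits TLFB's own recall error, which
the generator models only as simple omission.
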