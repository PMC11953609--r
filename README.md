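# tacwear

Minute-level analysis of wrist-worn transdermal alcohol sensor (TAS) data,
with contingency-management (CM) reward accounting and day-level agreement
statistics against timeline-followback (TLFB) self-report.

Transdermal sensors such as the BACtrack Skyn sample transdermal alcohol
concentration (TAC, µg/L) and skin temperature (°C) once a minute. Turning
that stream into clinically usable outcomes requires solving four problems
that this package implements as a tested pipeline:

1. **Wear classification.** Every minute of a participation window is
   exactly one of *worn*, *removed* (skin temperature < 30 °C for > 2
   consecutive recorded minutes — the device is off the body), *missing
   (overwritten)* — lost because the device's 72-hour rolling storage aged
   out before a data download at an attended research meeting — or *missing
   (unknown)*. The four classes always partition the window.
2. **Drinking-day detection.** An alcohol event is a maximal run of
   consecutive recorded minutes with TAC strictly above a threshold, lasting
   strictly longer than a minimum duration. The standard criteria are
   TAS15/TAS60/TAS90: TAC > 15 µg/L for > 15/60/90 min. A calendar day
   (midnight–11:59 PM) is a drinking day under a criterion when any
   qualifying event touches it; day sets nest: TAS90 ⊆ TAS60 ⊆ TAS15.
3. **CM ledger.** A day earns a £5 voucher when its peak TAC stays strictly
   below 115.660 µg/L and removals stay within a one-hour daily allowance;
   meetings 2–7 add block bonuses of £5 per day of a fully eligible
   inter-meeting block (£10, £10, £15, £10, £10, £15 on the canonical
   Monday-start schedule), and a £35 bonus rewards a fully eligible window:
   £75 + £70 + £35 = £180 maximum. The ledger carries one audit reason per
   ineligible day (data overwritten / TAC over / removal over).
4. **Agreement statistics.** With TLFB as the reference standard,
   day-level confusion matrices give sensitivity, specificity, PPV, NPV
   (percent) and PAC = (TP+TN)/N; drinking-day counts are compared by
   Spearman rank correlation with bias-corrected and accelerated (BCa)
   bootstrap intervals, and arms by pooled-variance t tests.

Because raw participant data of this kind are rarely shareable, the package
includes a synthetic cohort generator (`generate_cohort()`) that emulates
the whole study — episode kinetics, removals, storage overwriting, ambient
spikes, negative sensor noise, imperfect self-report — and returns ground
truth labels, so the entire pipeline runs and is validated end to end with
no external data.

## Worked example

```r
library(tacwear)
run <- run_pipeline(synthetic_config(n_participants = 8, seed = 42))
render_report(run)
```

```
# Sensor vs self-report agreement

| criterion | sensitivity | specificity | PPV | NPV | PAC |
|---|---|---|---|---|---|
| TAS15 | 94.12 | 97.53 | 94.12 | 97.53 | 0.97 |
| TAS60 | 94.12 | 97.53 | 94.12 | 97.53 | 0.97 |
| TAS90 | 91.18 | 97.53 | 93.94 | 96.34 | 0.96 |

# Minute accounting

- Recorded: 157561/172800 minutes (91.18%)
- Removal share of recorded: 22145/157561 minutes (14.05%)

# CM rewards

- Days earned: 12/60 (20.0%)
- Cohort total: GBP 60

# Drinking-day correlation

- Spearman rho = 0.883 (BCa 95% CI 0.107 to 0.981, n = 8)
```

Reading the output: each criterion row gives the day-level diagnostic
performance of the sensor classification against self-report on the 8
synthetic participants (sensitivity = detected drinking days among reported
drinking days; PAC is the overall proportion correctly classified). Minute
accounting shows how much of the 8 × 15-day window was recorded and how
much of the recorded time looked off-body. The CM section applies the
voucher schedule to the incentivized arm only — with heavy drinkers and
realistic removal behavior most days are ineligible, which is why only
12/60 days earned rewards. The correlation compares per-participant
drinking-day counts between the two measures; the wide BCa interval
reflects n = 8.

Lower-level entry points: `read_tac_csv()` / `read_tlfb_csv()` /
`read_schedule()` for your own data, `clamp_negative()`,
`build_wear_map()`, `detect_events()`, `classify_days()`, `assess_days()` +
`compute_ledger()` + `ledger_summary()`, `build_confusion()` +
`diagnostics()`, and `spearman_bca()`.

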