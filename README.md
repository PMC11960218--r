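# timeusecoda

Compositional comparison of device-measured and self-reported 24-hour time
use in children.

## The problem

How long children sleep, sit, and move each day is measured either with a
wrist accelerometer or with a 24-hour recall interview — and the two methods
systematically disagree. Because a day's sleep, sedentary time, light
physical activity (LPA) and moderate-to-vigorous physical activity (MVPA)
compete for a fixed total of 1440 minutes, the four durations form a
*composition*: over-reporting one behaviour forces under-reporting of
others, so method differences must be analysed jointly, not behaviour by
behaviour. This package is for researchers who want to quantify
device-vs-self-report divergence and ask which child characteristics (sex,
age, puberty, parental education, zBMI, aerobic fitness, academic
performance) are associated with it.

## What it implements

* **Device processing** — signal vector magnitude
  `SVM = |sqrt(ax² + ay² + az²) − 1 g|`, 1-minute epochs (mean SVM × 60,
  sampling-rate invariant), log-based sleep and non-wear labelling,
  MET-band cut-point classification (sedentary < 1.5 METs, LPA 1.5–2.99,
  MVPA ≥ 3), 40/40/20 MVPA/LPA/sedentary replacement of sports non-wear,
  valid-day (≤ 6 h non-wear, ≥ 10 h waking wear) and valid-participant
  (≥ 4 valid days incl. a weekend day) rules, and linear closure of each day
  to 1440 min.
* **Recall processing** — diary compilation at 5-minute resolution with the
  same MET bands, and the < 300 min/day sleep exclusion.
* **Matching & agreement** — date-matched day pairing, per-participant
  averaging, ICC(2,1) (two-way random effects, absolute agreement, with
  McGraw–Wong CIs), Bland–Altman bias and 95% limits of agreement, and MAPE
  (self-report as forecast, device as actual).
* **Compositional multilevel model** — isometric log-ratio coordinates
  z = √(rs/(r+s))·ln(g(num)/g(den)) over a configurable sequential binary
  partition, stacked 6-rows-per-child mixed models
  (`ilr × method × characteristic` fixed effects; wave, school and
  per-coordinate participant random effects), omnibus Wald χ² interaction
  tests with 3(L−1) df, back-transformed min/day composition estimates, and
  the converging / diverging / isomorphic / inverting pattern taxonomy.
* **Synthetic cohort generator** — ground-truth behaviour schedules, raw
  triaxial signals, wear logs and reporting-biased recall diaries with a
  single-seed determinism contract, so the whole pipeline is testable
  without any cohort data.

## Worked example

```r
library(timeusecoda)

cfg <- run_config(
  cohort = cohort_config(n_participants = 30, seed = 7),
  characteristics = c("sex", "zbmi")
)
res <- run_pipeline(cfg)
res
#> Pipeline result: 30 participants, 60 matched days (config 8c9399d9)
#>
#> Agreement (self vs device):
#>  behaviour       icc      bias  mape_pct
#>      sleep 0.8649555  28.89374  5.272937
#>        sed 0.9300518  16.07170  4.340765
#>        lpa 0.5828276 -82.00024 30.397019
#>       mvpa 0.5940589  37.03479 52.375674
#>
#> Method-by-characteristic interactions:
#>  characteristic     chi2 df         p n_participants significant
#>             sex 5.640452  3 0.1304752             30       FALSE
#>            zbmi 1.882611  3 0.5971249             30       FALSE
```

The agreement table reads: relative to the device, this synthetic cohort's
self-reports overstate sleep by ~29 min/day and MVPA by ~37 min/day while
understating LPA by ~82 min/day (the generator's default reporting biases),
with MVPA the least reliable behaviour in percentage terms. The interaction
table asks whether the device-vs-self divergence varies with each
characteristic; at n = 30 neither effect is detectable. Individual stages
are available as plain functions (`compute_svm()`, `label_day()`,
`compile_recall_day()`, `match_days()`, `icc_2_1()`, `bland_altman()`,
`build_stacked()`, `fit_interaction_model()`, `estimate_compositions()`,
`classify_pattern()`, ...), with `tidy()`/`glance()` methods and
`autoplot()`/`plot_estimates()` displays.

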