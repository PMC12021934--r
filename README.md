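# actiscan

Sleep-anchored hourly physical-activity exposures and survey-weighted
glycaemic association scans for minute-level wrist actigraphy.

## The problem

Activity guidelines prescribe *how much* to move; this package asks
*when* movement matters. Given minute-level wrist-accelerometry records
(MIMS values with wear/sleep classifications), `actiscan`:

1. applies valid-minute and valid-day (≥ 20 h) rules and a fully audited
   cohort exclusion cascade;
2. detects nightly sleep onset and offset with a mirrored rolling
   30-minute rule (≥ 15 sleep minutes per window) on a 20:00–10:00 night
   axis, and derives each person's overall and weekend sleep midpoints;
3. collapses activity into 24 hourly mean-MIMS exposures in two framings —
   clock time, and hours relative to the sleep midpoint (a practical
   circadian-phase proxy);
4. for every hourly window, fits a survey-weighted logistic (prevalent
   diabetes) or linear (log-scale fasting glucose, insulin, HOMA-IR, 2-h
   OGTT glucose) regression on activity **quintiles** with covariate
   adjustment, a design-based variance (weight-robust sandwich or
   stratified/PSU Taylor linearization), and a Wald trend test over the
   quintile index:

   `logit P(diabetes) = α + Σ_q β_q 1[Q = q] + γ'x`, with Q1 (lowest
   activity) as reference and per-window quintiles recomputed;
5. reports the 24-window grid as a tidy object with `tidy()`, `glance()`,
   `autoplot()` methods, plus subgroup (gender, age, chronotype, sleep
   duration) and extreme-sleep sensitivity analyses.

A synthetic cohort generator with known ground truth (sleep timing,
diurnal activity profile, survey design, configurable window-specific
effects on the outcomes) makes every stage testable and powers the
type-I-error and parameter-recovery simulation machinery. See the
methods vignette (`vignettes/activity-timing-methods.Rmd`) for the full
model description.

## Worked example

Simulate a cohort of 800 with a protective activity effect injected at
midpoint-relative window 13 (12–13 h after the sleep midpoint — the
afternoon for a typical 03:00 midpoint), run the full pipeline, and scan:

```r
library(actiscan)
cfg <- sim_config(n_participants = 800, n_days = 7,
                  effect_window = 13, effect_log_or = -0.3)
res <- run_pipeline(sim = cfg, analysis = "diabetes", framing = "relative",
                    out_dir = "run1", seed = 2024)
glance(res$scans$relative)
#> # A tibble: 1 × 8
#>   outcome  family   framing  n_windows n_estimable n_used extreme_window min_p_trend
#>   <chr>    <chr>    <chr>        <int>       <int>  <int>          <int>       <dbl>
#> 1 diabetes binomial relative        24          24    800             13  0.00000246
```

The scan localizes the injected window — the strongest trend is at
window 13 — and the quintile gradient there is monotone:

```r
dplyr::filter(tidy(res$scans$relative), window == 13)[,
  c("window", "quintile", "or", "or_low", "or_high", "p_trend")]
#> # A tibble: 5 × 6
#>   window quintile    or or_low or_high    p_trend
#>    <int> <chr>    <dbl>  <dbl>   <dbl>      <dbl>
#> 1     13 1        1     1        1     0.00000246
#> 2     13 2        0.499 0.266    0.935 0.00000246
#> 3     13 3        0.387 0.201    0.746 0.00000246
#> 4     13 4        0.226 0.107    0.480 0.00000246
#> 5     13 5        0.125 0.0468   0.334 0.00000246
```

`autoplot(res$scans$relative)` draws the Q5-vs-Q1 OR curve across all 24
windows with its CI ribbon; `run_pipeline()` also writes the cohort
audit, sleep tables, feature matrix, scan/curve TSVs and a `manifest.json`
(configuration, hash, cascade counts) to `out_dir`. A command-line entry
point with the same options is installed at `inst/cli/actiscan.R`.

## Reproduction

`scripts/acceptance.R` validates the installed package end to end —
detector agreement with a brute-force oracle on 1,000 random nights,
sleep-midpoint recovery to ≤ 0.5 min on clean bouts (n = 500), trend-test
type-I error on 500 null cohorts of n = 1000, recovery and localization
of an injected −0.2 trend log-OR at window 13 (n = 4000, 50 replicates),
and closed-form anchors for the weighted fits and insulin harmonization —
and writes the computed quantities as a flat JSON object:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

With `--seed 1` this prints detector agreement 1000/1000, a maximum
midpoint error of 0.267 min, a type-I rejection rate of 0.0474, a mean
recovered trend of −0.194 (truth −0.2) with 0.98 CI coverage and 0.98
localization, the exact 9.0 toy odds ratio, and a zero equal-weight
difference (≈ 4 min on one CPU). The same checks run as the
`test-acceptance.R` block of the test suite.
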