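---
title: "Methods: sleep-anchored activity timing and glycaemic association scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sleep-anchored activity timing and glycaemic association scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actiscan)
```

## The scientific question

Physical activity guidelines say how much to move, not *when*. Two people
with identical total activity can distribute it very differently across the
24-hour day, and the biological clock makes it plausible that the same
minutes of movement matter more at some circadian phases than others.
`actiscan` implements an analysis pipeline for that question using
minute-level wrist actigraphy: it estimates each person's sleep timing,
expresses their activity profile on a *sleep-midpoint-anchored* axis (a
practical proxy for circadian phase), and scans every one-hour window of
that axis for an association with prevalent diabetes or with continuous
glycaemic markers, under a complex-survey design.

The package also contains a synthetic cohort generator with fully known
ground truth, so every stage — the sleep detector, the feature extraction,
the survey-weighted models — can be validated quantitatively, and power or
type-I-error properties of the whole scan can be simulated.

## Data model

The minute layer is a long table: `participant_id`, timestamp `t`
(one-minute grid), `mims` (monitor-independent movement summary, a
device-independent acceleration magnitude), a `wear_class` of `wake_wear`,
`sleep_wear`, `non_wear` or `unknown`, and a logical `quality_flag` for
minutes the upstream classifier considered implausible. A minute is *valid*
when it is wake or sleep wear and unflagged; a calendar day
(midnight-to-midnight) is valid with at least 1200 valid minutes (20 h).

## Sleep timing

Nights live on a 14-hour axis from 20:00 to 09:59 the next morning
(0-based minute index 0–839; index 420 is 03:00). Onset and offset come
from a mirrored rolling rule on the night's sleep-wear flags:

* **onset** — slide a 30-minute window forward; in the first window holding
  at least 15 sleep minutes, onset is the first sleep minute.
* **offset** — slide the window backward from 09:59; in the first window
  holding at least 15 sleep minutes, offset is the last sleep minute.

The 15-of-30 requirement ignores isolated wake intrusions and isolated
sleep minutes. The nightly midpoint is `(onset + offset) / 2`; a
participant's **overall midpoint** is the midpoint of their mean onset and
mean offset across nights, and the **weekend midpoint** (Friday and
Saturday nights only) serves as a chronotype proxy. Both detectors are
tested against a brute-force window-enumeration oracle on random nights
(`tests/testthat/`), and the acceptance suite requires exact agreement on
1,000 random nights.

## Hourly exposures in two framings

Each participant's minute data are collapsed to 24 hourly mean-MIMS
exposures in two framings, using half-open windows labelled by their
ending hour:

* **clock framing** — window 1 is 00:01–01:00, …, window 24 is 23:01–00:00;
* **relative framing** — window *k* covers
  `(midpoint + (k−1) h, midpoint + k h]`, anchored at the participant's
  overall midpoint clock time each day.

A minute at clock second `s` with anchor second `a` falls in window
`ceiling(d / 3600)` where `d = (s − a) mod 86400` (with `d = 0` mapped to
86400). When the midpoint is exactly midnight the two framings coincide —
a property test. Only valid minutes contribute; a window with no valid
minutes across the recording is missing, which later excludes the
participant (`missing_hourly_window` in the audit).

## Cohort construction

`apply_exclusion_cascade()` applies, in a fixed order so the audit
partitions the input: age ≤ 20, pregnancy, fewer than 4 valid days, any
missing hourly window, unknown diabetes status, and — for the biomarker
analyses — missing outcome and current diabetes medication. Diabetes is
HbA1c ≥ 48 mmol/mol *or* self-report, evaluated with three-valued logic so
missing components propagate honestly. Fasting insulin measured in the
2013–2014 laboratory protocol is harmonized to the 2011–2012 scale with
`10^(1.024·log10(x) − 0.0802)`; HOMA-IR is `glucose·insulin/22.5`; the
continuous outcomes are analysed on the natural-log scale.

## The association scan

For each window, the cohort is split into quintiles of that window's mean
MIMS (unweighted type-7 percentile cuts; ties share a quintile; quintile 1,
lowest activity, is the reference with estimate exactly 0). A
survey-weighted logistic (diabetes) or linear (log biomarkers) model is fit
with quintile indicators plus covariates; a trend test enters the quintile
index 1–5 as a continuous term and reports its Wald p-value.

Because the classic `survey` machinery is not assumed, the design-based
variance is computed directly from the estimating-equation scores
`z_i = w_i x_i (y_i − μ_i)`: a weight-robust sandwich
`A⁻¹ M A⁻¹` with `M = n/(n−1) Σ (z_i − z̄)(z_i − z̄)'` by default, or
stratified/PSU Taylor linearization (scores summed within PSU, centered
within stratum, `n_h/(n_h−1)` factors) when design variables are supplied.
Weights are normalized to mean 1 internally, making weight rescaling an
exact no-op. Complete separation in the exposure or non-convergence yields
windows flagged `estimable = FALSE`, never silent drops or crashes; a
sparse nuisance-covariate level does not invalidate a window. Covariates
that are constant in the complete-case data (e.g. the stratifier inside its
own subgroup) are pruned before fitting.

Closed-form anchors: on a saturated 2×2 weighted table the fitted OR equals
the weighted cross-product ratio (the toy table 30/10/10/30 gives OR 9.0 to
1e-6), and equal weights reproduce the unweighted fit to 1e-8.

## The synthetic generator

`sim_config()` defaults encode the emulated study conditions; they are
fixed study parameters, not tuning knobs:

* sleep midpoint ~ N(420, 40²) minutes on the night axis (03:00 ± 40 min),
  truncated to [300, 540]; night-to-night jitter SD 15 min;
* sleep duration ~ N(7.5, 1.0²) h truncated to [5.5, 9.5], night jitter
  SD 0.5 h; 5% per-minute wake intrusions during sleep; 2% non-wear;
* minute MIMS are lognormal (sdlog 0.5) around a midpoint-relative diurnal
  profile: ~1.2 MIMS/min through the sleep windows, a wake-up ramp, a
  plateau of 12 MIMS/min 7–17 h after the midpoint, and an evening decline,
  multiplied by a participant effect `exp(b)`, `b ~ N(0, 0.25²)`, and a
  participant-by-window effect `exp(e_k)`, `e_k ~ N(0, 0.35²)`. The implied
  median daily total is ≈11,000 MIMS/day, matching population wrist
  accelerometry;
* outcomes: a logistic model on age, gender and (optionally) the quintile
  of activity in one designated window, with the intercept solved by
  `uniroot` to hit the target prevalence (default 18.7%); HbA1c and
  self-report are drawn consistently with the simulated status; insulin is
  stored on each cycle's raw laboratory scale so the pipeline's
  harmonization step is exercised;
* a two-stratum design (weight ratio 1:3 with lognormal jitter, 8 PSUs per
  stratum).

A single seed drives everything through per-participant substreams
(`(seed·48271 + i·1009) mod 2147483629 + 1`), so runs are exactly
reproducible and replicate seeds stay below 2³¹.

### Two generator branches

`generate_cohort()` produces the full minute layer and is used to validate
ingestion, detection and feature extraction (with fragmentation and
non-wear disabled, the estimated overall midpoint matches truth to
≤ 0.5 min for all of n = 500). `generate_feature_cohort()` draws the
participant-level hourly means, covariates, design and outcomes directly
from the same latent model, skipping the minute layer. The modelling-layer
simulations (type-I error at n = 1000 × 500 replicates; recovery of an
injected −0.2 trend log-OR at relative window 13, n = 4000 × 50 replicates)
run on this branch: simulating ~2×10⁹ minutes would buy nothing, because
minute-to-feature fidelity is already certified by the detector and
midpoint checks.

```{r recovery, eval = FALSE}
cfg <- sim_config(n_participants = 4000, effect_window = 13,
                  effect_log_or = -0.2, seed = 7)
recovery_report(cfg, n_replicates = 50)$summary
# mean trend estimate near -0.2, CI coverage ~0.95, localization >80%
```

## Running the pipeline

```{r pipeline, eval = FALSE}
res <- run_pipeline(sim = sim_config(n_participants = 500),
                    analysis = "diabetes", framing = "relative",
                    out_dir = "run1", seed = 1)
tidy(res$scans$relative)      # per-window, per-quintile grid
glance(res$scans$relative)    # one-row scan summary
autoplot(res$scans$relative)  # OR curve across the 24 windows
```

`run_pipeline()` writes a results directory: the cohort audit, nightly and
summary sleep tables, the feature matrix, wide and long scan tables, curve
data for `plot_curves()`, a JSON-lines stage log, and a `manifest.json`
holding the package version, full configuration and its hash, and the
exclusion-cascade counts — every number in the grid is reproducible from
the manifest plus inputs. A command-line wrapper lives at
`inst/cli/actiscan.R`.

## Numerical choices

* Confidence intervals use normal quantiles by default (`df = Inf`),
  switchable to t quantiles via `df`; design-based degrees of freedom are
  not well defined without the full design, and n is large in the intended
  use.
* Quintile cuts are unweighted type-7 percentiles; a value equal to a cut
  falls in the lower quintile so ties share a label, and an all-constant
  exposure puts everyone in quintile 1 (then skipped with a warning).
* The logistic fits use `quasibinomial()` purely to keep `stats::glm`
  quiet about non-integer weighted responses; point estimates equal the
  binomial ML fit.

## Limitations

* Sleep detection trusts the upstream wear/sleep classifier; the rolling
  rule cleans fragmentation but cannot recover from systematic
  misclassification, and only the 20:00–10:00 axis is searched (no
  daytime naps, no shift-work schedules).
* The generator is a validation instrument, not a population emulator: it
  reproduces the qualitative diurnal structure and survey design, not real
  marginal distributions; cross-sectional outcomes mean associations, not
  causal effects of timing.
* Variance estimation assumes with-replacement sampling of PSUs within
  strata (the standard Taylor approximation); single-PSU strata contribute
  no variance rather than erroring.
* Small cohorts (a few hundred) with the full covariate set can be
  legitimately non-estimable in the logistic scan; the grid reports that
  explicitly rather than degrading quietly.
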