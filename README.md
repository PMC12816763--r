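# musclek

Muscle oxidative capacity from NIRS recovery kinetics, free-living
activity metrics, and the multi-stage statistics that relate them —
with synthetic-data generators so every stage has a recoverable ground
truth.

## The problem

In COPD, skeletal muscle loses oxidative capacity, and it has been
unclear whether that loss tracks behaviour (physical inactivity) or the
disease itself (airflow obstruction). A noninvasive way to measure muscle
oxidative capacity uses near-infrared spectroscopy (NIRS): after brief
muscle contractions raise muscle oxygen consumption (mVO2), a series of
short arterial occlusions is applied; during each occlusion the tissue
saturation index (TSI, %) falls at a rate equal to the instantaneous
consumption, and the sequence of per-occlusion slopes traces the
monoexponential recovery

    mVO2(t) = a + A * exp(-k * t),

whose rate constant `k` (min⁻¹) is directly proportional to muscle
oxidative capacity. This package is for researchers working with such
recordings and their accompanying accelerometry and clinical covariates.
It implements:

* **`nirs_kinetics`** — per-occlusion slope extraction, physiological-range
  and arterial-occlusion QC, bounded multistart nonlinear least squares
  for `k`, duplicate-assessment averaging (`oxidative_capacity()`).
* **`activity`** — wear detection, vector-magnitude counts per minute
  (VMU/min), a documented step counter, and the day-validity rules
  (≥ 8 daytime wear hours, ≥ 4 valid days) (`summarize_activity()`).
* **`cohort_stats`** — spirometric classification (never smoker /
  Controls / PRISm / GOLD 1–4), Welch's ANOVA, Games–Howell contrasts,
  Monte-Carlo Fisher exact tests (`compare_groups()`).
* **`regression_pipeline`** — correlates of log(k): missingness /
  zero-frequency / collinearity prefilter, univariate screen (p ≤ 0.20),
  LASSO + random-forest + gradient-boosting consensus importance
  filtering, VIF exclusion, multivariable OLS, multiplicative effect
  translation, stratified and leave-variable-out sensitivity analyses
  (`run_correlates_pipeline()`).
* **`synthetic_data`** — generators for NIRS recordings, accelerometer
  streams and cohorts with known truth (`simulate_nirs_recording()`,
  `simulate_accel_stream()`, `simulate_cohort()`).
* **`run_study()`** — the end-to-end orchestrator writing study-style
  tables, selection traces and a run log.

## Worked example

Simulate a Controls-range recording (true k = 1.67 min⁻¹), estimate k,
and translate model coefficients into percent effects:

```r
library(musclek)

sched <- occlusion_schedule(seed = 2)           # 5x5 s + 10x10 s, twice
par   <- nirs_sim_params(k_true = 1.67, noise_sd = 0, seed = 3)
rec   <- simulate_nirs_recording(par, sched)

res <- oxidative_capacity(rec)
res
#> <oxcap_result> k_mean = 1.670 min^-1 from 2/2 converged fits
#> (1.671, 1.669); arterial QC: pass

physiological_range(rec)
#> <physiological_range> TSI min 35.1%, max 78.0% (span 42.9)

translate_effect(0.0045, delta = -10, variable = "fev1_pct_pred")
#> <effect_translation> fev1_pct_pred: delta -10 -> -4.40% in k
translate_effect(-0.0102, delta = 10, variable = "age")
#> <effect_translation> age: delta 10 -> -9.70% in k
```

The first block reproduces the measurement chain: 30 intermittent
occlusions become 30 mVO2 points (15 per assessment), each assessment is
fit to the monoexponential, and the duplicate k estimates (1.671 and
1.669 min⁻¹ here — within 0.1% of the generating 1.67) are averaged. The
effect translations read coefficients of a log(k) model multiplicatively:
a 10-unit lower FEV1 %predicted corresponds to a 4.4% lower k, and 10
years of aging to a 9.7% lower k.

A full synthetic study (cohort of 241, NIRS and activity subsamples,
group comparisons, selection pipeline, sensitivity analyses):

```r
cfg <- run_config(out_dir = "study_out",
                  seeds = list(cohort = 1, nirs = 2, activity = 3,
                               pipeline = 4))
run_study(cfg)
```

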