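# eyeblinkr

Simulation and analysis of delay eyeblink-conditioning and motor-battery
data in mice.

Delay eyeblink conditioning is the standard assay of cerebellar
associative learning: a neutral cue (CS, an LED) precedes a corneal air
puff (US) by a fixed interstimulus interval (ISI), and over days of
training the animal learns to close its eyelid — a conditioned response
(CR) — before the puff arrives. The raw data are eyelid-position traces
in arbitrary units; every scientific quantity (CR proportion, amplitude,
latency, adaptive timing) depends on a chain of scoring steps that this
package implements as tested, composable functions:

- **Paradigm & simulation** — the 240-trial session structure (20 blocks
  of 1 CS-only + 1 US-only + 10 paired trials, semi-random within block),
  the 250 → 500 ms ISI switch at day 11, air-puff trigger-delay
  compensation, and a seeded generator of whole synthetic cohorts with
  per-trial ground truth (`make_schedule()`, `us_trigger_time()`,
  `simulate_cohort()`, `simulate_motor_tables()`).
- **Trace scoring** — zero-phase 50 Hz Butterworth filtering, pre-CS
  baseline alignment, the 7 × IQR trial-validity rule, normalization of
  every trace by the session-averaged unconditioned-response peak so that
  1 "normalized eye closure" (NEC) equals a full blink
  (`normalize_cohort()`), and CR detection with onset/peak latencies,
  amplitude, and the ±50 ms "perfectly timed" criterion
  (`score_trials()`, `detect_cr()`, `perfectly_timed()`).
- **Statistics** — the multilevel battery used on these outcomes: mixed
  binomial logistic, linear mixed, mixed beta, and Cox frailty models
  with day × genotype fixed effects, LR/Wald omnibus tests,
  random-structure selection by likelihood ratio, Holm-adjusted per-day
  genotype contrasts, and the noncentral-t sample-size calculation
  (`fit_trialwise_logistic()`, `fit_lmm()`, `fit_beta_mixed()`,
  `fit_cox_frailty()`, `holm_adjust()`, `power_sample_size()`).
- **Motor tasks** — ErasmusLadder two-part clean-sweep analysis, rotarod
  censored-latency preparation (300 s cap, 80 RPM exclusion), balance-beam
  and grip-strength log-scale models with back-translation
  (`ladder_prepare()`, `ladder_analyze()`, `rotarod_prepare()`,
  `beam_analyze()`, `grip_analyze()`).

Everything is data-frame in, tibble out, and pipes cleanly; fitted models
come back as `ebc_fit` objects with `tidy()`, `glance()` and `autoplot()`
methods. `run_pipeline()` chains simulate → preprocess → score → stats →
motor into a reproducible artifacts directory.

## Worked example

Simulate a small cohort (4 mice per genotype, 5 training days at the
250 ms ISI, 4 blocks per session), score it, and model the per-trial CR
outcome:

```r
library(eyeblinkr)
library(dplyr)

params <- sim_params(n_per_genotype = 4, days_phase1 = 5, days_phase2 = 0,
                     n_blocks = 4, seed = 1)
cohort <- simulate_cohort(params)
#> <ebc_cohort>
#>   1920 trials, 8 mice, 5 days, seed 1

summaries <- cohort$trials |>
  normalize_cohort() |>
  score_trials() |>
  summarize_sessions()

summaries |> filter(day == 5) |>
  select(mouse_id, genotype, cr_proportion, nec_250, mean_peak_ms)
#> # A tibble: 8 × 5
#>   mouse_id   genotype cr_proportion nec_250 mean_peak_ms
#>   <chr>      <chr>            <dbl>   <dbl>        <dbl>
#> 1 NF1_HET_01 NF1_HET           0.75   0.331         264.
#> 2 NF1_HET_02 NF1_HET           1      0.365         258.
#> 3 NF1_HET_03 NF1_HET           1      0.455         232.
#> 4 NF1_HET_04 NF1_HET           0.75   0.330         249.
#> 5 WT_01      WT                0.5    0.253         272.
#> 6 WT_02      WT                0.75   0.282         236.
#> 7 WT_03      WT                1      0.505         273.
#> 8 WT_04      WT                1      0.348         223.
```

By day 5 both genotypes respond on most CS-only trials, with peak
latencies clustering near the 250 ms US onset — the acquisition course the
generator is built to emulate. The trial-level mixed logistic model then
tests day, genotype and their interaction, with Holm-adjusted per-day
odds ratios (NF1_HET vs WT):

```r
fit <- cohort$trials |>
  normalize_cohort() |> score_trials() |> filter(valid) |>
  fit_trialwise_logistic(random = "intercepts")
fit
#> <ebc_fit> binomial model for 'is_cr' (157 obs, 8 mice)
#>   random structure: intercepts; logLik -83.57
#>   omnibus tests:
#>          term test statistic df df_resid   p.value
#>           day Wald    27.987  4       NA 1.255e-05
#>      genotype Wald     3.297  1       NA 6.941e-02
#>  day:genotype Wald     1.078  4       NA 8.978e-01

tidy(fit) |> select(level, estimate_exp, p.value, p.adjusted)
#> # A tibble: 5 × 4
#>   level estimate_exp p.value p.adjusted
#>   <chr>        <dbl>   <dbl>      <dbl>
#> 1 1             1.34   0.741      1
#> 2 2             1.90   0.398      1
#> 3 3             4.25   0.122      0.609
#> 4 4             2.99   0.250      1
#> 5 5             1.62   0.634      1
```

A strong day effect (learning), no significant genotype differences at
this toy size. Two desk constants of the paradigm:

```r
us_trigger_time(250, 14)                      # air-puff trigger, ms
#> [1] 236
power_sample_size(0.2, 0.2, power = 0.8)      # planned group size
#> [1] 17
```

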