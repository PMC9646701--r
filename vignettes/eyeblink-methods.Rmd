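---
title: "Scoring and modelling delay eyeblink conditioning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and modelling delay eyeblink conditioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eyeblinkr)
```

## The measurement problem

In delay eyeblink conditioning a mouse learns that a neutral cue (the
conditional stimulus, CS — an LED) predicts a corneal air puff (the
unconditional stimulus, US). Training sessions consist of 20 blocks of 12
trials — 1 CS-only, 1 US-only and 10 paired trials in random order within
each block, 240 trials per session — and run for ten days at a 250 ms
interstimulus interval (ISI) followed by ten days at 500 ms. The switch
makes the task harder and exposes how the *timing* of the learned blink
adapts. Because the air-puff hardware has an inherent delivery delay
(14 ms by default), the puff is triggered `isi - delay` ms after CS onset
so that it strikes the cornea exactly at the ISI; `us_trigger_time(250, 14)`
is 236 ms.

The raw observable is an eyelid-position trace per trial (2000 ms at
300 frames/s, 500 ms of it before CS onset), in arbitrary units that vary
with camera placement. Everything downstream — conditioned-response (CR)
detection, amplitude and latency metrics, group statistics — depends on
turning those traces into comparable, normalized measurements. This
package implements that full path, together with a synthetic-cohort
generator so that every stage can be verified against known ground truth,
and the multilevel statistical battery used on the resulting outcomes and
on four companion motor tasks (ErasmusLadder, accelerating rotarod,
balance beam, grip strength).

## Trace scoring

Per session (one mouse, one day) the pipeline is:

1. **Zero-phase low-pass filtering** (`lowpass_zero_phase()`): a 4th-order
   Butterworth at 50 Hz applied forward and backward, so the passband is
   untouched twice as steeply and no phase lag distorts latencies. The
   implementation reflects the trace (odd symmetry) by 24 × order samples
   at each end before `signal::filtfilt`, which confines the IIR start-up
   transient to the padding; without it a constant trace would not come
   back constant at the edges.
2. **Baseline alignment** (`baseline_align()`): the median of the 500 ms
   pre-CS window is subtracted. The median, rather than the mean, keeps a
   single stray pre-CS blink from shifting the baseline.
3. **Validity** (`trial_validity()`): a trial is invalid when its largest
   absolute pre-CS excursion from the baseline median exceeds 7 times the
   interquartile range of that same window. The IQR is computed
   within-trial; a session-pooled reference would let one noisy trial
   contaminate its neighbours. Two numerical points: a perfectly flat
   baseline (IQR 0) is valid, and excursions are compared against
   `7 * IQR` plus a guard of `1e-4` times the trace maximum. The guard
   absorbs the acausal tail the zero-phase filter smears backward from
   post-CS events (measured at most ~3e-5 of the trace maximum for the
   earliest admissible CR) while staying orders of magnitude below any
   physiological artifact; because it scales with the trace, validity is
   invariant to rescaling the raw signal.
4. **UR-referenced normalization** (`session_ur_factor()`,
   `normalize_session()`): the filtered, aligned traces of the session's
   valid US-containing trials are averaged sample-wise and the maximum of
   that average over the window from US impact to trace end is the
   normalization factor — the size of a full reflexive blink in raw units.
   Dividing every trace by it yields normalized eye closure (NEC): 0 is
   the open baseline, 1 a full blink. Restricting the search window to
   after US impact keeps CRs in paired trials from inflating the factor;
   by default both US-only and paired trials contribute
   (`ur_source = "both"`), since both contain the reflex, with
   `"us_only"` available when a CR-free reference is wanted. Sessions with
   no valid US-containing trial, or a non-positive factor (no reflexive
   closure), are unusable and reported as such — never silently dropped.

Conditioned behavior is then read from **valid CS-only trials**, which show
the complete CR kinetics with no UR superimposed. `detect_cr()` takes the
earliest maximal sample in (CS onset, CS onset + 1000 ms] as the CR peak
and walks back to the first sample of the ≥ 0.02 NEC run leading to it
(sustained for at least 10 ms) as the CR onset. A CR is scored when the
peak exceeds 0.1 NEC, onset latency lies in [50, 500] ms and peak latency
in [100, 1000] ms, all intervals closed. The onset rule is an
operationalization — "onset" has no unique definition on a noisy trace —
and both threshold and sustain time are exposed as arguments. Latencies
are reported at sample resolution (3⅓ ms at 300 fps).

Session summaries (`summarize_sessions()`) report the CR proportion and
perfectly-timed proportion over valid CS-only trials, mean NEC at 250 and
500 ms after CS onset over valid CS-only trials (CR and non-CR alike), and
mean onset/peak latencies over CR-present trials. A CR is *perfectly
timed* when its peak falls within ±50 ms of the omitted US onset
(200–300 ms for the 250 ms ISI, 450–550 ms for the 500 ms phase).
`aggregate_cohort()` reduces summaries to per-day-by-genotype tables
(mean, SD, median, quartiles).

Two scoring decisions deserve note. First, the NEC-at-250/500 ms outcomes
are computed over CS-only trials, consistent with restricting conditioned
behavior to CS-only trials, even though amplitude outcomes are sometimes
described over all trials; paired trials are contaminated by the UR from
US impact onward. Second, all interval checks are closed, so a peak
exactly at a window boundary counts as inside.

## The synthetic cohort

`simulate_cohort()` draws the trial table of a whole experiment: two
genotypes (`WT`, `NF1_HET`), `n_per_genotype` mice each, the 240-trial
block structure above, the ISI switch at day 11. Traces are built from

- Gaussian baseline noise (`noise_sd`, raw units);
- an optional pre-CS artifact bump (probability `artifact_prob`);
- a raised-cosine CR bump on CS-containing trials, present with
  probability `p_max (1 - e^{-k_g d})` (day `d` within phase, per-genotype
  rate `k_g`); its amplitude grows with the same saturating law toward
  `amp_max`, and its peak time is Normal around a mean that relaxes toward
  the current US onset at `timing_adapt_rate` per day. At the ISI switch
  both probability and amplitude restart from `carry_over` (default 0.8)
  times their phase-1 terminal value, mimicking the partial drop such
  cohorts show;
- a stereotyped UR on US-containing trials: half-cosine rise over
  `ur_rise_ms` to `ur_gain`, exponential decay with `ur_decay_ms`,
  starting at US impact. CR and UR add; values above `ur_gain` are
  soft-capped at 1.05 × `ur_gain`, a smooth stand-in for saturation at
  full closure that keeps normalization well-posed.

The raised cosine was chosen for the CR because it is smooth, compactly
supported and fully described by onset, peak and amplitude — real averaged
CR traces show exactly such unimodal rises. Defaults (`p_max = 0.9`,
`amp_max = 0.7` NEC, `k` = 0.35/0.45 per genotype, timing jitter 50 ms,
2% artifact rate) reproduce the qualitative acquisition course of real
cohorts: CR proportion rising from ~0 to ~0.9 over ten days with the
mutant genotype slightly faster, peak times drifting toward the US.

Ground truth is recorded per trial: whether a CR was planted, and its
onset/peak latency *as seen through the standard measurement* — the clean,
noise-free bump passed through the scoring filter and divided by the
factor an ideal scorer derives from the noise-free UR (slightly below
`ur_gain`, since the filter attenuates the sharp UR rise) — using the same
definitional scan the detector implements. Planted bumps are constrained
so their threshold crossing and peak stay inside the detection windows
with margin; on a noise- and artifact-free cohort normalized with
`ur_source = "us_only"` (whose factor coincides with that ideal one),
`detect_cr()` reproduces the ground-truth presence, onset and peak
*exactly* at sample resolution. This
perfect-recovery property is the package's strongest end-to-end check; it
shows the plumbing is lossless, not that scoring is robust — robustness
under noise is probed separately by the oracle-equivalence tests on random
traces. What the simulator deliberately omits: inter-trial-interval gating
(trials are independent snippets; the ITI affects acquisition rate, not
scoring correctness), eyelid biomechanics, slow drifts, and any claim that
the learning-curve parameters are calibrated to a specific dataset.

One root seed spawns an independent child stream per mouse, so cohorts are
reproducible under reordering and subsetting of mice.

The motor-task generator (`simulate_motor_tables()`) mirrors the
structures the motor analyses assume: ladder correct-step proportions from
a two-part law (clean sweep — all steps correct — with a logit-linear
probability defaulting to a 16% rate, otherwise a Beta draw), rotarod
latencies from a day-trending log-normal right-censored at 300 s (with an
80 RPM sub-cohort to exclude, as in the real design), balance-beam times
and grip forces from log-normals, each with a shared per-mouse random
effect.

## The statistical battery

All outcomes carry repeated measures per mouse, so every model is
multilevel, estimated by maximum likelihood, with training day treated as
categorical (per-day contrasts and day-specific random structure are the
quantities of interest):

- trial-level CR presence and clean-sweep flags: mixed **binomial
  logistic** regression (`fit_trialwise_logistic()`, lme4), Wald
  chi-square omnibus tests per term;
- NEC amplitudes and CR latencies: **linear mixed models** (`fit_lmm()`,
  lme4, optional log transform), likelihood-ratio omnibus tests from
  nested ML refits;
- proportions strictly inside (0, 1): **mixed beta regression**
  (`fit_beta_mixed()`, glmmTMB, logit link), LR tests. Boundary values
  must first be compressed with `compress_proportions()` —
  `(y(n-1)+0.5)/n` — because mixed ladder trials can still contain 0;
- censored latencies: **Cox proportional hazards** with a per-mouse
  log-normal frailty (`fit_cox_frailty()`, survival), Wald tests.

Factors are coded sum-to-zero, which makes the Wald block tests
type-III-style; the LR tests compare each main effect against the additive
model and the interaction against the full one. Two random structures are
considered (`select_random_structure()`): random intercepts per mouse, and
additionally per-mouse-by-day deviations, compared by LR at 0.05. The
day-specific structure is realized as `(1 | mouse) + (1 | mouse:day)` —
independent deviations with a common variance — rather than a full
unstructured covariance over day levels, which is not identifiable at
cohort sizes of ~20 mice per group; when the richer fit fails the
intercepts model is kept with a warning, and the chosen structure is
recorded in the fit object. For the Cox family the per-mouse frailty *is*
the random structure.

Per-day (or per-width) genotype contrasts are computed uniformly from
fixed-effect design-row differences — estimate `c'β`, standard error
`√(c'Vc)` — back-transformed to odds or hazard ratios where the link is
logit or log, with normal intervals (t with `n_mice − 2` degrees of
freedom for the gaussian family), and Holm step-down adjustment across the
days of one phase. Contrasts whose link-scale standard error exceeds 5 are
flagged `unstable`: that is the signature of (quasi-)complete separation,
e.g. a day on which one genotype never responds, where the odds ratio is
finite only by the grace of the random-effect shrinkage. Aliased
coefficients (as arise when an exploding frailty absorbs a between-mouse
effect) are dropped from Wald blocks, and contrasts touching them are
omitted rather than fabricated.

`power_sample_size()` performs the planning calculation by direct
iteration of the noncentral-t power function of the two-sample t-test; at
a raw difference of 0.2 against an SD of 0.2 (standardized effect 1.0),
80% power and two-sided α = 0.05 it returns 17 per group.

## Motor-task analyses

The ErasmusLadder correct-step proportion is bimodal: a point mass of
clean sweeps and a continuum of mixed trials. `ladder_prepare()` splits
accordingly (clean sweep ⟺ proportion exactly 1, tolerance 1e-9, after
upstream backstep exclusion) and `ladder_analyze()` runs the two-part
analysis: logistic on the flag over all trials, beta on the compressed
proportions of mixed trials. `rotarod_prepare()` drops the 80 RPM rows,
caps latencies at 300 s and flags the cap as censoring for the Cox
frailty model. `beam_analyze()` and `grip_analyze()` model log-times and
log-forces (both right-skewed) with random intercepts per mouse;
`grip_analyze()` exponentiates the group means back to force units and
reports the group difference of back-translated means with a delta-method
interval. Back-translated means are exactly equivariant under rescaling
the forces.

## Numerical and testing choices

Problem sizes in the test suite are chosen to make every property
checkable in minutes while keeping the asymptotics honest: the
perfect-recovery cohort uses 4 mice × 5 days × 24 trials; the
oracle-equivalence checks run 1000 random short traces against
brute-force reimplementations of the defining rules; the type-I
calibration study runs 200 null replicates per family at 12–28 mice —
cluster counts sized so that the Wald and LR genotype tests, which are
asymptotic in the number of mice, operate in their valid regime (with very
few clusters the Wald test for a between-mouse effect is materially
anticonservative, a property of the test, not of the implementation) —
and the anchored-recovery study simulates 41 mice × 10 days with a 0.18
day-6 group difference and per-genotype between-mouse SDs of 0.17/0.26,
asking the day-6 contrast to land in the published interval [0.06, 0.29]
in ≥ 80% of replicates.

Other conventions: sample indices are 0-based in the EBC-CSV interchange
format and all latencies are milliseconds relative to CS onset; trace
values round-trip bit-exactly through the CSV (written with 17 significant
digits and parsed with strtod); ties at the CR peak resolve to the
earliest sample; the trigger-time rule is pure subtraction, so a 500 ms
ISI with a 14 ms delay gives 486 ms; `run_pipeline()` is deterministic —
a config and seed fix every artifact byte.

## Known limitations

The simulator's learning dynamics are a plausible family, not a fitted
model; passing recovery tests demonstrates correctness of scoring, not
realism of the generator. The diagonal day-by-mouse random structure
understates covariance between adjacent days. Wald inference for
between-mouse effects is only as good as the mouse count; with fewer than
~10 mice per group treat the per-day odds ratios as descriptive. The Cox
frailty fit can degenerate on small cohorts (the frailty absorbing the
genotype effect); such fits surface as `NA` tests rather than numbers.
Real deposited datasets need a column-mapping step into the EBC-CSV
schema before `read_ebc()` will accept them.
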