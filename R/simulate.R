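# Synthetic eyelid-trace simulator.
#
# A trial trace is the sum of Gaussian baseline noise, an optional pre-CS
# blink artifact, a raised-cosine conditioned-response (CR) bump on
# CS-containing trials, and a stereotyped unconditioned response (UR) on
# US-containing trials (half-cosine rise, exponential decay). Values above
# the UR peak are soft-capped at 1.05 x ur_gain, mimicking saturation at
# full eyelid closure while keeping UR-referenced normalization well-posed.

# Raised-cosine bump: amplitude `amp` at `peak_ms`, compact support
# peak +/- half_width_ms. `t_ms` is time relative to CS onset.
raised_cosine <- function(t_ms, peak_ms, amp, half_width_ms) {
  y <- numeric(length(t_ms))
  inside <- abs(t_ms - peak_ms) <= half_width_ms
  y[inside] <- amp * 0.5 * (1 + cos(pi * (t_ms[inside] - peak_ms) / half_width_ms))
  y
}

# Time (ms) before the continuous-time peak at which the bump crosses `thr`.
bump_crossing_offset_ms <- function(amp, thr, half_width_ms) {
  if (amp <= thr) return(NA_real_)
  half_width_ms / pi * acos(2 * thr / amp - 1)
}

# Stereotyped UR starting at `start_ms` (relative to CS onset): half-cosine
# rise to `gain` over `rise_ms`, then exponential decay with `decay_ms`.
ur_shape <- function(t_ms, start_ms, gain, rise_ms, decay_ms) {
  s <- t_ms - start_ms
  y <- numeric(length(t_ms))
  rising <- s >= 0 & s <= rise_ms
  falling <- s > rise_ms
  y[rising] <- gain * 0.5 * (1 - cos(pi * s[rising] / rise_ms))
  y[falling] <- gain * exp(-(s[falling] - rise_ms) / decay_ms)
  y
}

# Soft saturation: identity up to `gain`, smooth compression into
# (gain, 1.05 * gain] above it.
soft_cap <- function(y, gain) {
  cap <- 1.05 * gain
  over <- y > gain
  y[over] <- gain + (cap - gain) * tanh((y[over] - gain) / (cap - gain))
  y
}

# Normalization factor an ideal scorer would derive from this parameter
# set's noise-free UR: the stereotyped UR trace, low-pass filtered and
# baseline-aligned exactly as the preprocessing chain does, maximised over
# [US impact, trace end]. Slightly below ur_gain because the filter
# attenuates the sharp UR rise; recording ground truth against this factor
# makes noise-free recovery exact at sample resolution.
clean_ur_factor <- function(params, isi_ms) {
  n <- trace_n_samples(params)
  cs_idx <- cs_onset_sample(params)
  t_cs <- (seq_len(n) - 1 - cs_idx) / params$fps * 1000
  ur <- lowpass_zero_phase(
    ur_shape(t_cs, isi_ms, params$ur_gain, params$ur_rise_ms,
             params$ur_decay_ms), params$fps)
  ur <- ur - stats::median(ur[seq_len(cs_idx)])
  from <- cs_idx + ms_to_samples(isi_ms, params$fps)
  max(ur[seq.int(from + 1L, n)])
}

# Definitional scan for the planted CR on a clean NEC trace: grid argmax in
# (CS onset, CS onset + 1000 ms], onset = start of the above-threshold run
# leading to the peak. Used to record ground truth; detect_cr() implements
# the same definition independently on scored traces.
scan_clean_cr <- function(nec, fps, cs_idx) {
  n <- length(nec)
  win <- seq.int(cs_idx + 2L, min(n, cs_idx + 1L + ms_to_samples(1000, fps)))
  peak_rel <- which.max(nec[win])
  peak_idx <- win[peak_rel]
  peak_nec <- nec[peak_idx]
  onset_idx <- peak_idx
  while (onset_idx > 1L && nec[onset_idx - 1L] >= CR_ONSET_THRESHOLD_NEC) {
    onset_idx <- onset_idx - 1L
  }
  list(
    onset_ms = samples_to_ms(onset_idx - cs_idx - 1L, fps),
    peak_ms = samples_to_ms(peak_idx - cs_idx - 1L, fps),
    peak_nec = peak_nec
  )
}

#' Simulate one eyelid-trace trial
#'
#' Draws a single trial from the generative model: baseline noise, optional
#' pre-CS artifact, a CR bump (on CS-containing trials, with the day- and
#' genotype-dependent probability from [cr_probability()]), and a UR (on
#' US-containing trials). Uses the current RNG state unless `seed` is given.
#'
#' @param trial_type `"CS_ONLY"`, `"US_ONLY"` or `"PAIRED"`.
#' @param day Training day.
#' @param genotype `"WT"` or `"NF1_HET"`.
#' @param params A [sim_params()] object.
#' @param seed Optional seed.
#' @return A list with `samples` (raw-unit numeric trace) and `truth`, a
#'   one-row tibble holding the planted CR (presence, onset/peak latency in
#'   ms at sample resolution as seen through the standard low-pass filter,
#'   peak NEC) and artifact flag.
#' @export
simulate_trial <- function(trial_type, day, genotype, params, seed = NULL) {
  stopifnot(inherits(params, "sim_params"))
  trial_type <- match.arg(trial_type, c("CS_ONLY", "US_ONLY", "PAIRED"))
  with_seed(seed, {
    n <- trace_n_samples(params)
    cs_idx <- cs_onset_sample(params)       # 0-based CS onset sample
    t_cs <- (seq_len(n) - 1 - cs_idx) / params$fps * 1000  # ms rel. CS onset
    ph <- phase_of_day(day, params)
    isi <- ph$isi_ms

    trace <- stats::rnorm(n, 0, params$noise_sd)

    is_artifact <- stats::runif(1) < params$artifact_prob
    if (is_artifact) {
      center <- stats::runif(1, -params$pre_cs_ms + 80, -80)
      trace <- trace + raised_cosine(t_cs, center, params$artifact_amp, 40)
    }

    has_cs <- trial_type %in% c("CS_ONLY", "PAIRED")
    has_us <- trial_type %in% c("US_ONLY", "PAIRED")

    is_cr <- FALSE
    truth_onset <- truth_peak <- truth_amp <- NA_real_
    if (has_cs) {
      is_cr <- stats::runif(1) < cr_probability(day, genotype, params)
      if (is_cr) {
        amp <- cr_amplitude(day, genotype, params) *
          exp(stats::rnorm(1, 0, params$amp_jitter_sd))
        amp <- min(max(amp, 0.12), 1)
        off <- bump_crossing_offset_ms(amp, CR_ONSET_THRESHOLD_NEC,
                                       params$cr_half_width_ms)
        peak <- stats::rnorm(1, cr_peak_mean_ms(day, params),
                             params$timing_sd_ms)
        # keep the planted bump inside the detection windows with margin
        peak <- min(max(peak, max(105, 55 + off)), min(995, 495 + off))
        bump <- raised_cosine(t_cs, peak, amp * params$ur_gain,
                              params$cr_half_width_ms)
        trace <- trace + bump
        clean_nec <- lowpass_zero_phase(bump, params$fps) /
          clean_ur_factor(params, isi)
        tr <- scan_clean_cr(clean_nec, params$fps, cs_idx)
        truth_onset <- tr$onset_ms
        truth_peak <- tr$peak_ms
        truth_amp <- tr$peak_nec
      }
    }
    if (has_us) {
      trace <- trace + ur_shape(t_cs, isi, params$ur_gain,
                                params$ur_rise_ms, params$ur_decay_ms)
    }
    trace <- soft_cap(trace, params$ur_gain)

    list(
      samples = trace,
      truth = tibble::tibble(
        is_cr = is_cr, onset_ms = truth_onset, peak_ms = truth_peak,
        peak_nec = truth_amp, is_artifact = is_artifact
      )
    )
  })
}

#' Simulate a full eyeblink-conditioning cohort
#'
#' Generates `n_per_genotype` mice per genotype, each trained for
#' `days_phase1 + days_phase2` daily sessions of `12 * n_blocks` trials laid
#' out by [make_schedule()]. One root seed spawns an independent child
#' stream per mouse, so cohorts are reproducible under reordering.
#'
#' @param params A [sim_params()] object.
#' @return A list of class `ebc_cohort`: `trials` (tibble; one row per trial
#'   with metadata and the raw trace in the `samples` list-column), `truth`
#'   (tibble of planted CR ground truth keyed by mouse/day/trial), and
#'   `params`.
#' @export
#' @examples
#' co <- simulate_cohort(sim_params(n_per_genotype = 1, days_phase1 = 1,
#'                                  days_phase2 = 0, n_blocks = 1, seed = 1))
#' nrow(co$trials)
simulate_cohort <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  genos <- c("WT", "NF1_HET")
  mice <- tibble::tibble(
    genotype = rep(genos, each = params$n_per_genotype),
    mouse_id = paste0(rep(genos, each = params$n_per_genotype), "_",
                      sprintf("%02d", rep(seq_len(params$n_per_genotype), 2)))
  )
  mouse_seeds <- derive_seeds(params$seed, nrow(mice))
  n_days <- params$days_phase1 + params$days_phase2
  cs_idx <- cs_onset_sample(params)

  per_mouse <- purrr::map2(mice$mouse_id, seq_len(nrow(mice)), function(mid, i) {
    geno <- mice$genotype[i]
    with_seed(mouse_seeds[i], {
      purrr::map(seq_len(n_days), function(day) {
        ph <- phase_of_day(day, params)
        sched <- make_schedule(params$n_blocks)
        sims <- purrr::map(as.character(sched$trial_type), function(tt) {
          simulate_trial(tt, day, geno, params)
        })
        trials <- tibble::tibble(
          mouse_id = mid, genotype = geno, day = day,
          phase = ph$phase, block = sched$block, trial = sched$trial,
          trial_type = sched$trial_type, isi_ms = ph$isi_ms,
          fps = params$fps, cs_onset_index = cs_idx,
          samples = purrr::map(sims, "samples")
        )
        truth <- dplyr::bind_cols(
          tibble::tibble(mouse_id = mid, genotype = geno, day = day,
                         trial = sched$trial,
                         trial_type = sched$trial_type, isi_ms = ph$isi_ms),
          purrr::list_rbind(purrr::map(sims, "truth"))
        )
        list(trials = trials, truth = truth)
      })
    })
  })
  flat <- purrr::list_flatten(per_mouse)
  structure(
    list(
      trials = purrr::list_rbind(purrr::map(flat, "trials")),
      truth = purrr::list_rbind(purrr::map(flat, "truth")),
      params = params
    ),
    class = "ebc_cohort"
  )
}

#' @export
print.ebc_cohort <- function(x, ...) {
  cat("<ebc_cohort>\n")
  cat(sprintf("  %d trials, %d mice, %d days, seed %d\n",
              nrow(x$trials), dplyr::n_distinct(x$trials$mouse_id),
              dplyr::n_distinct(x$trials$day), x$params$seed))
  invisible(x)
}
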