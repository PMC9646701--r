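#' Simulation parameters for a synthetic eyeblink-conditioning cohort
#'
#' Bundles every constant the trace simulator needs. Defaults encode the
#' standard delay-conditioning paradigm: 300 frames/s eyelid-position
#' snippets of 2000 ms with a 500 ms pre-CS baseline, ten training days at a
#' 250 ms interstimulus interval (ISI) followed by ten days at 500 ms, and
#' sessions of 20 blocks each holding 1 CS-only, 1 US-only and 10 paired
#' trials. Learning dynamics (saturating acquisition of conditioned-response
#' probability and amplitude, peak timing adapting toward US onset) are the
#' simulator's own model of the qualitative acquisition curves such cohorts
#' show; they are not fitted to any particular animal.
#'
#' @param n_per_genotype Mice per genotype (two genotypes: `"WT"`,
#'   `"NF1_HET"`).
#' @param fps Sampling rate of the eyelid trace, samples/s.
#' @param trace_ms Trial snippet duration, ms.
#' @param pre_cs_ms Pre-CS baseline duration, ms.
#' @param days_phase1,days_phase2 Training days in the 250 ms and 500 ms ISI
#'   phases.
#' @param n_blocks Blocks per session; each block holds 1 CS-only, 1 US-only
#'   and 10 paired trials.
#' @param isi_phase1_ms,isi_phase2_ms ISI (CS onset to US onset), ms.
#' @param us_delay_ms Inherent air-puff delivery delay, ms; the puff is
#'   triggered this much before the intended US onset.
#' @param learn_rate_by_genotype Named numeric, per-genotype acquisition rate
#'   constant (1/day) of the saturating learning curve.
#' @param p_max Asymptotic CR probability, in (0, 1].
#' @param amp_max Asymptotic CR peak amplitude, NEC units.
#' @param carry_over Fraction of the phase-1 terminal level retained when the
#'   ISI switches (CR probability and amplitude restart from this fraction).
#' @param timing_adapt_rate Rate (1/day) at which the mean CR peak time moves
#'   toward the current US onset.
#' @param timing_sd_ms CR peak-time jitter SD, ms.
#' @param cr_peak_init_ms Mean CR peak time on the first training day, ms
#'   after CS onset.
#' @param cr_half_width_ms Half-width of the raised-cosine CR bump, ms.
#' @param amp_jitter_sd SD of the multiplicative log-normal per-trial CR
#'   amplitude jitter.
#' @param noise_sd Baseline Gaussian noise SD, raw units.
#' @param ur_gain Unconditioned-response peak, raw units.
#' @param ur_rise_ms,ur_decay_ms UR rise time and exponential decay constant,
#'   ms.
#' @param artifact_prob Per-trial probability of a pre-CS blink artifact.
#' @param artifact_amp Artifact bump amplitude, raw units.
#' @param seed Root RNG seed; per-mouse child seeds are derived from it.
#'
#' @return A list of class `sim_params`.
#' @export
#' @examples
#' p <- sim_params(n_per_genotype = 2, seed = 1)
#' p$fps
sim_params <- function(n_per_genotype = 20,
                       fps = 300,
                       trace_ms = 2000,
                       pre_cs_ms = 500,
                       days_phase1 = 10,
                       days_phase2 = 10,
                       n_blocks = 20,
                       isi_phase1_ms = 250,
                       isi_phase2_ms = 500,
                       us_delay_ms = 14,
                       learn_rate_by_genotype = c(WT = 0.35, NF1_HET = 0.45),
                       p_max = 0.9,
                       amp_max = 0.7,
                       carry_over = 0.8,
                       timing_adapt_rate = 0.5,
                       timing_sd_ms = 50,
                       cr_peak_init_ms = 200,
                       cr_half_width_ms = 120,
                       amp_jitter_sd = 0.15,
                       noise_sd = 0.1,
                       ur_gain = 5,
                       ur_rise_ms = 30,
                       ur_decay_ms = 300,
                       artifact_prob = 0.02,
                       artifact_amp = 2,
                       seed = 1L) {
  for (nm in c("fps", "trace_ms", "pre_cs_ms", "isi_phase1_ms",
               "isi_phase2_ms", "ur_rise_ms", "ur_decay_ms",
               "cr_half_width_ms", "timing_sd_ms")) {
    stop_if_not_scalar_number(get(nm), nm, min = 0, strict_min = TRUE)
  }
  stop_if_not_scalar_number(n_per_genotype, "n_per_genotype", min = 1)
  stop_if_not_scalar_number(days_phase1, "days_phase1", min = 0)
  stop_if_not_scalar_number(days_phase2, "days_phase2", min = 0)
  stop_if_not_scalar_number(n_blocks, "n_blocks", min = 1)
  stop_if_not_scalar_number(noise_sd, "noise_sd", min = 0)
  stop_if_not_scalar_number(us_delay_ms, "us_delay_ms", min = 0)
  stop_if_not_scalar_number(ur_gain, "ur_gain", min = 0, strict_min = TRUE)
  if (!is.numeric(p_max) || p_max <= 0 || p_max > 1) {
    abort_bad_arg("`p_max` must be in (0, 1].")
  }
  if (artifact_prob < 0 || artifact_prob > 1) {
    abort_bad_arg("`artifact_prob` must be in [0, 1].")
  }
  if (carry_over < 0 || carry_over > 1) {
    abort_bad_arg("`carry_over` must be in [0, 1].")
  }
  if (is.null(names(learn_rate_by_genotype)) ||
      !all(c("WT", "NF1_HET") %in% names(learn_rate_by_genotype))) {
    abort_bad_arg(
      "`learn_rate_by_genotype` must be named with entries for WT and NF1_HET."
    )
  }
  if (pre_cs_ms >= trace_ms) abort_bad_arg("`pre_cs_ms` must be < `trace_ms`.")

  structure(
    list(
      n_per_genotype = as.integer(n_per_genotype), fps = fps,
      trace_ms = trace_ms, pre_cs_ms = pre_cs_ms,
      days_phase1 = as.integer(days_phase1),
      days_phase2 = as.integer(days_phase2),
      n_blocks = as.integer(n_blocks),
      isi_phase1_ms = isi_phase1_ms, isi_phase2_ms = isi_phase2_ms,
      us_delay_ms = us_delay_ms,
      learn_rate_by_genotype = learn_rate_by_genotype,
      p_max = p_max, amp_max = amp_max, carry_over = carry_over,
      timing_adapt_rate = timing_adapt_rate, timing_sd_ms = timing_sd_ms,
      cr_peak_init_ms = cr_peak_init_ms,
      cr_half_width_ms = cr_half_width_ms,
      amp_jitter_sd = amp_jitter_sd,
      noise_sd = noise_sd, ur_gain = ur_gain,
      ur_rise_ms = ur_rise_ms, ur_decay_ms = ur_decay_ms,
      artifact_prob = artifact_prob, artifact_amp = artifact_amp,
      seed = as.integer(seed)
    ),
    class = "sim_params"
  )
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params>\n")
  cat(sprintf("  %d mice/genotype, %d+%d days, %d blocks/session\n",
              x$n_per_genotype, x$days_phase1, x$days_phase2, x$n_blocks))
  cat(sprintf("  %g fps, %g ms traces, ISI %g -> %g ms, seed %d\n",
              x$fps, x$trace_ms, x$isi_phase1_ms, x$isi_phase2_ms, x$seed))
  invisible(x)
}

# Samples per trace and 0-based CS onset sample, from params.
trace_n_samples <- function(params) ms_to_samples(params$trace_ms, params$fps)
cs_onset_sample <- function(params) ms_to_samples(params$pre_cs_ms, params$fps)
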