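# Trace preprocessing: zero-phase low-pass filtering, pre-CS baseline
# alignment, IQR trial validity, and UR-referenced normalization to NEC
# units. Processing order is filter -> align -> validity -> normalize, so
# high-frequency sensor spikes cannot trip the validity rule.

#' Zero-phase low-pass Butterworth filter
#'
#' Filters the trace forward and backward (zero phase lag, unit DC gain)
#' with a Butterworth low-pass of the given order; applied twice the
#' effective attenuation order doubles.
#'
#' @param samples Numeric trace.
#' @param fps Sampling rate, samples/s.
#' @param cutoff Cutoff frequency, Hz (must be below Nyquist).
#' @param order Filter order (single pass).
#' @return Filtered trace, same length.
#' @export
#' @examples
#' lowpass_zero_phase(rep(2, 100), fps = 300)[1:3]
lowpass_zero_phase <- function(samples, fps, cutoff = FILTER_CUTOFF_HZ,
                               order = FILTER_ORDER) {
  stop_if_not_scalar_number(fps, "fps", min = 0, strict_min = TRUE)
  stop_if_not_scalar_number(cutoff, "cutoff", min = 0, strict_min = TRUE)
  if (cutoff >= fps / 2) {
    abort_bad_arg("`cutoff` must be below the Nyquist frequency fps/2.")
  }
  if (length(samples) < 3 * order) {
    abort_bad_arg("Trace too short to filter: need at least 3 x order samples.")
  }
  if (!all(is.finite(samples))) abort_bad_arg("`samples` must be finite.")
  bf <- signal::butter(order, cutoff / (fps / 2), type = "low")
  # odd-symmetric reflection padding confines the IIR start-up transient to
  # the padding; 24 x order samples pushes the edge error to ~1e-15
  n <- length(samples)
  pad <- min(n - 1L, 24L * order)
  xp <- c(2 * samples[1] - rev(samples[2:(pad + 1)]),
          samples,
          2 * samples[n] - rev(samples[(n - pad):(n - 1)]))
  as.numeric(signal::filtfilt(bf, xp))[(pad + 1):(pad + n)]
}

#' Align a trace to its pre-CS baseline
#'
#' Subtracts the median of the `pre_cs_ms` window immediately before CS
#' onset (median, not mean, so a single pre-CS blink does not shift the
#' baseline).
#'
#' @param samples Numeric trace.
#' @param cs_onset_index 0-based sample index of CS onset.
#' @param fps Sampling rate, samples/s.
#' @param pre_cs_ms Baseline window duration, ms.
#' @return List with `samples` (aligned trace) and `baseline_offset` (the
#'   raw-unit median subtracted).
#' @export
baseline_align <- function(samples, cs_onset_index, fps, pre_cs_ms = 500) {
  n_pre <- ms_to_samples(pre_cs_ms, fps)
  if (cs_onset_index < n_pre) {
    abort_bad_arg(sprintf(
      "Need %d pre-CS samples but CS onset is at sample %d.",
      n_pre, cs_onset_index))
  }
  pre <- samples[seq.int(cs_onset_index - n_pre + 1L, cs_onset_index)]
  offset <- stats::median(pre)
  list(samples = samples - offset, baseline_offset = offset)
}

pre_cs_segment <- function(samples, cs_onset_index, fps, pre_cs_ms = 500) {
  n_pre <- ms_to_samples(pre_cs_ms, fps)
  samples[seq.int(cs_onset_index - n_pre + 1L, cs_onset_index)]
}

#' Trial validity from pre-CS activity
#'
#' A trial is invalid when the largest absolute excursion of its pre-CS
#' baseline from the baseline median exceeds `k` times the interquartile
#' range of that same window. A perfectly flat baseline (IQR 0, no
#' deviation) is valid; any deviation on a zero-IQR baseline is invalid.
#'
#' @param samples Baseline-aligned trace.
#' @inheritParams baseline_align
#' @param k Excursion limit in multiples of the IQR.
#'
#' @details Deviations are compared against `k * IQR` plus a numerical
#' guard of `1e-4` times the largest absolute trace value. The guard
#' absorbs the acausal tail a zero-phase IIR filter smears backward from
#' post-CS events into an otherwise flat (zero-IQR) baseline — measured at
#' most a few times `1e-5` of the trace maximum for the earliest admissible
#' CR — while staying orders of magnitude below any physiological pre-CS
#' artifact. Because the guard scales with the trace, the flag is invariant
#' to rescaling the raw signal.
#' @return `TRUE` if the trial is valid.
#' @export
trial_validity <- function(samples, cs_onset_index, fps, k = VALIDITY_IQR_K,
                           pre_cs_ms = 500) {
  pre <- pre_cs_segment(samples, cs_onset_index, fps, pre_cs_ms)
  dev <- max(abs(pre - stats::median(pre)))
  dev <= k * stats::IQR(pre) + 1e-4 * max(abs(samples))
}

us_impact_sample <- function(cs_onset_index, isi_ms, fps) {
  cs_onset_index + ms_to_samples(isi_ms, fps)
}

#' Session normalization factor from the averaged unconditioned response
#'
#' Averages the filtered, baseline-aligned traces of the session's valid
#' US-containing trials sample-wise and takes the maximum of that average
#' over the window from US impact to trace end. Dividing traces by this
#' factor puts them on the NEC scale (1 = full blink).
#'
#' @param session Tibble of one session's trials after filtering and
#'   alignment, with list-column `samples`, plus `trial_type`, `isi_ms`,
#'   `cs_onset_index`, `fps` and logical `valid`.
#' @param ur_source Which US-containing trials feed the factor: `"both"`
#'   (US-only and paired, default) or `"us_only"`.
#' @return The normalization factor (raw units per NEC).
#' @export
session_ur_factor <- function(session, ur_source = c("both", "us_only")) {
  ur_source <- match.arg(ur_source)
  keep_types <- if (ur_source == "both") c("US_ONLY", "PAIRED") else "US_ONLY"
  us <- dplyr::filter(session, .data$trial_type %in% keep_types, .data$valid)
  if (nrow(us) == 0) {
    rlang::abort("Session unusable: no valid US-containing trials.",
                 class = "eyeblinkr_no_ur")
  }
  avg <- Reduce(`+`, us$samples) / nrow(us)
  from <- us_impact_sample(us$cs_onset_index[1], us$isi_ms[1], us$fps[1])
  factor <- max(avg[seq.int(from + 1L, length(avg))])
  if (!is.finite(factor) || factor <= 0) {
    rlang::abort("Session unusable: no reflexive eyelid closure after the US.",
                 class = "eyeblinkr_no_ur")
  }
  factor
}

#' Normalize one session of trials to NEC units
#'
#' Applies the full preprocessing chain to every trial of one mouse-day
#' session: zero-phase low-pass filter, pre-CS baseline alignment, IQR
#' validity flag, then division by the session's UR-referenced
#' normalization factor. Invalid trials are flagged but still normalized so
#' they remain available for quality-control plots; downstream scoring
#' excludes them.
#'
#' @param session Tibble of one session's trials with list-column `samples`
#'   and columns `trial_type`, `isi_ms`, `cs_onset_index`, `fps`.
#' @param cutoff,order Filter settings, see [lowpass_zero_phase()].
#' @param k Validity limit, see [trial_validity()].
#' @param pre_cs_ms Baseline window, ms.
#' @inheritParams session_ur_factor
#' @return The session tibble with `samples` replaced by the NEC trace in
#'   list-column `nec`, plus `valid`, `norm_factor` and `baseline_offset`.
#' @export
normalize_session <- function(session, cutoff = FILTER_CUTOFF_HZ,
                              order = FILTER_ORDER, k = VALIDITY_IQR_K,
                              pre_cs_ms = 500,
                              ur_source = c("both", "us_only")) {
  ur_source <- match.arg(ur_source)
  aligned <- purrr::pmap(
    list(session$samples, session$cs_onset_index, session$fps),
    function(s, cs, fps) {
      baseline_align(lowpass_zero_phase(s, fps, cutoff, order), cs, fps,
                     pre_cs_ms)
    })
  out <- session
  out$samples <- purrr::map(aligned, "samples")
  out$baseline_offset <- purrr::map_dbl(aligned, "baseline_offset")
  out$valid <- purrr::pmap_lgl(
    list(out$samples, out$cs_onset_index, out$fps),
    function(s, cs, fps) trial_validity(s, cs, fps, k, pre_cs_ms))
  factor <- session_ur_factor(out, ur_source)
  out$norm_factor <- factor
  out$nec <- purrr::map(out$samples, function(s) s / factor)
  out$samples <- NULL
  out
}

#' Normalize every session of a cohort
#'
#' Splits a trial table by mouse and day and applies [normalize_session()]
#' to each session. Sessions without a usable UR (no valid US-containing
#' trial, or a non-positive factor) are dropped from the output and listed
#' in the `unusable_sessions` attribute together with the reason, mirroring
#' the exclusion of animals without reflexive closures.
#'
#' @param trials Trial tibble (e.g. `simulate_cohort(...)$trials`).
#' @inheritParams normalize_session
#' @return Tibble of normalized trials; attribute `unusable_sessions` is a
#'   tibble of skipped (mouse_id, day) pairs with reasons.
#' @export
normalize_cohort <- function(trials, cutoff = FILTER_CUTOFF_HZ,
                             order = FILTER_ORDER, k = VALIDITY_IQR_K,
                             pre_cs_ms = 500,
                             ur_source = c("both", "us_only")) {
  ur_source <- match.arg(ur_source)
  sessions <- dplyr::group_split(trials, .data$mouse_id, .data$day)
  bad <- list()
  kept <- purrr::map(sessions, function(s) {
    tryCatch(
      normalize_session(s, cutoff, order, k, pre_cs_ms, ur_source),
      eyeblinkr_no_ur = function(e) {
        bad[[length(bad) + 1]] <<- tibble::tibble(
          mouse_id = s$mouse_id[1], day = s$day[1], reason = conditionMessage(e))
        NULL
      })
  })
  kept <- purrr::compact(kept)
  if (length(kept) == 0) {
    rlang::abort("No usable sessions: every session lacks a valid UR.",
                 class = "eyeblinkr_no_ur")
  }
  out <- purrr::list_rbind(kept)
  attr(out, "unusable_sessions") <- purrr::list_rbind(bad)
  out
}
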