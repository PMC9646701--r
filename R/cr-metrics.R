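# Conditioned-response detection and per-trial / per-session outcomes.

#' Detect a conditioned response in one normalized CS-only trace
#'
#' The CR peak is the earliest maximal sample of the NEC trace over the
#' window (CS onset, CS onset + 1000 ms]. The onset is the start of the
#' contiguous run of samples at or above `onset_threshold` leading up to
#' that peak, provided the run stays above threshold for at least
#' `sustain_ms`. A CR is present when the peak amplitude exceeds
#' `amp_threshold` NEC and the onset and peak latencies fall inside the
#' closed windows 50-500 ms and 100-1000 ms after CS onset. Latencies are
#' reported at sample resolution in ms; when no CR is present they are `NA`.
#'
#' @param nec NEC trace of a valid CS-only trial.
#' @param fps Sampling rate, samples/s.
#' @param cs_onset_index 0-based CS onset sample.
#' @param onset_threshold Onset-defining NEC threshold.
#' @param sustain_ms Minimum time the trace must stay above the threshold.
#' @param amp_threshold Minimum CR peak amplitude, NEC.
#' @param onset_window,peak_window Closed admissible latency windows, ms.
#' @return One-row tibble: `is_cr`, `onset_ms`, `peak_ms`, `peak_nec`.
#' @export
detect_cr <- function(nec, fps, cs_onset_index,
                      onset_threshold = CR_ONSET_THRESHOLD_NEC,
                      sustain_ms = CR_SUSTAIN_MS,
                      amp_threshold = CR_AMP_THRESHOLD_NEC,
                      onset_window = CR_ONSET_WINDOW_MS,
                      peak_window = CR_PEAK_WINDOW_MS) {
  n <- length(nec)
  last <- min(n, cs_onset_index + 1L + ms_to_samples(1000, fps))
  win <- seq.int(cs_onset_index + 2L, last)
  peak_rel <- which.max(nec[win])   # earliest maximal sample
  peak_idx <- win[peak_rel]
  peak_nec <- nec[peak_idx]
  peak_ms <- samples_to_ms(peak_idx - cs_onset_index - 1L, fps)

  onset_ms <- NA_real_
  if (peak_nec >= onset_threshold) {
    onset_idx <- peak_idx
    while (onset_idx > 1L && nec[onset_idx - 1L] >= onset_threshold) {
      onset_idx <- onset_idx - 1L
    }
    run_end <- onset_idx
    while (run_end < n && nec[run_end + 1L] >= onset_threshold) {
      run_end <- run_end + 1L
    }
    if (samples_to_ms(run_end - onset_idx + 1L, fps) >= sustain_ms) {
      onset_ms <- samples_to_ms(onset_idx - cs_onset_index - 1L, fps)
    }
  }

  is_cr <- !is.na(onset_ms) &&
    peak_nec > amp_threshold &&
    onset_ms >= onset_window[1] && onset_ms <= onset_window[2] &&
    peak_ms >= peak_window[1] && peak_ms <= peak_window[2]

  tibble::tibble(
    is_cr = is_cr,
    onset_ms = if (is_cr) onset_ms else NA_real_,
    peak_ms = if (is_cr) peak_ms else NA_real_,
    peak_nec = peak_nec
  )
}

#' Is a CR peak perfectly timed?
#'
#' A CR is perfectly timed when its peak falls within `half_window` ms of
#' the (omitted) US onset, boundaries included: 200-300 ms after CS for the
#' 250 ms ISI, 450-550 ms for the 500 ms ISI.
#'
#' @param peak_ms CR peak latency after CS onset, ms (vectorized).
#' @param isi_ms ISI of the trial's phase, ms.
#' @param half_window Half-width of the window, ms.
#' @return Logical vector.
#' @export
#' @examples
#' perfectly_timed(c(250, 549, 551), c(250, 500, 500))
perfectly_timed <- function(peak_ms, isi_ms,
                            half_window = PERFECT_HALF_WINDOW_MS) {
  peak_ms >= isi_ms - half_window & peak_ms <= isi_ms + half_window
}

#' NEC value at a fixed time after CS onset
#'
#' @param nec NEC trace.
#' @param t_ms Time after CS onset, ms.
#' @inheritParams detect_cr
#' @return NEC value at sample `round(cs_onset_index + t_ms * fps / 1000)`.
#' @export
nec_at <- function(nec, t_ms, fps, cs_onset_index) {
  idx <- cs_onset_index + as.integer(round(t_ms * fps / 1000))
  if (any(idx < 0L) || any(idx >= length(nec))) {
    abort_bad_arg("`t_ms` falls outside the trace.")
  }
  nec[idx + 1L]
}

#' Score every CS-only trial of a normalized cohort
#'
#' Runs [detect_cr()] on each valid CS-only trial and evaluates the
#' perfectly-timed flag and the NEC amplitudes at 250 and 500 ms after CS
#' onset. Invalid CS-only trials are kept as rows with `valid = FALSE` and
#' `NA` metrics so that session summaries can report exclusion counts;
#' US-only and paired trials are not scored (conditioned behavior is read
#' from CS-only trials, which show the full CR kinetic profile).
#'
#' @param normalized Tibble from [normalize_cohort()]/[normalize_session()].
#' @inheritParams detect_cr
#' @return Tibble with one row per CS-only trial: metadata, `valid`,
#'   `is_cr`, `onset_ms`, `peak_ms`, `peak_nec`, `perfect`, `nec_250`,
#'   `nec_500`.
#' @export
score_trials <- function(normalized,
                         onset_threshold = CR_ONSET_THRESHOLD_NEC,
                         sustain_ms = CR_SUSTAIN_MS,
                         amp_threshold = CR_AMP_THRESHOLD_NEC) {
  cs <- dplyr::filter(normalized, .data$trial_type == "CS_ONLY")
  if (nrow(cs) == 0) {
    abort_bad_arg("No CS-only trials to score.")
  }
  res <- purrr::pmap(
    list(cs$nec, cs$fps, cs$cs_onset_index, cs$valid, cs$isi_ms),
    function(nec, fps, cs_idx, valid, isi) {
      if (!valid) {
        return(tibble::tibble(is_cr = NA, onset_ms = NA_real_,
                              peak_ms = NA_real_, peak_nec = NA_real_,
                              perfect = NA, nec_250 = NA_real_,
                              nec_500 = NA_real_))
      }
      d <- detect_cr(nec, fps, cs_idx, onset_threshold, sustain_ms,
                     amp_threshold)
      d$perfect <- d$is_cr & !is.na(d$peak_ms) &
        perfectly_timed(d$peak_ms, isi)
      d$perfect[!d$is_cr] <- FALSE
      d$nec_250 <- nec_at(nec, 250, fps, cs_idx)
      d$nec_500 <- nec_at(nec, 500, fps, cs_idx)
      d
    })
  dplyr::bind_cols(
    dplyr::select(cs, -"nec"),
    purrr::list_rbind(res)
  )
}

#' Summarize scored trials per mouse-day session
#'
#' For each (mouse, day): CR proportion and perfectly-timed proportion over
#' valid CS-only trials, mean NEC at 250/500 ms over valid CS-only trials
#' (CR and non-CR alike), and mean onset/peak latency over CR-present
#' trials. Sessions whose CS-only trials are all invalid are emitted with
#' `n_cs_only_valid = 0` and `NA` metrics rather than dropped.
#'
#' @param scored Tibble from [score_trials()].
#' @return Tibble with one row per session.
#' @export
summarize_sessions <- function(scored) {
  scored |>
    dplyr::group_by(.data$mouse_id, .data$genotype, .data$day, .data$phase,
                    .data$isi_ms) |>
    dplyr::summarise(
      n_cs_only_valid = sum(.data$valid),
      n_invalid = sum(!.data$valid),
      cr_proportion = if (sum(.data$valid) > 0) {
        sum(.data$is_cr[.data$valid]) / sum(.data$valid)
      } else NA_real_,
      nec_250 = mean(.data$nec_250[.data$valid]),
      nec_500 = mean(.data$nec_500[.data$valid]),
      mean_onset_ms = if (any(.data$is_cr %in% TRUE)) {
        mean(.data$onset_ms[.data$is_cr %in% TRUE])
      } else NA_real_,
      mean_peak_ms = if (any(.data$is_cr %in% TRUE)) {
        mean(.data$peak_ms[.data$is_cr %in% TRUE])
      } else NA_real_,
      perfect_proportion = if (sum(.data$valid) > 0) {
        sum(.data$perfect[.data$valid]) / sum(.data$valid)
      } else NA_real_,
      .groups = "drop"
    )
}

#' Aggregate session summaries into per-day-by-genotype tables
#'
#' For every metric of [summarize_sessions()] output, computes across mice
#' the mean, SD, median and quartiles per (phase, day, genotype) — the
#' layout of the study's summary tables (e.g. "NEC250ms, mean (SD)"; "CR
#' proportion, median (q25-q75)"). With a single mouse the SD is `NA`.
#'
#' @param summaries Tibble from [summarize_sessions()].
#' @return Long tibble: `phase`, `day`, `genotype`, `metric`, `n`, `mean`,
#'   `sd`, `median`, `q25`, `q75`.
#' @export
aggregate_cohort <- function(summaries) {
  if (nrow(summaries) == 0) abort_bad_arg("No summaries to aggregate.")
  metrics <- c("cr_proportion", "nec_250", "nec_500", "mean_onset_ms",
               "mean_peak_ms", "perfect_proportion")
  summaries |>
    tidyr::pivot_longer(dplyr::all_of(metrics), names_to = "metric") |>
    dplyr::group_by(.data$phase, .data$day, .data$genotype, .data$metric) |>
    dplyr::summarise(
      n = sum(!is.na(.data$value)),
      mean = mean(.data$value, na.rm = TRUE),
      sd = stats::sd(.data$value, na.rm = TRUE),
      median = stats::median(.data$value, na.rm = TRUE),
      q25 = stats::quantile(.data$value, 0.25, na.rm = TRUE, names = FALSE),
      q75 = stats::quantile(.data$value, 0.75, na.rm = TRUE, names = FALSE),
      .groups = "drop"
    )
}
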