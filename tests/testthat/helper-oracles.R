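# Independent brute-force oracles used to cross-check the implementation.
# Each one is a direct transcription of the defining rule, sharing no code
# with the package internals it checks.

# Frequency-domain low-pass: zero out all FFT bins above the cutoff and
# invert. An idealized filter; used only to bound pass/stop-band behavior.
oracle_fft_lowpass <- function(x, fps, cutoff) {
  n <- length(x)
  f <- stats::fft(x)
  freqs <- (seq_len(n) - 1) / n * fps
  freqs <- pmin(freqs, fps - freqs) # two-sided
  f[freqs > cutoff] <- 0
  Re(stats::fft(f, inverse = TRUE)) / n
}

# Definitional trial-validity scan (same guard as the implementation).
oracle_validity <- function(samples, cs_onset_index, fps, k = 7,
                            pre_cs_ms = 500) {
  n_pre <- round(fps * pre_cs_ms / 1000)
  pre <- samples[(cs_onset_index - n_pre + 1):cs_onset_index]
  dev <- max(abs(pre - median(pre)))
  dev <= k * IQR(pre) + 1e-4 * max(abs(samples))
}

# Definitional UR normalization factor.
oracle_ur_factor <- function(session, ur_source = "both") {
  types <- if (ur_source == "both") c("US_ONLY", "PAIRED") else "US_ONLY"
  keep <- session$trial_type %in% types & session$valid
  stopifnot(any(keep))
  traces <- session$samples[keep]
  avg <- Reduce(`+`, traces) / length(traces)
  from <- session$cs_onset_index[keep][1] +
    round(session$fps[keep][1] * session$isi_ms[keep][1] / 1000)
  max(avg[(from + 1):length(avg)])
}

# Definitional CR scan: argmax over (CS, CS + 1000 ms], onset = first
# sample of the >= threshold run containing the peak, sustained >= 10 ms;
# CR iff amplitude > 0.1 and onset in [50, 500] and peak in [100, 1000].
oracle_detect_cr <- function(nec, fps, cs_idx, thr = 0.02, amp = 0.1,
                             sustain_ms = 10) {
  n <- length(nec)
  idx <- (cs_idx + 2):min(n, cs_idx + 1 + round(fps))
  peak_i <- idx[which.max(nec[idx])]
  peak_nec <- nec[peak_i]
  peak_ms <- (peak_i - cs_idx - 1) / fps * 1000
  onset_ms <- NA_real_
  if (peak_nec >= thr) {
    above <- nec >= thr
    o <- peak_i
    while (o > 1 && above[o - 1]) o <- o - 1
    e <- o
    while (e < n && above[e + 1]) e <- e + 1
    if ((e - o + 1) / fps * 1000 >= sustain_ms) {
      onset_ms <- (o - cs_idx - 1) / fps * 1000
    }
  }
  is_cr <- !is.na(onset_ms) && peak_nec > amp &&
    onset_ms >= 50 && onset_ms <= 500 && peak_ms >= 100 && peak_ms <= 1000
  list(is_cr = is_cr,
       onset_ms = if (is_cr) onset_ms else NA_real_,
       peak_ms = if (is_cr) peak_ms else NA_real_,
       peak_nec = peak_nec)
}

# A tiny hand-built session table in the layout normalize_session()
# consumes after filtering/alignment (list-column `samples` + metadata).
make_session <- function(traces, types, fps = 10, cs_idx = 5, isi = 250,
                         valid = TRUE) {
  tibble::tibble(
    mouse_id = "m1", genotype = "WT", day = 1L, phase = "ISI250",
    block = 1L, trial = seq_along(traces),
    trial_type = factor(types, levels = c("CS_ONLY", "US_ONLY", "PAIRED")),
    isi_ms = isi, fps = fps, cs_onset_index = cs_idx,
    samples = traces, valid = rep_len(valid, length(traces))
  )
}

# Small noise-free cohort parameters reused across recovery tests:
# 6 mice x 5 days x 3 blocks = 90 CS-only trials.
recovery_params <- function(seed = 101) {
  sim_params(n_per_genotype = 3, days_phase1 = 3, days_phase2 = 2,
             n_blocks = 3, noise_sd = 0, artifact_prob = 0, seed = seed)
}
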