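#' Build a semi-random trial schedule for one session
#'
#' A session consists of `n_blocks` blocks of 12 trials; each block holds
#' exactly 1 CS-only, 1 US-only and 10 paired CS-US trials in a seeded random
#' order (the "semi-random" constraint: composition is fixed per block, order
#' is random within it).
#'
#' @param n_blocks Number of blocks (default 20, i.e. 240 trials).
#' @param seed Optional RNG seed; the caller's RNG state is left untouched.
#' @return A tibble with columns `trial` (1-based within session), `block`,
#'   and `trial_type` (factor: `CS_ONLY`, `US_ONLY`, `PAIRED`).
#' @export
#' @examples
#' sched <- make_schedule(20, seed = 1)
#' table(sched$trial_type)
make_schedule <- function(n_blocks = 20, seed = NULL) {
  if (!is.numeric(n_blocks) || length(n_blocks) != 1 || n_blocks < 1) {
    abort_bad_arg("`n_blocks` must be a single integer >= 1.")
  }
  n_blocks <- as.integer(n_blocks)
  block_types <- c("CS_ONLY", "US_ONLY", rep("PAIRED", 10))
  types <- with_seed(seed, {
    unlist(lapply(seq_len(n_blocks), function(b) sample(block_types)))
  })
  tibble::tibble(
    trial = seq_len(12L * n_blocks),
    block = rep(seq_len(n_blocks), each = 12L),
    trial_type = factor(types, levels = c("CS_ONLY", "US_ONLY", "PAIRED"))
  )
}

#' Air-puff trigger time compensating the delivery delay
#'
#' The puff-delivery hardware has an inherent delay, so the US must be
#' triggered `delivery_delay_ms` before the intended US onset for the puff to
#' hit the cornea exactly at the ISI. For the standard 250 ms ISI and a 14 ms
#' delay the trigger time is 236 ms after CS onset.
#'
#' @param isi_ms Interstimulus interval (CS onset to intended US onset), ms.
#' @param delivery_delay_ms Delivery delay of the puff, ms.
#' @return Trigger time after CS onset, ms.
#' @export
#' @examples
#' us_trigger_time(250, 14) # 236
us_trigger_time <- function(isi_ms, delivery_delay_ms = 14) {
  stop_if_not_scalar_number(isi_ms, "isi_ms", min = 0, strict_min = TRUE)
  stop_if_not_scalar_number(delivery_delay_ms, "delivery_delay_ms", min = 0)
  if (delivery_delay_ms >= isi_ms) {
    abort_bad_arg("`delivery_delay_ms` must be smaller than `isi_ms`.")
  }
  isi_ms - delivery_delay_ms
}

# Phase bookkeeping: day -> phase label, ISI and 1-based within-phase day.
phase_of_day <- function(day, params) {
  in1 <- day <= params$days_phase1
  list(
    phase = ifelse(in1, "ISI250", "ISI500"),
    isi_ms = ifelse(in1, params$isi_phase1_ms, params$isi_phase2_ms),
    local_day = ifelse(in1, day, day - params$days_phase1)
  )
}

# Saturating acquisition law shared by CR probability and amplitude:
# phase 1: a_max * (1 - exp(-k d)); phase 2 restarts from carry_over times
# the phase-1 terminal value and grows to a_max.
saturating_level <- function(day, k, a_max, params) {
  ph <- phase_of_day(day, params)
  d <- ph$local_day
  if (ph$phase == "ISI250" || params$days_phase1 == 0L) {
    a_max * (1 - exp(-k * d))
  } else {
    end1 <- a_max * (1 - exp(-k * params$days_phase1))
    floor_lv <- params$carry_over * end1
    floor_lv + (a_max - floor_lv) * (1 - exp(-k * d))
  }
}

#' True conditioned-response probability on a given training day
#'
#' Saturating acquisition curve `p_max * (1 - exp(-k_g * d))` within a phase
#' (`d` the 1-based day within the phase); at the ISI switch the curve
#' restarts from `carry_over` times the phase-1 terminal value and regrows
#' toward `p_max`. Monotone nondecreasing within each phase.
#'
#' @param day Training day (1-based over both phases).
#' @param genotype `"WT"` or `"NF1_HET"`.
#' @param params A [sim_params()] object.
#' @return CR probability in `[0, p_max]`.
#' @export
#' @examples
#' p <- sim_params()
#' cr_probability(6, "WT", p)
cr_probability <- function(day, genotype, params) {
  stopifnot(inherits(params, "sim_params"))
  if (!all(genotype %in% names(params$learn_rate_by_genotype))) {
    abort_bad_arg(sprintf("Unknown genotype: %s",
                          paste(setdiff(genotype,
                                        names(params$learn_rate_by_genotype)),
                                collapse = ", ")))
  }
  n_days <- params$days_phase1 + params$days_phase2
  if (any(day < 1 | day > n_days)) {
    abort_bad_arg(sprintf("`day` must be in 1..%d.", n_days))
  }
  k <- params$learn_rate_by_genotype[genotype]
  mapply(function(d, kk) saturating_level(d, kk, params$p_max, params),
         day, k, USE.NAMES = FALSE)
}

# CR peak amplitude (NEC units) on a given day; same saturating law.
cr_amplitude <- function(day, genotype, params) {
  k <- params$learn_rate_by_genotype[[genotype]]
  saturating_level(day, k, params$amp_max, params)
}

# Mean CR peak time (ms after CS onset): within a phase the mean relaxes
# exponentially toward the current US onset; phase 2 starts from the phase-1
# terminal mean.
cr_peak_mean_ms <- function(day, params) {
  ph <- phase_of_day(day, params)
  relax <- function(start, target, d) {
    target + (start - target) * exp(-params$timing_adapt_rate * (d - 1))
  }
  if (ph$phase == "ISI250") {
    relax(params$cr_peak_init_ms, params$isi_phase1_ms, ph$local_day)
  } else {
    end1 <- if (params$days_phase1 > 0) {
      relax(params$cr_peak_init_ms, params$isi_phase1_ms, params$days_phase1)
    } else {
      params$cr_peak_init_ms
    }
    relax(end1, params$isi_phase2_ms, ph$local_day)
  }
}
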