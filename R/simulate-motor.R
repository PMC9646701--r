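# Synthetic motor-task tables: ladder step proportions from a two-part
# (hurdle) law, rotarod latencies from a right-censored log-normal,
# balance-beam crossing times and grip forces from log-normals, all with
# per-mouse random effects.

#' Parameters for the synthetic motor-task tables
#'
#' Defaults mirror the study's task structure: 24 wild-type and 23 mutant
#' mice; 5 ladder days of 42 runs with a 16% clean-sweep rate; 4 rotarod
#' days of 4 trials censored at 300 s, with part of the cohort switched to
#' 80 RPM for trials 3-4 of days 3-4 (excluded downstream); one recorded
#' balance-beam day with two crossings per width (6 and 12 mm); 4 grip days
#' of 2 pulls with forces around 90 units. Genotype shifts default to 0 (no
#' true effect); set them for power simulations.
#'
#' @param n_wt,n_het Mice per genotype.
#' @param ladder_days,ladder_trials Ladder days and runs per day.
#' @param clean_sweep_prob Baseline clean-sweep probability (day 1).
#' @param ladder_day_effect Per-day improvement of the clean-sweep log-odds.
#' @param mixed_mu Baseline mean correct-step proportion in mixed trials.
#' @param mixed_day_effect Per-day improvement of the mixed-trial logit mean.
#' @param mixed_phi Beta precision of mixed-trial proportions.
#' @param ladder_mouse_sd Per-mouse random-effect SD (logit scale).
#' @param ladder_genotype_logit Genotype shift of both ladder parts (logit).
#' @param rotarod_days,rotarod_trials Rotarod days and trials per day.
#' @param rotarod_meanlog Log-latency mean on day 1.
#' @param rotarod_day_gain Per-day increase of the log-latency mean.
#' @param rotarod_sdlog Log-latency SD.
#' @param rotarod_mouse_sd Per-mouse random-effect SD (log scale).
#' @param rotarod_frac_80 Fraction of mice run at 80 RPM on trials 3-4 of
#'   days 3-4.
#' @param rotarod_genotype_log Genotype shift of the log latency.
#' @param censor_s Rotarod censoring bound, s.
#' @param beam_meanlog_6,beam_meanlog_12 Log crossing-time means per width.
#' @param beam_sdlog,beam_mouse_sd Beam log-scale SDs.
#' @param beam_reps Crossings per width.
#' @param beam_genotype_log Genotype shift of the log crossing time.
#' @param grip_days,grip_reps Grip days and pulls per day.
#' @param grip_meanlog,grip_sdlog,grip_mouse_sd Grip log-scale parameters.
#' @param grip_genotype_log Genotype shift of the log force.
#' @param seed Root RNG seed.
#' @return A list of class `motor_sim_params`.
#' @export
motor_sim_params <- function(n_wt = 24, n_het = 23,
                             ladder_days = 5, ladder_trials = 42,
                             clean_sweep_prob = 0.16,
                             ladder_day_effect = 0.15,
                             mixed_mu = 0.75, mixed_day_effect = 0.12,
                             mixed_phi = 8, ladder_mouse_sd = 0.3,
                             ladder_genotype_logit = 0,
                             rotarod_days = 4, rotarod_trials = 4,
                             rotarod_meanlog = log(60),
                             rotarod_day_gain = 0.35,
                             rotarod_sdlog = 0.45,
                             rotarod_mouse_sd = 0.25,
                             rotarod_frac_80 = 0.6,
                             rotarod_genotype_log = 0,
                             censor_s = ROTAROD_CENSOR_S,
                             beam_meanlog_6 = log(6),
                             beam_meanlog_12 = log(4),
                             beam_sdlog = 0.3, beam_mouse_sd = 0.2,
                             beam_reps = 2, beam_genotype_log = 0,
                             grip_days = 4, grip_reps = 2,
                             grip_meanlog = log(90), grip_sdlog = 0.12,
                             grip_mouse_sd = 0.05, grip_genotype_log = 0,
                             seed = 1L) {
  p <- as.list(environment())
  structure(p, class = "motor_sim_params")
}

#' Simulate the four motor-task tables
#'
#' Draws seeded synthetic tables with the statistical structure the motor
#' analyses assume: ladder correct-step proportions from a two-part law
#' (clean sweep with a logit-linear probability, otherwise a beta draw),
#' rotarod latencies from a day-trending log-normal right-censored at the
#' 300 s ceiling (with an 80 RPM sub-experiment to exclude), beam crossing
#' times and grip forces from log-normals. One shared per-mouse random
#' effect per task induces the within-mouse correlation the multilevel
#' models target.
#'
#' @param params A [motor_sim_params()] object.
#' @return List of tibbles: `ladder`, `rotarod`, `beam`, `grip`.
#' @export
#' @examples
#' tabs <- simulate_motor_tables(motor_sim_params(n_wt = 3, n_het = 3))
#' names(tabs)
simulate_motor_tables <- function(params = motor_sim_params()) {
  stopifnot(inherits(params, "motor_sim_params"))
  p <- params
  mice <- tibble::tibble(
    genotype = c(rep("WT", p$n_wt), rep("NF1_HET", p$n_het)),
    mouse_id = c(paste0("WT_", sprintf("%02d", seq_len(p$n_wt))),
                 paste0("NF1_HET_", sprintf("%02d", seq_len(p$n_het))))
  )
  g_ind <- as.numeric(mice$genotype == "NF1_HET")

  with_seed(p$seed, {
    # ErasmusLadder -----------------------------------------------------
    u <- stats::rnorm(nrow(mice), 0, p$ladder_mouse_sd)
    ladder <- tidyr::expand_grid(mice, day = seq_len(p$ladder_days),
                                 trial = seq_len(p$ladder_trials))
    iu <- match(ladder$mouse_id, mice$mouse_id)
    eta_clean <- stats::qlogis(p$clean_sweep_prob) +
      p$ladder_day_effect * (ladder$day - 1) +
      p$ladder_genotype_logit * g_ind[iu] + u[iu]
    clean <- stats::runif(nrow(ladder)) < stats::plogis(eta_clean)
    mu <- stats::plogis(stats::qlogis(p$mixed_mu) +
                          p$mixed_day_effect * (ladder$day - 1) +
                          p$ladder_genotype_logit * g_ind[iu] + u[iu])
    prop <- stats::rbeta(nrow(ladder), mu * p$mixed_phi, (1 - mu) * p$mixed_phi)
    ladder$prop_correct <- ifelse(clean, 1, prop)
    ladder$is_clean_sweep <- clean

    # Accelerating rotarod ---------------------------------------------
    v <- stats::rnorm(nrow(mice), 0, p$rotarod_mouse_sd)
    in80 <- stats::runif(nrow(mice)) < p$rotarod_frac_80
    rotarod <- tidyr::expand_grid(mice, day = seq_len(p$rotarod_days),
                                  trial = seq_len(p$rotarod_trials))
    iu <- match(rotarod$mouse_id, mice$mouse_id)
    rotarod$rpm_condition <- ifelse(
      in80[iu] & rotarod$day >= 3 & rotarod$trial >= 3, 80, 40)
    raw <- stats::rlnorm(nrow(rotarod),
                         p$rotarod_meanlog + p$rotarod_day_gain * (rotarod$day - 1) +
                           p$rotarod_genotype_log * g_ind[iu] + v[iu],
                         p$rotarod_sdlog)
    rotarod$censored <- raw >= p$censor_s
    rotarod$latency_s <- pmin(raw, p$censor_s)

    # Balance beam -------------------------------------------------------
    w <- stats::rnorm(nrow(mice), 0, p$beam_mouse_sd)
    beam <- tidyr::expand_grid(mice, width_mm = c(6, 12),
                               rep = seq_len(p$beam_reps))
    iu <- match(beam$mouse_id, mice$mouse_id)
    beam$time_s <- stats::rlnorm(
      nrow(beam),
      ifelse(beam$width_mm == 6, p$beam_meanlog_6, p$beam_meanlog_12) +
        p$beam_genotype_log * g_ind[iu] + w[iu],
      p$beam_sdlog)

    # Grip strength ------------------------------------------------------
    z <- stats::rnorm(nrow(mice), 0, p$grip_mouse_sd)
    grip <- tidyr::expand_grid(mice, day = seq_len(p$grip_days),
                               rep = seq_len(p$grip_reps))
    iu <- match(grip$mouse_id, mice$mouse_id)
    grip$force_n <- stats::rlnorm(
      nrow(grip),
      p$grip_meanlog + p$grip_genotype_log * g_ind[iu] + z[iu],
      p$grip_sdlog)

    list(ladder = ladder, rotarod = rotarod, beam = beam, grip = grip)
  })
}
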