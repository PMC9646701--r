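# Motor battery analyses: ladder two-part step analysis, rotarod
# censored-latency preparation, balance-beam and grip-strength log-scale
# models with back-translation to the measurement scale.

#' Split ladder trials into the two-part analysis tables
#'
#' A ladder trial is a "clean sweep" when its proportion of correct steps
#' equals 1 (after upstream backstep exclusion; equality within 1e-9). The
#' two-part analysis models (a) the clean-sweep flag over all trials and
#' (b) the correct-step proportion within the remaining mixed trials.
#'
#' @param ladder Tibble with `mouse_id`, `genotype`, `day`, `trial` and
#'   `prop_correct` in \[0, 1\].
#' @return List: `all_trials` (input plus `is_clean_sweep`), `mixed_trials`
#'   (trials with `prop_correct < 1`), `n_clean`, `n_mixed`.
#' @export
ladder_prepare <- function(ladder) {
  if (!"prop_correct" %in% names(ladder)) {
    abort_bad_arg("Missing column(s): prop_correct.")
  }
  p <- ladder$prop_correct
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    abort_bad_arg("`prop_correct` must lie in [0, 1].")
  }
  all_trials <- dplyr::mutate(ladder, is_clean_sweep = p >= 1 - 1e-9)
  mixed <- dplyr::filter(all_trials, !.data$is_clean_sweep)
  list(
    all_trials = all_trials,
    mixed_trials = mixed,
    n_clean = sum(all_trials$is_clean_sweep),
    n_mixed = nrow(mixed)
  )
}

#' Two-part ladder analysis
#'
#' Part one: mixed binomial logistic regression of the clean-sweep flag
#' over all trials (day x genotype, per-mouse random effects). Part two:
#' mixed beta regression of the correct-step proportion within mixed trials
#' after boundary compression with [compress_proportions()] (mixed trials
#' can still contain proportion 0).
#'
#' @param prepared Output of [ladder_prepare()].
#' @param random Random structure passed to the fitters.
#' @return List of two `ebc_fit`s: `clean_sweep`, `mixed`.
#' @export
ladder_analyze <- function(prepared,
                           random = c("auto", "intercepts", "slopes")) {
  random <- match.arg(random)
  if (nrow(prepared$mixed_trials) == 0) {
    abort_bad_arg("No mixed trials: every trial is a clean sweep.")
  }
  clean_fit <- fit_trialwise_logistic(prepared$all_trials,
                                      outcome = "is_clean_sweep",
                                      time_var = "day", random = random)
  mixed <- prepared$mixed_trials
  mixed$prop_compressed <- compress_proportions(mixed$prop_correct)
  beta_fit <- fit_beta_mixed(mixed, outcome = "prop_compressed",
                             time_var = "day", random = random)
  list(clean_sweep = clean_fit, mixed = beta_fit)
}

#' Prepare rotarod latencies for the censored survival analysis
#'
#' Drops the 80 RPM sub-experiment rows, caps latencies at the 300 s
#' ceiling, and flags capped latencies as censored (`event = FALSE`).
#'
#' @param rotarod Tibble with `mouse_id`, `genotype`, `day`, `trial`,
#'   `rpm_condition` and `latency_s`.
#' @param censor_s Censoring bound, s.
#' @return Tibble of 40 RPM rows with `latency_s` capped, `censored` and
#'   `event` columns.
#' @export
rotarod_prepare <- function(rotarod, censor_s = ROTAROD_CENSOR_S) {
  needed <- c("rpm_condition", "latency_s")
  missing <- setdiff(needed, names(rotarod))
  if (length(missing) > 0) {
    abort_bad_arg(sprintf("Missing column(s): %s.",
                          paste(missing, collapse = ", ")))
  }
  rotarod |>
    dplyr::filter(.data$rpm_condition == 40) |>
    dplyr::mutate(
      censored = .data$latency_s >= censor_s,
      latency_s = pmin(.data$latency_s, censor_s),
      event = !.data$censored
    )
}

#' Balance-beam crossing-time analysis
#'
#' Log-transformed crossing times analysed with a linear mixed model with
#' beam width, genotype and their interaction as fixed effects and random
#' intercepts per mouse; likelihood-ratio omnibus tests and Holm-adjusted
#' per-width genotype contrasts (on the log scale).
#'
#' @param beam Tibble with `mouse_id`, `genotype`, `width_mm` and `time_s`.
#' @return An `ebc_fit`.
#' @export
beam_analyze <- function(beam) {
  if (!all(c("width_mm", "time_s") %in% names(beam))) {
    abort_bad_arg("Missing column(s): width_mm, time_s.")
  }
  if (any(beam$time_s <= 0)) abort_bad_arg("Crossing times must be positive.")
  fit_lmm(beam, outcome = "time_s", time_var = "width_mm",
          random = "intercepts", transform = "log")
}

#' Grip-strength analysis with back-translated group means
#'
#' Log-transformed peak forces analysed with a linear mixed model (genotype
#' fixed, random intercepts per mouse). Group means and their confidence
#' intervals are exponentiated back to force units; the genotype difference
#' is reported as the difference of back-translated means with a
#' delta-method confidence interval.
#'
#' @param grip Tibble with `mouse_id`, `genotype` and `force_n`.
#' @return An `ebc_fit` with an extra `back_translated` tibble (per-group
#'   means and the group difference, in newton).
#' @export
grip_analyze <- function(grip) {
  if (!"force_n" %in% names(grip)) abort_bad_arg("Missing column(s): force_n.")
  if (any(grip$force_n <= 0)) abort_bad_arg("Forces must be positive.")
  fit <- fit_lmm(grip, outcome = "force_n", time_var = NULL,
                 random = "intercepts", transform = "log")
  b <- if (inherits(fit$model, "merMod")) lme4::fixef(fit$model)
       else stats::coef(fit$model)
  V <- as.matrix(stats::vcov(fit$model))
  df <- prepare_model_frame(grip, "force_n", NULL)
  X <- stats::model.matrix(~genotype, df)
  glev <- levels(df$genotype)
  rows <- lapply(glev, function(g) X[which(df$genotype == g)[1], ])
  C <- do.call(rbind, rows)
  m <- drop(C %*% b)                # log-scale group means
  Vm <- C %*% V %*% t(C)
  t_df <- max(nlevels(df$mouse_id) - 2, 1)
  crit <- stats::qt(0.975, t_df)
  se_m <- sqrt(diag(Vm))
  grad <- c(-exp(m[1]), exp(m[2])) # delta method for exp(m2) - exp(m1)
  diff_est <- exp(m[2]) - exp(m[1])
  diff_se <- sqrt(drop(t(grad) %*% Vm %*% grad))
  fit$back_translated <- tibble::tibble(
    group = c(glev, paste(glev[2], "-", glev[1])),
    estimate = c(exp(m), diff_est),
    conf.low = c(exp(m - crit * se_m), diff_est - crit * diff_se),
    conf.high = c(exp(m + crit * se_m), diff_est + crit * diff_se)
  )
  fit
}
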