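# End-to-end pipeline: simulate (or load) -> preprocess -> score ->
# summarise -> statistical battery -> motor analyses, writing per-stage
# artifacts, a QC report and a reproducibility log.

read_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (grepl("\\.ya?ml$", config)) {
      config <- yaml::read_yaml(config)
    } else if (grepl("\\.json$", config)) {
      config <- jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      abort_bad_arg("Config file must be .yaml/.yml or .json.")
    }
  }
  if (!is.list(config)) abort_bad_arg("`config` must be a list or a file path.")
  config
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    rlang::abort(sprintf("Pipeline stage '%s' failed: %s", name,
                         conditionMessage(e)),
                 class = "eyeblinkr_pipeline_error", parent = e)
  })
}

fit_to_list <- function(fit) {
  list(
    family = fit$family, outcome = fit$outcome,
    random_structure = fit$random_structure, loglik = fit$loglik,
    n_obs = fit$n_obs, n_mice = fit$n_mice,
    omnibus = as.data.frame(fit$omnibus),
    contrasts = if (!is.null(fit$contrasts)) as.data.frame(fit$contrasts),
    back_translated = if (!is.null(fit$back_translated)) {
      as.data.frame(fit$back_translated)
    }
  )
}

#' Run the full analysis pipeline
#'
#' Simulates a cohort (or reads one from EBC-CSV), normalizes and scores
#' the traces, summarises sessions, aggregates the per-day-by-genotype
#' tables, fits the per-phase statistical battery (trialwise CR logistic,
#' NEC-at-250-ms linear mixed model, perfectly-timed logistic), and
#' optionally simulates and analyses the motor battery. All numeric
#' artifacts are written as CSV/JSON under `out_dir` together with a QC
#' report (invalid trials, unusable sessions) and a log recording versions,
#' the seed and a config hash; a rerun with the same config is
#' byte-identical.
#'
#' @param config List or path to a YAML/JSON file. Recognised entries:
#'   `seed` (default 1), `sim` (arguments to [sim_params()]), `input`
#'   (EBC-CSV path, overrides simulation), `preprocess` (arguments to
#'   [normalize_cohort()]), `random` (random structure for the fitters),
#'   `motor` (logical, default TRUE) and `motor_sim` (arguments to
#'   [motor_sim_params()]).
#' @param out_dir Artifacts directory (created if needed).
#' @return Invisibly, a list with the in-memory artifacts and their paths.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("ebc_run_")) {
  config <- read_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config[["seed"]] %||% 1L
  random <- config[["random"]] %||% "auto"

  sim_res <- stage("simulate", {
    if (!is.null(config[["input"]])) {
      list(cohort = NULL, trials = read_ebc(config[["input"]]))
    } else {
      sim_args <- config[["sim"]] %||% list()
      sim_args$seed <- seed
      co <- simulate_cohort(do.call(sim_params, sim_args))
      list(cohort = co, trials = co$trials)
    }
  })
  cohort <- sim_res$cohort
  trials <- sim_res$trials

  normalized <- stage("preprocess", {
    do.call(normalize_cohort, c(list(trials), config[["preprocess"]] %||% list()))
  })
  scored <- stage("cr_metrics", score_trials(normalized))
  summaries <- stage("cr_metrics", summarize_sessions(scored))
  tables <- stage("cr_metrics", aggregate_cohort(summaries))

  qc <- tibble::tibble(
    mouse_id = summaries$mouse_id, day = summaries$day,
    n_cs_only_valid = summaries$n_cs_only_valid,
    n_invalid = summaries$n_invalid, reason = "scored"
  )
  unusable <- attr(normalized, "unusable_sessions")
  if (!is.null(unusable) && nrow(unusable) > 0) {
    qc <- dplyr::bind_rows(qc, dplyr::mutate(
      unusable, n_cs_only_valid = NA_integer_, n_invalid = NA_integer_))
  }

  fits <- stage("stats_models", {
    out <- list()
    for (ph in unique(scored$phase)) {
      sub <- dplyr::filter(scored, .data$phase == ph, .data$valid)
      if (dplyr::n_distinct(sub$day) < 2 ||
          dplyr::n_distinct(sub$genotype) < 2) next
      out[[paste0("cr_logistic_", ph)]] <-
        fit_trialwise_logistic(sub, random = random)
      out[[paste0("nec250_lmm_", ph)]] <-
        fit_lmm(sub, outcome = "nec_250", random = random)
      if (dplyr::n_distinct(sub$perfect) > 1) {
        out[[paste0("perfect_logistic_", ph)]] <-
          fit_trialwise_logistic(sub, outcome = "perfect", random = random)
      }
    }
    out
  })

  motor_fits <- NULL
  if (isTRUE(config[["motor"]] %||% TRUE)) {
    motor_fits <- stage("motor_tasks", {
      margs <- config[["motor_sim"]] %||% list()
      margs$seed <- seed
      tabs <- simulate_motor_tables(do.call(motor_sim_params, margs))
      prep <- ladder_prepare(tabs$ladder)
      lad <- ladder_analyze(prep, random = if (random == "auto") "auto" else random)
      rr <- rotarod_prepare(tabs$rotarod)
      list(
        ladder_clean_sweep = lad$clean_sweep, ladder_mixed = lad$mixed,
        rotarod = fit_cox_frailty(rr),
        beam = beam_analyze(tabs$beam),
        grip = grip_analyze(tabs$grip)
      )
    })
  }

  paths <- list(
    session_summaries = file.path(out_dir, "session_summaries.csv"),
    cohort_tables = file.path(out_dir, "cohort_tables.csv"),
    cr_trials = file.path(out_dir, "cr_trials.csv"),
    qc_report = file.path(out_dir, "qc_report.csv"),
    fits = file.path(out_dir, "fits.json"),
    log = file.path(out_dir, "log.txt")
  )
  readr::write_csv(summaries, paths$session_summaries)
  readr::write_csv(tables, paths$cohort_tables)
  readr::write_csv(dplyr::select(scored, -dplyr::any_of("samples")),
                   paths$cr_trials)
  readr::write_csv(qc, paths$qc_report)
  jsonlite::write_json(
    purrr::map(c(fits, motor_fits), fit_to_list),
    paths$fits, auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(c(
    sprintf("eyeblinkr %s | R %s", as.character(utils::packageVersion("eyeblinkr")),
            paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("seed: %s", seed),
    sprintf("config_hash: %s", rlang::hash(config))
  ), paths$log)

  invisible(list(cohort = cohort, normalized = normalized, scored = scored,
                 summaries = summaries, tables = tables, fits = fits,
                 motor_fits = motor_fits, qc = qc, paths = paths))
}
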