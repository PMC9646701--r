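# Multilevel model battery: mixed binomial logistic, linear mixed, mixed
# beta, and Cox frailty fits with day x genotype structure, LR or Wald
# omnibus tests per term, random-structure selection and Holm-corrected
# per-timepoint genotype contrasts.
#
# All models are estimated by maximum likelihood so log-likelihoods are
# comparable across nested fits. Factors are coded sum-to-zero, making the
# Wald block tests type-III-style; reported contrasts are computed from
# design-row differences and are invariant to the coding.

# ---- data preparation -------------------------------------------------

prepare_model_frame <- function(data, outcome, time_var, mouse_var = "mouse_id") {
  needed <- c(outcome, "genotype", mouse_var, time_var)
  missing <- setdiff(needed, names(data))
  if (length(missing) > 0) {
    abort_bad_arg(sprintf("Missing column(s): %s.",
                          paste(missing, collapse = ", ")))
  }
  df <- dplyr::as_tibble(data)
  df <- df[!is.na(df[[outcome]]), , drop = FALSE]
  df$mouse_id <- factor(df[[mouse_var]])
  glev <- unique(as.character(df$genotype))
  df$genotype <- if (setequal(glev, c("WT", "NF1_HET"))) {
    factor(df$genotype, levels = c("WT", "NF1_HET"))
  } else {
    factor(df$genotype)
  }
  if (nlevels(df$genotype) != 2) {
    abort_bad_arg("`genotype` must have exactly two levels.")
  }
  stats::contrasts(df$genotype) <- stats::contr.sum(2)
  if (!is.null(time_var)) {
    df[[time_var]] <- factor(df[[time_var]])
    if (nlevels(df[[time_var]]) > 1) {
      stats::contrasts(df[[time_var]]) <- stats::contr.sum(nlevels(df[[time_var]]))
    }
    df$.mouse_time <- interaction(df$mouse_id, df[[time_var]], drop = TRUE)
  }
  df
}

fixed_rhs_full <- function(time_var) {
  if (is.null(time_var)) "genotype" else paste0(time_var, " * genotype")
}

random_part <- function(structure) {
  switch(structure,
    intercepts = "(1 | mouse_id)",
    slopes = "(1 | mouse_id) + (1 | .mouse_time)",
    abort_bad_arg(sprintf("Unknown random structure '%s'.", structure))
  )
}

# Fit one mixed model; returns list(model, loglik, df, messages).
mixed_fit_once <- function(data, outcome, fixed_rhs, family, structure,
                           nAGQ = 1) {
  f <- stats::as.formula(paste(outcome, "~", fixed_rhs, "+",
                               random_part(structure)))
  msgs <- character(0)
  collect <- function(w) {
    msgs <<- c(msgs, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  mod <- withCallingHandlers(
    switch(family,
      gaussian = if (structure == "intercepts") {
        tryCatch(
          lme4::lmer(f, data = data, REML = FALSE),
          error = function(e) {
            # e.g. one observation per mouse: random intercept
            # unidentifiable, degenerate to the fixed-effects model
            msgs <<- c(msgs, paste("lmer failed, fixed-effects fallback:",
                                   conditionMessage(e)))
            stats::lm(stats::as.formula(paste(outcome, "~", fixed_rhs)),
                      data = data)
          })
      } else {
        lme4::lmer(f, data = data, REML = FALSE)
      },
      binomial = {
        n_re <- length(lme4::findbars(f))
        lme4::glmer(f, data = data, family = stats::binomial(),
                    nAGQ = if (n_re > 1) 1L else as.integer(nAGQ))
      },
      beta = glmmTMB::glmmTMB(f, data = data, family = glmmTMB::beta_family()),
      abort_bad_arg(sprintf("Unknown family '%s'.", family))
    ),
    warning = collect
  )
  ll <- stats::logLik(mod)
  list(model = mod, loglik = as.numeric(ll), df = attr(ll, "df"),
       messages = msgs)
}

fixef_of <- function(model) {
  if (inherits(model, "glmmTMB")) glmmTMB::fixef(model)$cond
  else if (inherits(model, "merMod")) lme4::fixef(model)
  else stats::coef(model)
}

vcov_fixed <- function(model) {
  if (inherits(model, "glmmTMB")) as.matrix(stats::vcov(model)$cond)
  else as.matrix(stats::vcov(model))
}

# ---- random-structure selection ---------------------------------------

#' Choose between random intercepts and timepoint random slopes
#'
#' Fits the model with (a) random intercepts per mouse and (b) additionally
#' per-mouse-by-timepoint deviations (the identifiable diagonal realization
#' of "random slopes per time point per mouse"), compares them with a
#' likelihood-ratio test, and keeps the slopes model when p < 0.05. If the
#' slopes model fails to fit, the intercepts model is kept with a warning.
#'
#' @param data Data frame with `mouse_id`, `genotype`, the timepoint column
#'   and the outcome.
#' @param outcome Name of the outcome column.
#' @param family `"gaussian"`, `"binomial"` or `"beta"`.
#' @param time_var Name of the timepoint column (default `"day"`).
#' @param nAGQ Quadrature points for single-term binomial fits.
#' @return List: `structure` (`"intercepts"` or `"slopes"`), `lr` (the test
#'   tibble), `loglik_intercepts`, `loglik_slopes`.
#' @export
select_random_structure <- function(data, outcome, family, time_var = "day",
                                    nAGQ = 1) {
  df <- prepare_model_frame(data, outcome, time_var)
  rhs <- fixed_rhs_full(time_var)
  fit_i <- mixed_fit_once(df, outcome, rhs, family, "intercepts", nAGQ)
  fit_s <- tryCatch(
    mixed_fit_once(df, outcome, rhs, family, "slopes", nAGQ),
    error = function(e) NULL
  )
  if (is.null(fit_s) || !is.finite(fit_s$loglik) ||
      fit_s$loglik < fit_i$loglik - 1e-6) {
    warning("Slopes model did not converge; falling back to random intercepts.")
    return(list(structure = "intercepts", lr = NULL,
                loglik_intercepts = fit_i$loglik, loglik_slopes = NA_real_))
  }
  lr <- lr_test(fit_i$loglik, fit_s$loglik, fit_i$df, fit_s$df)
  list(
    structure = if (lr$p.value < 0.05) "slopes" else "intercepts",
    lr = lr,
    loglik_intercepts = fit_i$loglik,
    loglik_slopes = fit_s$loglik
  )
}

# ---- omnibus tests ----------------------------------------------------

# LR omnibus per term via nested ML refits (type-II style: each main effect
# tested against the additive model, the interaction against the full one).
omnibus_lr <- function(df, outcome, family, structure, time_var, nAGQ,
                       full_fit) {
  rows <- list()
  if (is.null(time_var)) {
    null_fit <- mixed_fit_once(df, outcome, "1", family, structure, nAGQ)
    lr <- lr_test(null_fit$loglik, full_fit$loglik, null_fit$df, full_fit$df)
    rows[["genotype"]] <- lr
  } else {
    add <- mixed_fit_once(df, outcome, paste0(time_var, " + genotype"),
                          family, structure, nAGQ)
    day_only <- mixed_fit_once(df, outcome, time_var, family, structure, nAGQ)
    gen_only <- mixed_fit_once(df, outcome, "genotype", family, structure, nAGQ)
    rows[[time_var]] <- lr_test(gen_only$loglik, add$loglik, gen_only$df, add$df)
    rows[["genotype"]] <- lr_test(day_only$loglik, add$loglik, day_only$df, add$df)
    rows[[paste0(time_var, ":genotype")]] <-
      lr_test(add$loglik, full_fit$loglik, add$df, full_fit$df)
  }
  out <- purrr::list_rbind(rows, names_to = "term")
  out$test <- "LR"
  out$df_resid <- nrow(df) - full_fit$df
  out[, c("term", "test", "statistic", "df", "df_resid", "p.value")]
}

# Wald chi-square block test per fixed-effect term.
omnibus_wald <- function(b, V, fixed_rhs, data) {
  tt <- stats::terms(stats::reformulate(fixed_rhs))
  X <- stats::model.matrix(tt, data)
  assign <- attr(X, "assign")
  labels <- attr(tt, "term.labels")
  rows <- purrr::map(seq_along(labels), function(i) {
    cols <- colnames(X)[assign == i]
    idx <- match(intersect(cols, names(b)), names(b))
    idx <- idx[!is.na(b[idx])] # aliased coefficients carry no information
    if (length(idx) == 0) {
      return(tibble::tibble(term = labels[i], test = "Wald",
                            statistic = NA_real_, df = NA_integer_,
                            df_resid = NA_real_, p.value = NA_real_))
    }
    bb <- b[idx]
    stat <- tryCatch(
      drop(t(bb) %*% solve(V[idx, idx, drop = FALSE]) %*% bb),
      error = function(e) NA_real_)
    tibble::tibble(term = labels[i], test = "Wald",
                   statistic = stat, df = length(idx),
                   df_resid = NA_real_,
                   p.value = stats::pchisq(stat, length(idx),
                                           lower.tail = FALSE))
  })
  purrr::list_rbind(rows)
}

# ---- per-timepoint genotype contrasts ---------------------------------

# Genotype contrast (level 2 minus level 1) at each level of time_var,
# from design-row differences; `link` controls back-transformation of the
# estimate column added as `estimate_exp` (odds / hazard ratio).
genotype_contrasts <- function(b, V, df, fixed_rhs, time_var,
                               link = c("identity", "logit", "log"),
                               t_df = NULL) {
  link <- match.arg(link)
  X <- stats::model.matrix(stats::reformulate(fixed_rhs), df)
  X <- X[, intersect(colnames(X), names(b)), drop = FALSE]
  X <- X[, names(b)[names(b) %in% colnames(X)], drop = FALSE]
  glev <- levels(df$genotype)
  levels_t <- if (is.null(time_var)) NA_character_ else levels(df[[time_var]])
  rows <- purrr::map(levels_t, function(lv) {
    pick <- function(g) {
      sel <- df$genotype == g
      if (!is.null(time_var)) sel <- sel & df[[time_var]] == lv
      which(sel)[1]
    }
    i1 <- pick(glev[1]); i2 <- pick(glev[2])
    if (is.na(i1) || is.na(i2)) return(NULL)
    cvec <- X[i2, ] - X[i1, ]
    if (any(is.na(b[cvec != 0]))) return(NULL) # contrast hits aliased terms
    est <- sum(cvec * b)
    se <- sqrt(drop(t(cvec) %*% V %*% cvec))
    stat <- est / se
    if (is.null(t_df)) {
      p <- 2 * stats::pnorm(-abs(stat))
      crit <- stats::qnorm(0.975)
    } else {
      p <- 2 * stats::pt(-abs(stat), t_df)
      crit <- stats::qt(0.975, t_df)
    }
    tibble::tibble(
      level = lv, contrast = paste(glev[2], "-", glev[1]),
      estimate = est, std.error = se, statistic = stat,
      conf.low = est - crit * se, conf.high = est + crit * se,
      p.value = min(max(p, .Machine$double.xmin), 1)
    )
  })
  out <- purrr::list_rbind(purrr::compact(rows))
  if (nrow(out) == 0) return(out)
  out$p.adjusted <- holm_adjust(out$p.value)
  if (link != "identity") {
    out$estimate_exp <- exp(out$estimate)
    out$conf.low_exp <- exp(out$conf.low)
    out$conf.high_exp <- exp(out$conf.high)
  }
  # flag contrasts destabilised by (quasi-)complete separation
  out$unstable <- out$std.error > 5
  out
}

# ---- fit container ----------------------------------------------------

new_ebc_fit <- function(model, family, outcome, time_var, structure,
                        omnibus, contrasts, loglik, n_obs, n_mice,
                        transform = "none", structure_lr = NULL,
                        messages = character(0), extra = list()) {
  structure(
    c(list(
      model = model, family = family, outcome = outcome,
      time_var = time_var, random_structure = structure,
      omnibus = omnibus, contrasts = contrasts, loglik = loglik,
      n_obs = n_obs, n_mice = n_mice, transform = transform,
      structure_lr = structure_lr, messages = messages
    ), extra),
    class = "ebc_fit"
  )
}

#' @export
print.ebc_fit <- function(x, ...) {
  cat(sprintf("<ebc_fit> %s model for '%s' (%d obs, %d mice)\n",
              x$family, x$outcome, x$n_obs, x$n_mice))
  cat(sprintf("  random structure: %s; logLik %.2f\n",
              x$random_structure, x$loglik))
  cat("  omnibus tests:\n")
  print(as.data.frame(x$omnibus), row.names = FALSE, digits = 4)
  if (!is.null(x$contrasts) && nrow(x$contrasts) > 0) {
    cat(sprintf("  %d per-%s genotype contrasts (Holm-adjusted); see tidy()\n",
                nrow(x$contrasts), x$time_var %||% "group"))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Shared driver for the three lme4/glmmTMB families.
ebc_mixed_fit <- function(data, outcome, family, time_var = "day",
                          random = c("auto", "intercepts", "slopes"),
                          transform = c("none", "log"), nAGQ = 1) {
  random <- match.arg(random)
  transform <- match.arg(transform)
  df <- prepare_model_frame(data, outcome, time_var)
  if (transform == "log") {
    if (any(df[[outcome]] <= 0)) {
      abort_bad_arg("Log transform requires a strictly positive outcome.")
    }
    df[[outcome]] <- log(df[[outcome]])
  }
  if (family == "binomial") {
    y <- df[[outcome]]
    if (dplyr::n_distinct(as.integer(y)) < 2) {
      abort_bad_arg("Degenerate fit: the binary outcome takes a single value.")
    }
  }
  if (family == "beta") {
    y <- df[[outcome]]
    if (any(y <= 0 | y >= 1)) {
      abort_bad_arg(paste(
        "Beta regression requires outcomes strictly inside (0, 1);",
        "apply compress_proportions() first."))
    }
  }

  structure_lr <- NULL
  if (random == "auto") {
    if (is.null(time_var)) {
      random <- "intercepts"
    } else {
      sel <- select_random_structure(df, outcome, family, time_var, nAGQ)
      random <- sel$structure
      structure_lr <- sel$lr
    }
  }

  rhs <- fixed_rhs_full(time_var)
  fit <- mixed_fit_once(df, outcome, rhs, family, random, nAGQ)
  b <- fixef_of(fit$model)
  V <- vcov_fixed(fit$model)

  omnibus <- if (family == "binomial") {
    omnibus_wald(b, V, rhs, df)
  } else {
    omnibus_lr(df, outcome, family, random, time_var, nAGQ, fit)
  }
  link <- switch(family, binomial = "logit", beta = "logit", "identity")
  t_df <- if (family == "gaussian") max(nlevels(df$mouse_id) - 2, 1) else NULL
  contrasts <- genotype_contrasts(b, V, df, rhs, time_var, link, t_df)

  new_ebc_fit(fit$model, family, outcome, time_var, random, omnibus,
              contrasts, fit$loglik, nrow(df), nlevels(df$mouse_id),
              transform, structure_lr, fit$messages)
}

# ---- exported fitters -------------------------------------------------

#' Trial-level mixed binomial logistic regression
#'
#' Fits a per-trial Bernoulli mixed logistic model with timepoint, genotype
#' and their interaction as fixed effects and per-mouse random effects
#' (structure chosen by [select_random_structure()] when `random = "auto"`).
#' Omnibus tests are Wald chi-square blocks per term; per-timepoint genotype
#' odds ratios carry Holm-adjusted p-values. Contrasts whose standard error
#' explodes under (quasi-)complete separation are flagged `unstable`.
#'
#' @param data Trial-level data with `mouse_id`, `genotype`, the timepoint
#'   column and a binary outcome.
#' @param outcome Name of the binary outcome column (default `"is_cr"`).
#' @param time_var Timepoint column name (default `"day"`).
#' @param random Random-effect structure.
#' @param nAGQ Quadrature points (single random term only).
#' @return An `ebc_fit`.
#' @export
fit_trialwise_logistic <- function(data, outcome = "is_cr", time_var = "day",
                                   random = c("auto", "intercepts", "slopes"),
                                   nAGQ = 1) {
  ebc_mixed_fit(data, outcome, "binomial", time_var, random, "none", nAGQ)
}

#' Linear mixed model with per-timepoint genotype contrasts
#'
#' ML-fitted linear mixed model with timepoint x genotype fixed effects,
#' per-mouse random effects, likelihood-ratio omnibus tests and
#' Holm-adjusted per-timepoint genotype mean differences (t-based with
#' `n_mice - 2` degrees of freedom).
#'
#' @inheritParams fit_trialwise_logistic
#' @param outcome Name of the continuous outcome column.
#' @param transform `"none"` or `"log"` (applied before fitting).
#' @return An `ebc_fit`.
#' @export
fit_lmm <- function(data, outcome, time_var = "day",
                    random = c("auto", "intercepts", "slopes"),
                    transform = c("none", "log")) {
  ebc_mixed_fit(data, outcome, "gaussian", time_var, random,
                match.arg(transform))
}

#' Mixed beta regression for proportion outcomes
#'
#' Beta regression (logit link) with timepoint x genotype fixed effects and
#' per-mouse random effects, fitted with glmmTMB; likelihood-ratio omnibus
#' tests. Outcomes must lie strictly inside (0, 1) — apply
#' [compress_proportions()] to boundary-valued data first.
#'
#' @inheritParams fit_lmm
#' @return An `ebc_fit`.
#' @export
fit_beta_mixed <- function(data, outcome, time_var = "day",
                           random = c("auto", "intercepts", "slopes")) {
  ebc_mixed_fit(data, outcome, "beta", time_var, random, "none")
}

#' Cox proportional-hazards model with per-mouse frailty
#'
#' Cox model for right-censored latencies with timepoint, genotype and
#' their interaction as fixed effects and a per-mouse log-normal frailty
#' (gaussian on the log-hazard). Omnibus tests are Wald chi-square blocks;
#' per-timepoint genotype hazard ratios carry Holm-adjusted p-values.
#'
#' @param data Data with `mouse_id`, `genotype`, the timepoint column, the
#'   latency column and a logical/0-1 `event` column (TRUE = observed fall,
#'   FALSE = censored).
#' @param time_col Name of the latency column (default `"latency_s"`).
#' @param event_col Name of the event indicator column.
#' @param time_var Timepoint column name (default `"day"`).
#' @return An `ebc_fit`.
#' @export
fit_cox_frailty <- function(data, time_col = "latency_s",
                            event_col = "event", time_var = "day") {
  df <- prepare_model_frame(data, time_col, time_var)
  if (!event_col %in% names(df)) {
    abort_bad_arg(sprintf("Missing column(s): %s.", event_col))
  }
  if (any(df[[time_col]] <= 0)) abort_bad_arg("Latencies must be positive.")
  ev <- as.logical(df[[event_col]])
  if (sum(ev) == 0) abort_bad_arg("Zero events: all latencies are censored.")

  rhs <- fixed_rhs_full(time_var)
  f <- stats::as.formula(sprintf(
    "survival::Surv(%s, %s) ~ %s + survival::frailty(mouse_id, distribution = 'gaussian')",
    time_col, event_col, rhs))
  mod <- survival::coxph(f, data = df)
  b <- stats::coef(mod)
  V <- mod$var[seq_along(b), seq_along(b), drop = FALSE]
  dimnames(V) <- list(names(b), names(b))
  omnibus <- omnibus_wald(b, V, rhs, df)
  contrasts <- genotype_contrasts(b, V, df, rhs, time_var, link = "log")
  new_ebc_fit(mod, "cox", time_col, time_var, "frailty", omnibus, contrasts,
              mod$loglik[2], nrow(df), nlevels(df$mouse_id),
              extra = list(n_events = sum(ev)))
}
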