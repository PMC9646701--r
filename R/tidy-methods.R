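# broom-style accessors for fitted battery models.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an `ebc_fit`
#'
#' @param x An `ebc_fit`.
#' @param type `"contrasts"` (per-timepoint genotype contrasts with
#'   Holm-adjusted p-values), `"omnibus"` (per-term LR/Wald tests) or
#'   `"fixed"` (raw fixed-effect coefficients).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ebc_fit <- function(x, type = c("contrasts", "omnibus", "fixed"), ...) {
  type <- match.arg(type)
  switch(type,
    contrasts = x$contrasts %||% tibble::tibble(),
    omnibus = x$omnibus,
    fixed = {
      b <- if (inherits(x$model, "glmmTMB")) glmmTMB::fixef(x$model)$cond
           else if (inherits(x$model, "merMod")) lme4::fixef(x$model)
           else stats::coef(x$model)
      tibble::tibble(term = names(b), estimate = unname(b))
    }
  )
}

#' Glance at an `ebc_fit`
#'
#' @param x An `ebc_fit`.
#' @param ... Unused.
#' @return One-row tibble: family, outcome, random structure,
#'   log-likelihood, sizes and a convergence flag.
#' @export
glance.ebc_fit <- function(x, ...) {
  tibble::tibble(
    family = x$family, outcome = x$outcome,
    random_structure = x$random_structure,
    logLik = x$loglik, n_obs = x$n_obs, n_mice = x$n_mice,
    clean_fit = length(x$messages) == 0
  )
}
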