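# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded package functions do not
#' perturb the caller's RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive independent child seeds from a root seed; keeps every derived seed
# below 2^31 so it stays a valid R integer.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

abort_bad_arg <- function(msg) {
  rlang::abort(msg, class = "eyeblinkr_invalid_argument")
}

stop_if_not_scalar_number <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort_bad_arg(sprintf("`%s` must be a single finite number.", name))
  }
  if (strict_min && x <= min) {
    abort_bad_arg(sprintf("`%s` must be > %s.", name, format(min)))
  }
  if (!strict_min && x < min) {
    abort_bad_arg(sprintf("`%s` must be >= %s.", name, format(min)))
  }
  invisible(x)
}

ms_to_samples <- function(ms, fps) as.integer(round(fps * ms / 1000))

# 0-based sample offset -> milliseconds
samples_to_ms <- function(idx, fps) idx / fps * 1000
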