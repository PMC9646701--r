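# EBC-CSV: a plain-text interchange format for eyelid-trace datasets.
# Wide dialect: one row per trial, metadata columns plus fixed-length
# sample columns s0..s{n-1}. Long dialect: one row per sample with
# `sample_index` (0-based) and `value`. Both carry a `schema_version`
# column; round-trips are bit-exact for trace values.

EBC_SCHEMA_VERSION <- "1.0"

ebc_meta_cols <- c("schema_version", "mouse_id", "genotype", "day", "phase",
                   "block", "trial", "trial_type", "isi_ms", "fps",
                   "cs_onset_index")

#' Write a trial table to EBC-CSV
#'
#' @param trials Trial tibble with the metadata columns of
#'   `simulate_cohort()$trials` and the raw trace in list-column `samples`.
#' @param path Output file.
#' @param dialect `"wide"` (one row per trial) or `"long"` (one row per
#'   sample).
#' @return `path`, invisibly.
#' @export
write_ebc <- function(trials, path, dialect = c("wide", "long")) {
  dialect <- match.arg(dialect)
  meta <- dplyr::select(trials, -"samples")
  meta <- dplyr::mutate(meta, schema_version = EBC_SCHEMA_VERSION,
                        .before = 1)
  # trace values are serialized with 17 significant digits so that
  # write -> read round-trips are bit-exact
  if (dialect == "wide") {
    lens <- lengths(trials$samples)
    if (length(unique(lens)) != 1) {
      abort_bad_arg("Wide dialect requires equal-length traces.")
    }
    mat <- do.call(rbind, trials$samples)
    chr <- matrix(sprintf("%.17g", mat), nrow = nrow(mat))
    colnames(chr) <- paste0("s", seq_len(ncol(mat)) - 1L)
    out <- dplyr::bind_cols(meta, tibble::as_tibble(chr))
  } else {
    out <- meta
    out$samples <- trials$samples
    out <- tidyr::unnest_longer(out, "samples", values_to = "value",
                                indices_to = "sample_index")
    out$sample_index <- out$sample_index - 1L
    out$value <- sprintf("%.17g", out$value)
  }
  readr::write_csv(out, path)
  invisible(path)
}

#' Read an EBC-CSV trial table
#'
#' Detects the dialect from the columns, validates the schema (required
#' columns, unique (mouse, day, trial) keys, consistent per-trial sample
#' counts, declared genotype levels) and returns the same structure
#' [write_ebc()] consumes; `read_ebc(write_ebc(x))` is bit-exact for trace
#' values.
#'
#' @param path EBC-CSV file.
#' @param genotype_levels Declared genotype levels.
#' @return Trial tibble with list-column `samples`; attribute
#'   `schema_version`.
#' @export
read_ebc <- function(path, genotype_levels = c("WT", "NF1_HET")) {
  # everything is read as character and converted with base strtod, which
  # is correctly rounded (vroom's fast parser can be off by one ulp)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           .default = readr::col_character()))
  for (col in intersect(c("day", "block", "trial", "cs_onset_index"),
                        names(raw))) {
    raw[[col]] <- as.integer(raw[[col]])
  }
  for (col in intersect(c("isi_ms", "fps", "value"), names(raw))) {
    raw[[col]] <- as.numeric(raw[[col]])
  }
  if ("sample_index" %in% names(raw)) {
    raw$sample_index <- as.integer(raw$sample_index)
  }
  for (col in names(raw)[grepl("^s[0-9]+$", names(raw))]) {
    raw[[col]] <- as.numeric(raw[[col]])
  }
  long <- "sample_index" %in% names(raw)
  required <- if (long) c(ebc_meta_cols, "sample_index", "value") else ebc_meta_cols
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    rlang::abort(sprintf("EBC schema error: missing column(s) %s.",
                         paste(missing, collapse = ", ")),
                 class = "eyeblinkr_schema_error")
  }
  if (!long && !any(grepl("^s[0-9]+$", names(raw)))) {
    rlang::abort("EBC schema error: wide dialect needs sample columns s0, s1, ...",
                 class = "eyeblinkr_schema_error")
  }
  schema <- unique(raw$schema_version)

  if (long) {
    nested <- raw |>
      dplyr::arrange(.data$mouse_id, .data$day, .data$trial,
                     .data$sample_index) |>
      dplyr::group_by(dplyr::across(dplyr::all_of(setdiff(ebc_meta_cols,
                                                          "schema_version")))) |>
      dplyr::summarise(samples = list(.data$value), .groups = "drop")
    out <- nested
  } else {
    scols <- names(raw)[grepl("^s[0-9]+$", names(raw))]
    scols <- scols[order(as.integer(sub("^s", "", scols)))]
    mat <- as.matrix(raw[, scols])
    out <- raw[, setdiff(ebc_meta_cols, "schema_version")]
    out$samples <- lapply(seq_len(nrow(mat)), function(i) unname(mat[i, ]))
    out <- tibble::as_tibble(out)
  }

  key <- paste(out$mouse_id, out$day, out$trial, sep = "/")
  if (anyDuplicated(key)) {
    rlang::abort(sprintf("EBC schema error: duplicate trial key %s.",
                         key[duplicated(key)][1]),
                 class = "eyeblinkr_schema_error")
  }
  lens <- lengths(out$samples)
  if (length(unique(lens)) != 1) {
    off <- key[lens != lens[1]][1]
    rlang::abort(sprintf(
      "EBC schema error: inconsistent sample count for trial %s.", off),
      class = "eyeblinkr_schema_error")
  }
  badg <- setdiff(unique(out$genotype), genotype_levels)
  if (length(badg) > 0) {
    rlang::abort(sprintf("EBC schema error: undeclared genotype level '%s'.",
                         badg[1]),
                 class = "eyeblinkr_schema_error")
  }
  out$trial_type <- factor(out$trial_type,
                           levels = c("CS_ONLY", "US_ONLY", "PAIRED"))
  out <- dplyr::arrange(out, .data$mouse_id, .data$day, .data$trial)
  out <- out[, c(setdiff(ebc_meta_cols, "schema_version"), "samples")]
  attr(out, "schema_version") <- schema
  out
}
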