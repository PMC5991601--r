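# File formats: CSV for waveforms, EMG and feature tables; JSON for models,
# cross-validation reports and run configuration. All numeric columns are in
# SI units with unit suffixes in the column names (_s, _V, _A, _ohm, _F);
# distances are in millimetres (_mm), the convention of the application.

# Stable column order of the feature table.
FEATURE_COLUMNS <- c(
  "subject", "material", "distance_mm", "i_mt_a", "cmap_amp_v", "z_ohm",
  "t_l_s", "theta1", "theta2", "lin_r_squared", "rs_ohm", "rp_ohm", "cp_f",
  "tau_s", "tau_r_squared", "response", "at_lower_bound"
)

read_checked_csv <- function(path, required) {
  if (!file.exists(path)) nl_stop("io_failure", "file not found: %s", path)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) {
                   nl_stop("malformed_input", "cannot parse %s: %s", path,
                           conditionMessage(e))
                 })
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    nl_stop("malformed_input", "%s lacks required columns: %s", path,
            paste(missing_cols, collapse = ", "))
  }
  df
}

#' Read a pulse-response waveform from CSV
#'
#' Expects columns `time_s` and `voltage_V`, one pulse per file.
#'
#' @param path CSV file path.
#'
#' @return A validated data frame with `time_s`, `voltage_V`.
#' @export
read_waveform_table <- function(path) {
  df <- read_checked_csv(path, c("time_s", "voltage_V"))
  if (nrow(df) == 0) nl_stop("malformed_input", "%s has a header but no rows", path)
  for (col in c("time_s", "voltage_V")) {
    bad <- which(!is.finite(df[[col]]))
    if (length(bad) > 0) {
      nl_stop("malformed_input", "%s: non-numeric or missing %s at row %d",
              path, col, bad[1])
    }
  }
  nonmono <- which(diff(df$time_s) <= 0)
  if (length(nonmono) > 0) {
    nl_stop("malformed_input", "%s: time_s not strictly increasing at row %d",
            path, nonmono[1] + 1L)
  }
  df[, c("time_s", "voltage_V")]
}

#' Read a trigger-annotated EMG recording from CSV
#'
#' Expects columns `time_s`, `emg_V` and `trigger` (0/1); trigger onsets
#' (0 -> 1 transitions) become the stimulus instants.
#'
#' @param path CSV file path.
#'
#' @return An [emg_recording()].
#' @export
read_emg_table <- function(path) {
  df <- read_checked_csv(path, c("time_s", "emg_V", "trigger"))
  if (nrow(df) < 2) nl_stop("malformed_input", "%s: need at least 2 samples", path)
  if (!all(df$trigger %in% c(0, 1))) {
    nl_stop("malformed_input", "%s: trigger must be 0 or 1", path)
  }
  if (any(diff(df$time_s) <= 0)) {
    nl_stop("malformed_input", "%s: time_s not strictly increasing", path)
  }
  fs <- 1 / mean(diff(df$time_s))
  onsets <- which(diff(c(0, df$trigger)) == 1)
  if (length(onsets) == 0) nl_stop("malformed_input", "%s: no trigger onsets", path)
  emg_recording(df$emg_V, fs, df$time_s[onsets] - df$time_s[1])
}

#' Write feature records to CSV
#'
#' Columns follow the stable documented order; missing columns are filled
#' with `NA` so that write-then-read round-trips record sets field-wise.
#'
#' @param records Data frame of feature records.
#' @param path Output CSV path.
#'
#' @return The path, invisibly.
#' @export
write_feature_table <- function(records, path) {
  records <- as.data.frame(records)
  if (nrow(records) == 0) {
    nl_warn("empty_output", "writing header-only feature table to %s", path)
  }
  for (col in setdiff(FEATURE_COLUMNS, names(records))) records[[col]] <- NA
  ok <- tryCatch({
    utils::write.csv(records[, FEATURE_COLUMNS], path, row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) nl_stop("io_failure", "cannot write %s: %s", path,
                           conditionMessage(ok))
  invisible(path)
}

#' Read feature records from CSV
#'
#' @param path CSV path written by [write_feature_table()] (or assembled by
#'   hand with the same columns).
#'
#' @return A data frame of feature records.
#' @export
read_feature_table <- function(path) {
  df <- read_checked_csv(path, c("distance_mm", "i_mt_a", "cmap_amp_v",
                                 "z_ohm", "t_l_s"))
  df
}

#' Serialize a fitted distance model to JSON
#'
#' Stores the variant, coefficients, internal feature scaling, feature
#' options, fit diagnostics and package version; [read_model_json()]
#' restores an equivalent model.
#'
#' @param model A `nerve_model`.
#' @param path Output JSON path.
#'
#' @return The path, invisibly.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "nerve_model"))
  obj <- list(
    format = "nerveloc_model",
    package_version = as.character(utils::packageVersion("nerveloc")),
    variant = model$variant,
    options = unclass(model$options),
    coefficients = model$coefficients,
    coefficients_raw = model$coefficients_raw,
    scaling = model$scaling,
    sse = model$sse, converged = model$converged,
    n_obs = model$n_obs, seed = model$seed
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Restore a distance model written by [write_model_json()]
#'
#' @param path JSON path.
#'
#' @return A `nerve_model`.
#' @export
read_model_json <- function(path) {
  if (!file.exists(path)) nl_stop("io_failure", "file not found: %s", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "nerveloc_model")) {
    nl_stop("malformed_input", "%s is not a nerveloc model file", path)
  }
  opts <- do.call(feature_options, obj$options)
  relist_scaling <- function(s) {
    lapply(s, function(p) list(center = unlist(p$center), scale = unlist(p$scale)))
  }
  structure(
    list(
      variant = obj$variant, options = opts,
      scaling = relist_scaling(obj$scaling),
      coefficients = obj$coefficients,
      coefficients_raw = obj$coefficients_raw,
      sse = obj$sse, converged = obj$converged,
      n_obs = obj$n_obs, seed = obj$seed
    ),
    class = "nerve_model"
  )
}

#' Serialize a cross-validation report to JSON
#'
#' @param report A `cv_report`.
#' @param path Output JSON path.
#'
#' @return The path, invisibly.
#' @export
write_cv_report_json <- function(report, path) {
  stopifnot(inherits(report, "cv_report"))
  jsonlite::write_json(c(list(format = "nerveloc_cv_report"), unclass(report)),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

# Known run-config keys and their defaults (the CLI's file-based settings).
RUN_CONFIG_DEFAULTS <- list(
  impedance_freq = 5e5,
  window = 0.05,
  detection_mult = 5,
  variant = "base",
  latency_term = "ratio",
  mt_rp_term = "ratio",
  rs_cp_term = "ratio",
  cmap_level = 1,
  cv_k = 10L,
  seed = 1L
)

#' Read a run configuration from JSON
#'
#' Unknown keys are rejected; known keys fall back to documented defaults.
#'
#' @param path JSON path, or `NULL` for all defaults.
#'
#' @return A named list of settings.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- RUN_CONFIG_DEFAULTS
  if (!is.null(path)) {
    if (!file.exists(path)) nl_stop("io_failure", "file not found: %s", path)
    user <- jsonlite::read_json(path, simplifyVector = TRUE)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown) > 0) {
      nl_stop("malformed_input", "unknown config keys: %s",
              paste(unknown, collapse = ", "))
    }
    cfg[names(user)] <- user
  }
  cfg
}
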