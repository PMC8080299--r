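#' Write an epoch series to CSV
#'
#' Two columns, `timestamp` (ISO-8601 UTC) and `label`, at 30-s cadence;
#' `.gz` paths are compressed transparently.
#'
#' @param series An [epoch_series()].
#' @param path Output path (`.csv` or `.csv.gz`).
#' @return `path`, invisibly.
#' @export
write_epoch_series <- function(series, path) {
  df <- tibble::tibble(
    timestamp = format(epoch_times(series), "%Y-%m-%dT%H:%M:%SZ"),
    label = series$labels
  )
  readr::write_csv(df, path)
  invisible(path)
}

#' Read an epoch series from CSV
#'
#' Accepts the format written by [write_epoch_series()] (also tolerating an
#' extra leading header line, as some toolkit exports carry). Unknown labels
#' are rejected; skipped epochs (cadence gaps) are restored as `missing`
#' with a message; non-monotone timestamps are an error.
#'
#' @param path Input path (`.csv` or `.csv.gz`).
#' @param participant_id Id to attach (default: file stem).
#' @return An [epoch_series()].
#' @export
read_epoch_series <- function(path, participant_id = NULL) {
  if (is.null(participant_id)) {
    participant_id <- sub("\\.csv(\\.gz)?$", "", basename(path))
  }
  first <- readLines(path, n = 1)
  skip <- if (!grepl("timestamp", first, fixed = TRUE)) 1L else 0L
  df <- readr::read_csv(path, skip = skip, show_col_types = FALSE,
                        col_types = readr::cols(.default = "c"))
  if (!all(c("timestamp", "label") %in% names(df))) {
    names(df)[1:2] <- c("timestamp", "label")
  }
  ts <- lubridate::ymd_hms(df$timestamp, tz = "UTC", quiet = TRUE)
  if (anyNA(ts)) stop("read_epoch_series: malformed timestamp(s) in ", path)
  step <- as.numeric(diff(ts), units = "secs")
  if (any(step <= 0)) stop("read_epoch_series: non-monotone timestamps in ", path)
  n_total <- as.integer(round(
    as.numeric(difftime(ts[length(ts)], ts[1], units = "secs")) / EPOCH_SECONDS
  )) + 1L
  labels <- rep(missing_label(), n_total)
  pos <- as.integer(round(
    as.numeric(difftime(ts, ts[1], units = "secs")) / EPOCH_SECONDS
  )) + 1L
  if (anyDuplicated(pos)) stop("read_epoch_series: duplicate epochs in ", path)
  labels[pos] <- df$label
  n_filled <- n_total - length(pos)
  if (n_filled > 0) {
    message("read_epoch_series: restored ", n_filled,
            " skipped epoch(s) as missing")
  }
  epoch_series(labels, ts[1], participant_id)
}

#' Write all traces of a population as one long CSV
#'
#' Columns `participant_id`, `timestamp`, `label`; use a `.csv.gz` path for
#' compression.
#'
#' @param traces Named list of [epoch_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_traces_long <- function(traces, path) {
  long <- purrr::map_dfr(traces, function(s) {
    tibble::tibble(
      participant_id = s$participant_id,
      timestamp = format(epoch_times(s), "%Y-%m-%dT%H:%M:%SZ"),
      label = s$labels
    )
  })
  readr::write_csv(long, path)
  invisible(path)
}

#' @rdname write_traces_long
#' @param path Long CSV path to read back.
#' @return For the reader: a named list of [epoch_series()].
#' @export
read_traces_long <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = "c"))
  split_df <- split(df, df$participant_id)
  lapply(split_df, function(d) {
    epoch_series(d$label, lubridate::ymd_hms(d$timestamp[1], tz = "UTC"),
                 d$participant_id[1])
  })
}

#' Default run configuration
#'
#' All stage parameters of [run_pipeline()] in one serializable list:
#' population sizes and seed, sleep-window gap tolerance, wear-QC hours,
#' EHR scoring window, band thresholds, imputation k, CV folds, holdout
#' fraction and the grid selection.
#'
#' @param ... Overrides of any default field.
#' @return A named list of class `run_config`.
#' @export
default_run_config <- function(...) {
  cfg <- list(
    n_t2d = 60, n_control = 120, n_impaired_control = 30,
    days = 7, seed = 20190304,
    gap_tolerance_epochs = 60, qc_hours = 72,
    window_before_months = 6, window_after_months = 1,
    band_thresholds = c(0.5, 1.5),
    impute_k = 5, folds = 10, train_fraction = 0.8,
    algorithms = ALGORITHMS, feature_sets = FEATURE_SETS,
    mode = "cv", write_traces = FALSE
  )
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration (YAML)
#'
#' @param path YAML file path.
#' @return [read_run_config()]: a `run_config` list (defaults filled in).
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(default_run_config, raw)
}

#' @rdname read_run_config
#' @param config A `run_config` list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
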