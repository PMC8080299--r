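#' Per-day bout feature matrix
#'
#' Computes the 5 (activity) x 4 (phase) x 3 (statistic) bout features for
#' one noon-to-noon day. Bouts crossing a phase boundary are split; each
#' fragment counts as a bout in its own phase, which keeps the conservation
#' identity `n_bouts * mean_len = activity epochs in phase` exact.
#' Percentages are phase-relative with non-missing epochs as denominator;
#' a phase whose epochs are all missing gets `NA` percentages for the day.
#' Cells with no bouts report count 0, percentage 0 and mean length 0.
#'
#' @param labels Character vector of one day's epoch labels.
#' @param minutes Minutes-of-day of each epoch (same length).
#' @param phases A [partition_day()] result.
#' @return Tibble with 20 rows: `activity`, `phase`, `n_bouts`, `pct_time`,
#'   `mean_len`.
#' @export
compute_daily_features <- function(labels, minutes, phases) {
  stopifnot(length(labels) == length(minutes))
  phase <- phase_of_minute(phases, minutes)
  grid <- expand.grid(
    activity = activity_levels(), phase = phase_levels(),
    stringsAsFactors = FALSE
  )
  if (length(labels) == 0) {
    return(tibble::as_tibble(cbind(
      grid, n_bouts = 0, pct_time = NA_real_, mean_len = 0
    )))
  }
  ## a run ends where the label changes or the phase changes: bouts are
  ## split at phase boundaries, each fragment counting in its own phase
  new_run <- c(TRUE, labels[-1] != labels[-length(labels)] |
                 phase[-1] != phase[-length(phase)])
  run_id <- cumsum(new_run)
  runs <- tibble::tibble(
    activity = tapply(labels, run_id, `[`, 1),
    phase = tapply(phase, run_id, `[`, 1),
    length = as.integer(tapply(labels, run_id, length))
  )
  runs <- runs[runs$activity != missing_label(), , drop = FALSE]

  denom <- tapply(labels != missing_label(), phase, sum)
  denom_all <- stats::setNames(rep(0L, 4), phase_levels())
  denom_all[names(denom)] <- as.integer(denom)

  agg <- dplyr::summarise(
    dplyr::group_by(runs, .data$activity, .data$phase),
    n_bouts = dplyr::n(),
    total = sum(.data$length),
    .groups = "drop"
  )
  out <- dplyr::left_join(tibble::as_tibble(grid), agg,
                          by = c("activity", "phase"))
  out$n_bouts[is.na(out$n_bouts)] <- 0L
  out$total[is.na(out$total)] <- 0L
  d <- unname(denom_all[out$phase])
  out$pct_time <- ifelse(d > 0, 100 * out$total / d, NA_real_)
  out$mean_len <- ifelse(out$n_bouts > 0, out$total / out$n_bouts, 0)
  out$total <- NULL
  out
}

#' Average daily feature matrices into the participant feature vector
#'
#' Element-wise arithmetic mean over valid wear days (undefined percentages
#' from all-missing phases are skipped pairwise). The result is the
#' participant's 60-dimensional bout feature vector in [feature_names()]
#' order.
#'
#' @param daily_list List of [compute_daily_features()] tibbles (>= 1).
#' @return Named numeric vector of length 60.
#' @export
average_features <- function(daily_list) {
  if (length(daily_list) == 0) stop("average_features: zero valid days")
  long <- dplyr::bind_rows(daily_list, .id = "day")
  avg <- dplyr::summarise(
    dplyr::group_by(long, .data$activity, .data$phase),
    n_bouts = mean(.data$n_bouts, na.rm = TRUE),
    pct_time = mean(.data$pct_time, na.rm = TRUE),
    mean_len = mean(.data$mean_len, na.rm = TRUE),
    .groups = "drop"
  )
  avg$pct_time[is.nan(avg$pct_time)] <- 0
  wide <- tidyr::pivot_longer(avg, c("n_bouts", "pct_time", "mean_len"),
                              names_to = "stat")
  key <- paste(wide$activity, wide$phase, wide$stat, sep = "_")
  out <- stats::setNames(wide$value, key)[feature_names()]
  stopifnot(length(out) == 60L, !anyNA(names(out)))
  out
}

#' Wear-time quality control
#'
#' A trace passes if it holds at least `min_hours` of non-missing epochs and
#' at least one valid day (a day with any non-missing epoch) in each half of
#' the wear period. Both bounds are inclusive.
#'
#' @param series An [epoch_series()].
#' @param min_hours Minimum non-missing wear, hours (default 72).
#' @return List with `pass` (logical) and `reason` (`NA` if passed).
#' @export
wear_time_qc <- function(series, min_hours = 72) {
  nonmiss <- series$labels != missing_label()
  hours <- sum(nonmiss) / EPOCHS_PER_MINUTE / 60
  if (hours < min_hours) {
    return(list(pass = FALSE, reason = "insufficient-wear"))
  }
  day_id <- analysis_day_index(series)
  valid_days <- sort(unique(day_id[nonmiss]))
  n_days <- max(day_id)
  first_half <- any(valid_days <= ceiling(n_days / 2))
  second_half <- any(valid_days > floor(n_days / 2))
  if (!first_half || !second_half) {
    return(list(pass = FALSE, reason = "wear-not-spread"))
  }
  list(pass = TRUE, reason = NA_character_)
}

#' Extract the bout feature vector for one participant
#'
#' Runs the full per-participant hierarchy: sleep-window detection across
#' noon-to-noon days, day partition into four phases, per-day 5x4x3 bout
#' feature matrices, and the 7-day element-wise average.
#'
#' @param series An [epoch_series()].
#' @param gap_tolerance_epochs Sleep-window merge tolerance
#'   ([detect_sleep_window()]).
#' @param keep_daily Keep the per-day long table (for distribution reports).
#' @return List with `features` (named length-60 vector), `window`
#'   (`sleep_window`), `phases` (`day_phases`), `n_valid_days`, and `daily`
#'   (long tibble, or `NULL`). Returns `NULL` if no day has a detectable
#'   sleep window.
#' @export
extract_features <- function(series, gap_tolerance_epochs = 60,
                             keep_daily = FALSE) {
  window <- detect_sleep_window(series, gap_tolerance_epochs)
  if (window$n_valid == 0) return(NULL)
  phases <- partition_day(window)
  day_id <- analysis_day_index(series)
  mins <- epoch_minute_of_day(series)
  daily_list <- list()
  for (d in sort(unique(day_id))) {
    idx <- which(day_id == d)
    if (!any(series$labels[idx] != missing_label())) next
    daily_list[[as.character(d)]] <-
      compute_daily_features(series$labels[idx], mins[idx], phases)
  }
  feats <- average_features(daily_list)
  list(
    features = feats,
    window = window,
    phases = phases,
    n_valid_days = length(daily_list),
    daily = if (keep_daily) dplyr::bind_rows(daily_list, .id = "day") else NULL
  )
}

#' Bout feature table for a set of traces
#'
#' Applies [wear_time_qc()] and [extract_features()] to each trace and
#' assembles the wide participant-by-feature table.
#'
#' @param traces Named list of [epoch_series()] (names = participant ids).
#' @param gap_tolerance_epochs Sleep-window merge tolerance.
#' @param qc_hours Minimum non-missing wear for QC, hours.
#' @return List with `features` (tibble: `participant_id` + 60 feature
#'   columns + `sleep_onset`, `sleep_offset`, `wake_min`), and `qc` (tibble:
#'   `participant_id`, `pass`, `reason`).
#' @export
features_table <- function(traces, gap_tolerance_epochs = 60, qc_hours = 72) {
  qc <- purrr::map_dfr(traces, function(s) {
    r <- wear_time_qc(s, qc_hours)
    tibble::tibble(participant_id = s$participant_id, pass = r$pass,
                   reason = r$reason)
  })
  rows <- purrr::compact(purrr::map(traces[qc$pass], function(s) {
      fx <- extract_features(s, gap_tolerance_epochs)
      if (is.null(fx)) return(NULL)
      row <- tibble::as_tibble(as.list(fx$features))
      row$participant_id <- s$participant_id
      row$sleep_onset <- fx$window$onset
      row$sleep_offset <- fx$window$offset
      row$wake_min <- sum(fx$phases$duration_min[fx$phases$phase != "sleep"])
      row
    }))
  features <- dplyr::bind_rows(rows)
  if (nrow(features) > 0) {
    features <- features[, c("participant_id", feature_names(),
                             "sleep_onset", "sleep_offset", "wake_min")]
  }
  list(features = features, qc = qc)
}

#' Aggregate phase-relative percentages to 24-h occupancy
#'
#' Converts the per-phase percentage-time features of a participant row into
#' the fraction of the 24-hour day spent in each activity class, weighting
#' each phase by its duration. This is the aggregate the population activity
#' mix (e.g. 42% sedentary, 38% asleep) is stated in.
#'
#' @param features_row One row of the [features_table()] feature tibble (it
#'   carries the sleep window columns), or the whole tibble.
#' @return Tibble with `participant_id`, `activity`, `occupancy_pct`.
#' @export
occupancy_24h <- function(features_row) {
  f <- features_row
  wake <- f$wake_min
  sleep_dur <- MINUTES_PER_DAY - wake
  out <- purrr::map_dfr(activity_levels(), function(a) {
    pct <- f[[paste0(a, "_sleep_pct_time")]] * sleep_dur / MINUTES_PER_DAY
    for (ph in wake_phases()) {
      pct <- pct + f[[paste0(a, "_", ph, "_pct_time")]] *
        (wake / 3) / MINUTES_PER_DAY
    }
    tibble::tibble(participant_id = f$participant_id, activity = a,
                   occupancy_pct = pct)
  })
  dplyr::arrange(out, .data$participant_id)
}
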