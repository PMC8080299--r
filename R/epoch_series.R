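#' Construct an epoch series
#'
#' An `epoch_series` is one participant's wear-time sequence of 30-second
#' activity-label epochs with an absolute start timestamp. Labels are drawn
#' from the six-symbol alphabet: the five activity classes plus `missing`.
#'
#' @param labels Character vector of epoch labels.
#' @param start `POSIXct` timestamp of the first epoch (UTC).
#' @param participant_id Participant identifier (scalar character).
#' @return An object of class `epoch_series`: a list with elements
#'   `participant_id`, `start`, `labels` and `epoch_seconds`.
#' @export
epoch_series <- function(labels, start, participant_id = "p1") {
  stopifnot(is.character(labels), length(participant_id) == 1L)
  start <- lubridate::as_datetime(start, tz = "UTC")
  if (is.na(start)) stop("epoch_series: unparseable start timestamp")
  bad <- setdiff(unique(labels), c(activity_levels(), missing_label()))
  if (length(bad) > 0) {
    stop("epoch_series: unknown label(s): ", paste(bad, collapse = ", "))
  }
  structure(
    list(
      participant_id = as.character(participant_id),
      start = start,
      labels = labels,
      epoch_seconds = EPOCH_SECONDS
    ),
    class = "epoch_series"
  )
}

#' @export
print.epoch_series <- function(x, ...) {
  n <- length(x$labels)
  cat(sprintf(
    "<epoch_series> participant %s: %d epochs (%.2f days) from %s UTC\n",
    x$participant_id, n, n / EPOCHS_PER_DAY,
    format(x$start, "%Y-%m-%d %H:%M:%S")
  ))
  occ <- table(factor(x$labels, levels = c(activity_levels(), missing_label())))
  print(round(100 * occ / n, 1))
  invisible(x)
}

#' @export
length.epoch_series <- function(x) length(x$labels)

#' Epoch timestamps of a series
#'
#' @param series An `epoch_series`.
#' @return `POSIXct` vector, one timestamp per epoch (30-s cadence).
#' @export
epoch_times <- function(series) {
  series$start + (seq_along(series$labels) - 1L) * EPOCH_SECONDS
}

## Minute-of-day (0 <= m < 1440, fractional) for each epoch.
epoch_minute_of_day <- function(series) {
  t <- epoch_times(series)
  lubridate::hour(t) * 60 + lubridate::minute(t) + lubridate::second(t) / 60
}

#' Convert an epoch series to a tibble
#'
#' @param x An `epoch_series`.
#' @param ... Unused.
#' @return Tibble with columns `participant_id`, `timestamp`, `label`.
#' @importFrom tibble as_tibble
#' @method as_tibble epoch_series
#' @export
as_tibble.epoch_series <- function(x, ...) {
  tibble::tibble(
    participant_id = x$participant_id,
    timestamp = epoch_times(x),
    label = x$labels
  )
}

## Index (1-based) of the first epoch at or after local noon, plus the
## noon-to-noon analysis-day id of every epoch. Analysis days anchor at 12:00
## so a nocturnal sleep block is never split at midnight.
analysis_day_index <- function(series) {
  mins <- epoch_minute_of_day(series)
  ## minutes since the most recent noon, in [0, 1440)
  since_noon <- (mins - 720) %% MINUTES_PER_DAY
  t <- epoch_times(series)
  noon_anchor <- t - since_noon * 60
  day_id <- as.integer(round(
    as.numeric(difftime(noon_anchor, noon_anchor[1], units = "days"))
  )) + 1L
  day_id
}
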