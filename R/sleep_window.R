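## Circular mean of times-of-day (minutes in [0, 1440)), via unit vectors.
circular_mean_minutes <- function(m) {
  theta <- m / MINUTES_PER_DAY * 2 * pi
  mu <- atan2(mean(sin(theta)), mean(cos(theta)))
  out <- (mu / (2 * pi) * MINUTES_PER_DAY) %% MINUTES_PER_DAY
  if (MINUTES_PER_DAY - out < 1e-9) out <- 0  # fp wrap-around at midnight
  out
}

#' Detect a participant's personalized sleep window
#'
#' For each noon-to-noon 24-h analysis day, sleep bouts separated by
#' non-sleep gaps of at most `gap_tolerance_epochs` are chained into
#' "nearly continuous" candidate blocks; the block containing the most sleep
#' epochs is that day's night-sleep window (ties broken by earliest onset).
#' The participant-level window is the circular (unit-vector) mean of the
#' daily onsets and offsets. Days without any sleep epoch are flagged and
#' excluded from the average.
#'
#' @param series An [epoch_series()].
#' @param gap_tolerance_epochs Maximum non-sleep gap (epochs) bridged when
#'   chaining sleep bouts; default 60 epochs = 30 minutes.
#' @return Object of class `sleep_window`: list with `onset` and `offset`
#'   (participant-level minutes from midnight), `daily` (per-day tibble with
#'   `day`, `onset`, `offset`, `sleep_epochs`, `valid`) and `n_valid`.
#'   If every day is flagged, `onset`/`offset` are `NA` and `n_valid` is 0.
#' @export
detect_sleep_window <- function(series, gap_tolerance_epochs = 60) {
  stopifnot(inherits(series, "epoch_series"))
  day_id <- analysis_day_index(series)
  mins <- epoch_minute_of_day(series)
  days <- sort(unique(day_id))

  daily <- lapply(days, function(d) {
    idx <- which(day_id == d)
    blk <- best_sleep_block(series$labels[idx], gap_tolerance_epochs)
    if (is.null(blk)) {
      return(tibble::tibble(day = d, onset = NA_real_, offset = NA_real_,
                            sleep_epochs = 0L, valid = FALSE))
    }
    onset_min <- mins[idx[blk$start]]
    ## offset is the minute just after the last sleep epoch (half-open)
    offset_min <- (mins[idx[blk$end]] + 1 / EPOCHS_PER_MINUTE) %% MINUTES_PER_DAY
    tibble::tibble(day = d, onset = onset_min, offset = offset_min,
                   sleep_epochs = blk$sleep_epochs, valid = TRUE)
  })
  daily <- dplyr::bind_rows(daily)
  ok <- daily$valid
  out <- list(
    onset = if (any(ok)) circular_mean_minutes(daily$onset[ok]) else NA_real_,
    offset = if (any(ok)) circular_mean_minutes(daily$offset[ok]) else NA_real_,
    daily = daily,
    n_valid = sum(ok),
    gap_tolerance_epochs = gap_tolerance_epochs
  )
  class(out) <- "sleep_window"
  out
}

#' @export
print.sleep_window <- function(x, ...) {
  fmt <- function(m) {
    if (is.na(m)) return("NA")
    sprintf("%02d:%02d", floor(m / 60) %% 24, floor(m %% 60))
  }
  cat(sprintf("<sleep_window> onset %s, offset %s (%d valid day%s)\n",
              fmt(x$onset), fmt(x$offset), x$n_valid,
              if (x$n_valid == 1) "" else "s"))
  invisible(x)
}

## Best nearly-continuous sleep block within one analysis day.
## Chains of sleep bouts whose internal non-sleep gaps are all <= tol are
## scored by total sleep epochs; the maximal chains found greedily dominate
## every sub-chain, so greedy chaining is equivalent to brute force over all
## candidate (i, j) bout ranges. Ties go to the earliest-starting chain.
best_sleep_block <- function(labels, tol) {
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sl <- which(r$values == "sleep")
  if (length(sl) == 0) return(NULL)
  ## gap (epochs) between consecutive sleep bouts
  chain <- cumsum(c(1L, diff(starts[sl]) - r$lengths[sl[-length(sl)]] > tol))
  agg <- vapply(split(sl, chain), function(ix) {
    c(start = starts[ix[1]], end = ends[ix[length(ix)]],
      sleep_epochs = sum(r$lengths[ix]))
  }, numeric(3))
  best <- which.max(agg["sleep_epochs", ])  # which.max takes the first tie
  list(start = as.integer(agg["start", best]),
       end = as.integer(agg["end", best]),
       sleep_epochs = as.integer(agg["sleep_epochs", best]))
}
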