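#' Partition the 24-h day around a sleep window
#'
#' The wake interval (sleep offset to next sleep onset, circular) is split
#' into three contiguous equal-duration phases — morning, afternoon,
#' evening — which together with the sleep interval tile the 1440-minute
#' day. All intervals are half-open `[start, end)` on the circular
#' time-of-day axis.
#'
#' @param window A [detect_sleep_window()] result, or any list with numeric
#'   `onset` and `offset` minutes-of-day.
#' @return Object of class `day_phases`: tibble with columns `phase`,
#'   `start_min`, `end_min` (mod 1440) and `duration_min`.
#' @export
partition_day <- function(window) {
  onset <- window$onset
  offset <- window$offset
  if (is.na(onset) || is.na(offset)) {
    stop("partition_day: sleep window has no valid onset/offset")
  }
  wake <- (onset - offset) %% MINUTES_PER_DAY
  if (wake <= 0) stop("partition_day: sleep window spans the whole day")
  third <- wake / 3
  starts <- (offset + c(0, third, 2 * third)) %% MINUTES_PER_DAY
  phases <- tibble::tibble(
    phase = phase_levels(),
    start_min = c(onset, starts),
    end_min = c(offset, (starts + third) %% MINUTES_PER_DAY),
    duration_min = c(MINUTES_PER_DAY - wake, rep(third, 3))
  )
  structure(phases, class = c("day_phases", class(phases)))
}

#' Map times-of-day to day phases
#'
#' @param phases A [partition_day()] result.
#' @param minutes Numeric vector of minutes-of-day in `[0, 1440)`.
#' @return Character vector of phase labels, same length as `minutes`.
#' @export
phase_of_minute <- function(phases, minutes) {
  out <- rep(NA_character_, length(minutes))
  for (eps in c(-1e-9, 1e-6)) {  # strict pass, then fp-tolerant mop-up
    for (i in seq_len(nrow(phases))) {
      rel <- (minutes - phases$start_min[i]) %% MINUTES_PER_DAY
      hit <- rel < phases$duration_min[i] + eps
      out[is.na(out) & hit] <- phases$phase[i]
    }
    if (!anyNA(out)) break
  }
  out
}
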