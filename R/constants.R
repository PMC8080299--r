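#' @keywords internal
#' @importFrom rlang .data
#' @importFrom stats rnorm runif rpois rgeom rnbinom
"_PACKAGE"

## Epoch geometry: labels arrive at a fixed 30-second cadence, so a 24-h day
## holds exactly 2880 epochs and one minute holds 2.
EPOCH_SECONDS <- 30L
EPOCHS_PER_MINUTE <- 2L
EPOCHS_PER_DAY <- 2880L
MINUTES_PER_DAY <- 1440L

#' Activity label alphabet
#'
#' The five activity classes emitted by the epoch-level activity classifier,
#' plus the `missing` marker used for non-wear / dropped epochs.
#'
#' @return Character vector of the five activity labels (without `missing`).
#' @export
activity_levels <- function() {
  c("sedentary", "moderate", "walking", "sleep", "light_tasks")
}

#' @rdname activity_levels
#' @export
missing_label <- function() "missing"

wake_levels <- function() setdiff(activity_levels(), "sleep")

#' Day-phase labels
#'
#' The four phases of the personalized 24-h day: the detected sleep window
#' plus three equal-duration wake phases.
#'
#' @return Character vector `c("sleep", "morning", "afternoon", "evening")`.
#' @export
phase_levels <- function() c("sleep", "morning", "afternoon", "evening")

wake_phases <- function() c("morning", "afternoon", "evening")

bout_stats <- function() c("n_bouts", "pct_time", "mean_len")

#' Activity class table with MET constants
#'
#' Metabolic-equivalent-of-task (MET) constants for the five activity classes:
#' sedentary 1.5, moderate 4.9, walking 3.2, sleep 1.0, light tasks 2.2.
#' Stored for reference and downstream energy-expenditure work; the bout
#' feature pipeline itself is MET-free.
#'
#' @return A tibble with columns `activity` and `met`.
#' @export
activity_classes <- function() {
  tibble::tibble(
    activity = activity_levels(),
    met = c(1.5, 4.9, 3.2, 1.0, 2.2)
  )
}

#' Canonical bout-feature names
#'
#' The 60 feature names of the bout feature matrix, in fixed order:
#' activity (5) x phase (4) x statistic (3), named
#' `<activity>_<phase>_<stat>`.
#'
#' @return Character vector of length 60.
#' @export
feature_names <- function() {
  grid <- expand.grid(
    stat = bout_stats(),
    phase = phase_levels(),
    activity = activity_levels(),
    stringsAsFactors = FALSE
  )
  paste(grid$activity, grid$phase, grid$stat, sep = "_")
}
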