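#' Extract activity bouts from an epoch series
#'
#' A bout is a maximal run of consecutive epochs carrying the same activity
#' label. Runs of `missing` epochs terminate bouts and are excluded from the
#' result.
#'
#' @param series An [epoch_series()], or a bare character vector of labels.
#' @return Tibble with columns `activity`, `start` (0-based epoch offset) and
#'   `length` (epochs), in trace order.
#' @export
extract_bouts <- function(series) {
  labels <- if (inherits(series, "epoch_series")) series$labels else series
  bad <- setdiff(unique(labels), c(activity_levels(), missing_label()))
  if (length(bad) > 0) stop("extract_bouts: unknown label(s): ",
                            paste(bad, collapse = ", "))
  if (length(labels) == 0) {
    return(tibble::tibble(activity = character(), start = integer(),
                          length = integer()))
  }
  r <- rle(labels)
  start <- cumsum(c(0L, r$lengths[-length(r$lengths)]))
  keep <- r$values != missing_label()
  tibble::tibble(
    activity = r$values[keep],
    start = start[keep],
    length = r$lengths[keep]
  )
}
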