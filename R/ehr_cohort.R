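#' Packaged severity map (synthetic stand-in)
#'
#' Maps condition classes to activity-impairment severity scores on the
#' {0, 1, 2} scale (0 = no impairment expected, 2 = high impairment), and
#' flags the class used for incident-T2D codes. Real primary-care code
#' catalogs are licensed and out of scope, so the map ships as a small
#' synthetic catalog with Read-v2-like tokens; both the class list and the
#' scores are configurable.
#'
#' @return Tibble with columns `class`, `code`, `severity`, `t2d_code`.
#' @export
default_severity_map <- function() {
  path <- system.file("extdata", "severity_map_synthetic.csv",
                      package = "boutwise")
  if (nzchar(path)) {
    readr::read_csv(path, show_col_types = FALSE,
                    col_types = readr::cols(
                      class = "c", code = "c", severity = "i", t2d_code = "l"
                    ))
  } else {
    ## fallback when running from a source checkout
    severity_map_builtin()
  }
}

severity_map_builtin <- function() {
  tibble::tribble(
    ~class,               ~code,    ~severity, ~t2d_code,
    "routine_checkup",    "68B..",  0L, FALSE,
    "eczema",             "M111.",  0L, FALSE,
    "hypertension",       "G20..",  0L, FALSE,
    "hayfever",           "H170.",  0L, FALSE,
    "back_pain",          "N142.",  1L, FALSE,
    "osteoarthritis",     "N05..",  1L, FALSE,
    "depression",         "E112.",  1L, FALSE,
    "angina",             "G33..",  1L, FALSE,
    "hip_fracture",       "S30..",  2L, FALSE,
    "stroke",             "G66..",  2L, FALSE,
    "copd_severe",        "H3122",  2L, FALSE,
    "severe_arthritis",   "N040.",  2L, FALSE,
    "t2d_incident",       "C10F.",  0L, TRUE
  )
}

#' Identify T2D-positive participants
#'
#' A participant is T2D-positive if they self-reported a diabetes diagnosis
#' at the assessment centre (unless excluded), or if an incident T2D code is
#' dated after the baseline assessment and before accelerometer wear start.
#' Self-reported cases taking insulin within their first year *and* aged
#' under 35 at diagnosis are excluded (likely type 1 / monogenic diabetes).
#'
#' @param selfreport Tibble with `participant_id`, `diabetes_diagnosed`,
#'   `insulin_first_year`, `age_at_diagnosis`, `assessment_date`.
#' @param events EHR tibble (`participant_id`, `date`, `class`).
#' @param wear Tibble with `participant_id`, `wear_start`.
#' @param severity_map Map whose `t2d_code` flag marks incidence classes.
#' @return Tibble with `participant_id` and `t2d_status` in
#'   `{"positive", "negative", "excluded", "unresolvable"}`.
#' @export
identify_t2d <- function(selfreport, events, wear,
                         severity_map = default_severity_map()) {
  t2d_classes <- severity_map$class[severity_map$t2d_code]
  sr <- dplyr::left_join(selfreport, wear[, c("participant_id", "wear_start")],
                         by = "participant_id")
  incident_ids <- unique(
    dplyr::inner_join(
      dplyr::filter(events, .data$class %in% t2d_classes),
      sr[, c("participant_id", "assessment_date", "wear_start")],
      by = "participant_id"
    ) |>
      dplyr::filter(.data$date > .data$assessment_date,
                    .data$date < .data$wear_start) |>
      dplyr::pull("participant_id")
  )
  status <- vapply(seq_len(nrow(sr)), function(i) {
    if (is.na(sr$assessment_date[i]) || is.na(sr$wear_start[i])) {
      return("unresolvable")
    }
    if (isTRUE(sr$diabetes_diagnosed[i])) {
      excl <- isTRUE(sr$insulin_first_year[i]) &&
        !is.na(sr$age_at_diagnosis[i]) && sr$age_at_diagnosis[i] < 35
      return(if (excl) "excluded" else "positive")
    }
    if (sr$participant_id[i] %in% incident_ids) return("positive")
    "negative"
  }, character(1))
  tibble::tibble(participant_id = sr$participant_id, t2d_status = status)
}

#' EHR activity-impairment severity score
#'
#' The mean severity of a participant's EHR events dated inside the scoring
#' window, which runs from 6 months before wear start to 1 month after wear
#' end (new conditions may be recorded with delay). No in-window events
#' scores 0. Unmapped condition classes score 0 with a warning.
#'
#' @param events EHR tibble for one or many participants
#'   (`participant_id`, `date`, `class`).
#' @param wear Tibble with `participant_id`, `wear_start`, `wear_end`.
#' @param severity_map [default_severity_map()]-shaped tibble.
#' @param window_before_months,window_after_months Scoring window bounds.
#' @return Tibble with `participant_id`, `score`, `n_events` (in-window),
#'   `band` (see [assign_band()]). Participants present in `wear` but
#'   without events score 0.
#' @export
severity_score <- function(events, wear,
                           severity_map = default_severity_map(),
                           window_before_months = 6,
                           window_after_months = 1) {
  if (window_before_months < 0 || window_after_months < 0) {
    stop("severity_score: window months must be >= 0")
  }
  unmapped <- setdiff(unique(events$class), severity_map$class)
  if (length(unmapped) > 0) {
    warning("severity_score: unmapped condition class(es) score 0: ",
            paste(unmapped, collapse = ", "))
  }
  sev <- stats::setNames(severity_map$severity, severity_map$class)
  w <- wear
  w$w0 <- lubridate::add_with_rollback(
    w$wear_start, -lubridate::period(window_before_months, "months")
  )
  w$w1 <- lubridate::add_with_rollback(
    w$wear_end, lubridate::period(window_after_months, "months")
  )
  if (any(w$w1 < w$w0)) stop("severity_score: invalid window ordering")
  ev <- dplyr::inner_join(
    events, w[, c("participant_id", "w0", "w1")], by = "participant_id"
  )
  ev <- dplyr::filter(ev, .data$date >= .data$w0, .data$date <= .data$w1)
  ev$severity <- sev[ev$class]
  ev$severity[is.na(ev$severity)] <- 0
  agg <- dplyr::summarise(
    dplyr::group_by(ev, .data$participant_id),
    score = mean(.data$severity), n_events = dplyr::n(), .groups = "drop"
  )
  out <- dplyr::left_join(w[, "participant_id", drop = FALSE], agg,
                          by = "participant_id")
  out$score[is.na(out$score)] <- 0
  out$n_events[is.na(out$n_events)] <- 0L
  out$band <- assign_band(out$score)
  tibble::as_tibble(out)
}

#' Impairment band from a severity score
#'
#' Band thresholds: score < 0.5 is Norm-0 (no expected impairment),
#' 0.5 <= score < 1.5 is Norm-1 (intermediate, excluded from control sets),
#' score >= 1.5 is Norm-2 (high impairment). Upper boundaries are inclusive
#' upward (a score of exactly 1.5 is Norm-2).
#'
#' @param score Numeric vector in `[0, 2]`.
#' @param thresholds Length-2 numeric: the Norm-0/Norm-1 and Norm-1/Norm-2
#'   cut points.
#' @return Character vector of bands.
#' @export
assign_band <- function(score, thresholds = c(0.5, 1.5)) {
  if (any(score < 0 | score > 2, na.rm = TRUE)) {
    stop("assign_band: score out of [0, 2]")
  }
  ifelse(score < thresholds[1], "Norm-0",
         ifelse(score < thresholds[2], "Norm-1", "Norm-2"))
}

#' Assemble the cohort: labels, exclusions and Norm bands
#'
#' Combines T2D identification and impairment scoring into one assignment
#' per participant: `T2D`, `Norm-0`, `Norm-1-excluded`, `Norm-2`, or
#' `excluded` (with reason). T2D-positives are retained regardless of their
#' impairment band. Controls lacking EHR coverage (no `participant_id` in
#' the event table at all and `require_ehr = TRUE`) are excluded as
#' band-unknown.
#'
#' @param selfreport,events,wear As in [identify_t2d()] / [severity_score()].
#' @param severity_map Severity map tibble.
#' @param band_thresholds Passed to [assign_band()].
#' @param require_ehr Exclude controls without any EHR presence.
#' @param ... Window arguments passed to [severity_score()].
#' @return Tibble with `participant_id`, `label`, `score`, `band`,
#'   `exclusion_reason`.
#' @export
build_cohort <- function(selfreport, events, wear,
                         severity_map = default_severity_map(),
                         band_thresholds = c(0.5, 1.5),
                         require_ehr = FALSE, ...) {
  t2d <- identify_t2d(selfreport, events, wear, severity_map)
  sc <- severity_score(events, wear, severity_map, ...)
  sc$band <- assign_band(sc$score, band_thresholds)
  out <- dplyr::left_join(t2d, sc, by = "participant_id")
  out$label <- NA_character_
  out$exclusion_reason <- NA_character_
  has_ehr <- out$participant_id %in% unique(events$participant_id)
  for (i in seq_len(nrow(out))) {
    s <- out$t2d_status[i]
    if (s == "positive") {
      out$label[i] <- "T2D"
    } else if (s == "excluded") {
      out$label[i] <- "excluded"
      out$exclusion_reason[i] <- "insulin-age-rule"
    } else if (s == "unresolvable") {
      out$label[i] <- "excluded"
      out$exclusion_reason[i] <- "missing-dates"
    } else if (require_ehr && !has_ehr[i]) {
      out$label[i] <- "excluded"
      out$exclusion_reason[i] <- "no-ehr-coverage"
    } else if (out$band[i] == "Norm-0") {
      out$label[i] <- "Norm-0"
    } else if (out$band[i] == "Norm-1") {
      out$label[i] <- "Norm-1-excluded"
    } else {
      out$label[i] <- "Norm-2"
    }
  }
  out[, c("participant_id", "label", "score", "band", "exclusion_reason")]
}

#' Build the two case-control training sets
#'
#' Training set 1 (TS1) pairs all T2D-positives against a seeded uniform
#' sample of half the Norm-0 controls (floor rounding) to balance class
#' sizes; training set 2 (TS2) pairs the same positives against all Norm-2
#' (highly impaired) controls. Norm-1 participants appear in neither.
#' High-impairment T2D-positives are retained in both.
#'
#' @param assignments A [build_cohort()] tibble.
#' @param seed Seed for the Norm-0 half-sample (dedicated RNG stream).
#' @param n_norm0 Optional override of the Norm-0 sample size (default
#'   `floor(n/2)`).
#' @return List with tibbles `ts1` and `ts2`, each with `participant_id`,
#'   `outcome` (1 = T2D, 0 = control) and `training_set` tag.
#' @export
build_training_sets <- function(assignments, seed = 1, n_norm0 = NULL) {
  pos <- assignments$participant_id[assignments$label == "T2D"]
  norm0 <- assignments$participant_id[assignments$label == "Norm-0"]
  norm2 <- assignments$participant_id[assignments$label == "Norm-2"]
  if (length(pos) == 0) stop("build_training_sets: no T2D-positives")
  if (length(norm0) == 0) stop("build_training_sets: no Norm-0 controls")
  if (length(norm2) == 0) stop("build_training_sets: no Norm-2 controls")
  if (is.null(n_norm0)) n_norm0 <- floor(length(norm0) / 2)
  sampled <- with_seed(seed, sample(norm0, n_norm0))
  mk <- function(neg, tag) {
    tibble::tibble(
      participant_id = c(pos, neg),
      outcome = rep(c(1L, 0L), c(length(pos), length(neg))),
      training_set = tag
    )
  }
  list(ts1 = mk(sampled, "TS1"), ts2 = mk(norm2, "TS2"))
}
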