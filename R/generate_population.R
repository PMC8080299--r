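#' Population configuration for the synthetic cohort generator
#'
#' Bundles everything [generate_population()] needs: group sizes, the control
#' profile, the effect multipliers that derive the case and impaired-control
#' profiles from it, demographic group shifts, missingness and EHR event
#' rates, and the master seed. One master seed deterministically spawns
#' per-participant substreams, so the same config yields a byte-identical
#' population.
#'
#' @param n_t2d,n_control,n_impaired_control Group sizes (>= 0).
#' @param days Wear days per participant.
#' @param control_profile The control-group [activity_profile()].
#' @param t2d_multipliers,impaired_multipliers Effect multipliers applied to
#'   the control profile ([apply_multipliers()]); set all to 1 for a
#'   no-signal (null) population.
#' @param demo_shift_t2d Named additive shifts of numeric demographic
#'   variables for the case group; [default_demo_shifts()] by default.
#' @param demo_shift_scale_impaired Impaired controls receive
#'   `demo_shift_t2d` scaled by this factor (default 0.3 — mildly shifted
#'   toward the case group, their impairment being mostly behavioural).
#' @param demo_missing_rate Cell-level completely-at-random missingness rate
#'   of the demographics table, in `[0, 1)`.
#' @param ehr_rate_benign Expected number of in-window severity-0 events for
#'   clean controls (Poisson).
#' @param ehr_rate_impaired Expected number of in-window high-severity events
#'   for impaired controls, on top of one guaranteed event.
#' @param ehr_rate_outwindow Expected number of out-of-window events per
#'   participant.
#' @param t2d_incident_frac Fraction of cases identified through an incident
#'   EHR code (dated between assessment and wear start) rather than
#'   self-report.
#' @param seed Master seed.
#' @return An object of class `population_config`.
#' @export
population_config <- function(n_t2d = 100,
                              n_control = 100,
                              n_impaired_control = 0,
                              days = 7,
                              control_profile = boutwise::control_profile(),
                              t2d_multipliers = default_t2d_multipliers(),
                              impaired_multipliers = default_impaired_multipliers(),
                              demo_shift_t2d = default_demo_shifts(),
                              demo_shift_scale_impaired = 0.3,
                              demo_missing_rate = 0.05,
                              ehr_rate_benign = 0.7,
                              ehr_rate_impaired = 1,
                              ehr_rate_outwindow = 0.5,
                              t2d_incident_frac = 0.15,
                              seed = 20190304) {
  cfg <- structure(
    list(
      n_t2d = as.integer(n_t2d),
      n_control = as.integer(n_control),
      n_impaired_control = as.integer(n_impaired_control),
      days = as.integer(days),
      control_profile = control_profile,
      t2d_multipliers = t2d_multipliers,
      impaired_multipliers = impaired_multipliers,
      demo_shift_t2d = demo_shift_t2d,
      demo_shift_scale_impaired = demo_shift_scale_impaired,
      demo_missing_rate = demo_missing_rate,
      ehr_rate_benign = ehr_rate_benign,
      ehr_rate_impaired = ehr_rate_impaired,
      ehr_rate_outwindow = ehr_rate_outwindow,
      t2d_incident_frac = t2d_incident_frac,
      seed = as.integer(seed)
    ),
    class = "population_config"
  )
  validate_population_config(cfg)
  cfg
}

validate_population_config <- function(cfg) {
  counts <- c(cfg$n_t2d, cfg$n_control, cfg$n_impaired_control)
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("population_config: group counts must be >= 0")
  }
  if (cfg$days < 1) stop("population_config: days must be >= 1")
  if (cfg$demo_missing_rate < 0 || cfg$demo_missing_rate >= 1) {
    stop("population_config: demo_missing_rate must be in [0, 1)")
  }
  rates <- c(cfg$ehr_rate_benign, cfg$ehr_rate_impaired, cfg$ehr_rate_outwindow)
  if (any(rates < 0)) stop("population_config: EHR rates must be >= 0")
  if (cfg$t2d_incident_frac < 0 || cfg$t2d_incident_frac > 1) {
    stop("population_config: t2d_incident_frac must be in [0, 1]")
  }
  validate_profile(cfg$control_profile)
  invisible(cfg)
}

#' Default demographic group shifts for the case group
#'
#' Additive shifts applied to the control means of the numeric Table-2-style
#' covariates to obtain the case group's distributions: older, higher
#' adiposity, more television time, less self-reported activity.
#'
#' @return Named numeric vector of shifts (units of the shifted variable).
#' @export
default_demo_shifts <- function() {
  c(
    age = 3,
    body_fat_pct = 5,
    waist_cm = 8,
    sleep_duration_h = 0.2,
    tv_time_h = 0.6,
    townsend = 0.5,
    walk_min_day = -15,
    vigorous_min_day = -8,
    moderate_min_day = -10
  )
}

demographic_columns <- function() {
  c("sex", "age", "ethnic_group", "alcohol_status", "smoking_status",
    "body_fat_pct", "waist_cm", "sleep_duration_h", "tv_time_h", "townsend",
    "walk_min_day", "vigorous_min_day", "moderate_min_day")
}

#' Generate a synthetic population
#'
#' Draws a complete synthetic cohort: activity traces, a 13-variable
#' sociodemographic table, self-report and wear-period tables, an EHR event
#' stream and ground-truth group labels. Case traces come from the
#' effect-multiplied control profile; impaired controls get an intermediate
#' profile plus guaranteed high-severity in-window EHR events.
#'
#' @param config A [population_config()].
#' @return A list of class `synthetic_population` with elements `traces`
#'   (named list of [epoch_series()]), `demographics`, `selfreport`, `wear`,
#'   `ehr` (tibbles) and `labels` (tibble with `participant_id`, `group`).
#' @export
generate_population <- function(config) {
  validate_population_config(config)
  n <- config$n_t2d + config$n_control + config$n_impaired_control
  groups <- rep(c("t2d", "control", "impaired_control"),
                c(config$n_t2d, config$n_control, config$n_impaired_control))
  ids <- sprintf("P%04d", seq_len(max(n, 1))[seq_len(n)])
  labels <- tibble::tibble(participant_id = ids, group = groups)

  profiles <- list(
    control = config$control_profile,
    t2d = apply_multipliers(config$control_profile, config$t2d_multipliers),
    impaired_control = apply_multipliers(config$control_profile,
                                         config$impaired_multipliers)
  )

  seeds <- if (n > 0) spawn_seeds(config$seed, n + 3L) else integer(3)
  trace_seeds <- seeds[seq_len(n)]
  aux_seeds <- seeds[n + 1:3]

  wear <- generate_wear_periods(ids, aux_seeds[1])

  traces <- vector("list", n)
  names(traces) <- ids
  for (i in seq_len(n)) {
    traces[[i]] <- generate_trace(
      profiles[[groups[i]]], days = config$days, seed = trace_seeds[i],
      start = paste(wear$wear_start[i], "12:00:00"),
      participant_id = ids[i]
    )
  }

  demographics <- generate_demographics(
    labels,
    shifts = config$demo_shift_t2d,
    impaired_scale = config$demo_shift_scale_impaired,
    missing_rate = config$demo_missing_rate,
    seed = aux_seeds[2]
  )

  selfreport <- generate_selfreport(labels, demographics, wear,
                                    incident_frac = config$t2d_incident_frac,
                                    seed = aux_seeds[3])

  ehr <- generate_ehr(config, labels, wear, selfreport, seed = config$seed)

  structure(
    list(
      traces = traces,
      demographics = demographics,
      selfreport = selfreport,
      wear = wear,
      ehr = ehr,
      labels = labels
    ),
    class = "synthetic_population"
  )
}

#' @export
print.synthetic_population <- function(x, ...) {
  cat("<synthetic_population>", nrow(x$labels), "participants:\n")
  print(table(x$labels$group))
  invisible(x)
}

## Assessment-centre visit ~1-3 years before wear; wear period spans `days`.
generate_wear_periods <- function(ids, seed, days = 7) {
  with_seed(seed, {
    n <- length(ids)
    assessment <- as.Date("2013-06-01") + sample.int(365, n, replace = TRUE)
    wear_start <- assessment + 365 + sample.int(730, n, replace = TRUE)
    tibble::tibble(
      participant_id = ids,
      assessment_date = assessment,
      wear_start = wear_start,
      wear_end = wear_start + days
    )
  })
}

#' Generate the sociodemographic / lifestyle / anthropometry table
#'
#' Thirteen covariates per participant (sex, age, ethnic group, alcohol and
#' smoking status, body fat %, waist circumference, sleep duration, TV time,
#' Townsend index, self-reported walking / vigorous / moderate activity
#' durations), with group-dependent mean shifts on the numeric variables and
#' completely-at-random cell missingness.
#'
#' @param labels Tibble with `participant_id` and `group`.
#' @param shifts Named additive shifts for the case group
#'   ([default_demo_shifts()]).
#' @param impaired_scale Scale factor applied to `shifts` for impaired
#'   controls.
#' @param missing_rate Cell-level missingness rate in `[0, 1)`.
#' @param seed Integer seed.
#' @return Tibble with `participant_id` plus the 13 covariates.
#' @export
generate_demographics <- function(labels, shifts = default_demo_shifts(),
                                  impaired_scale = 0.5, missing_rate = 0.05,
                                  seed = 1) {
  n <- nrow(labels)
  scale_by_group <- c(control = 0, impaired_control = impaired_scale, t2d = 1)
  sc <- scale_by_group[labels$group]
  sh <- function(var) {
    s <- if (var %in% names(shifts)) shifts[[var]] else 0
    s * sc
  }
  with_seed(seed, {
    sex <- sample(c("Male", "Female"), n, replace = TRUE)
    d <- tibble::tibble(
      participant_id = labels$participant_id,
      sex = sex,
      age = pmin(69, pmax(40, round(stats::rnorm(n, 56 + sh("age"), 8)))),
      ethnic_group = sample(c("White", "Asian", "Black", "Other"), n,
                            replace = TRUE, prob = c(0.94, 0.03, 0.02, 0.01)),
      alcohol_status = sample(c("Never", "Previous", "Current"), n,
                              replace = TRUE, prob = c(0.06, 0.08, 0.86)),
      smoking_status = sample(c("Never", "Previous", "Current"), n,
                              replace = TRUE, prob = c(0.55, 0.35, 0.10)),
      body_fat_pct = pmin(55, pmax(8, stats::rnorm(
        n, 31 + ifelse(sex == "Male", -5, 5) + sh("body_fat_pct"), 6
      ))),
      waist_cm = pmax(55, stats::rnorm(
        n, 90 + ifelse(sex == "Male", 6, -6) + sh("waist_cm"), 10
      )),
      sleep_duration_h = pmin(12, pmax(3, stats::rnorm(
        n, 7.2 + sh("sleep_duration_h"), 1
      ))),
      tv_time_h = pmax(0, stats::rnorm(n, 2.7 + sh("tv_time_h"), 1.4)),
      townsend = stats::rnorm(n, -1.5 + sh("townsend"), 2.8),
      walk_min_day = pmax(0, stats::rnorm(n, 60 + sh("walk_min_day"), 35)),
      vigorous_min_day = pmax(0, stats::rnorm(n, 20 + sh("vigorous_min_day"), 20)),
      moderate_min_day = pmax(0, stats::rnorm(n, 45 + sh("moderate_min_day"), 30))
    )
    if (missing_rate > 0 && n > 0) {
      for (col in demographic_columns()) {
        hole <- stats::runif(n) < missing_rate
        d[[col]][hole] <- NA
      }
    }
    d
  })
}

## Self-report table: most cases carry an assessment-centre diagnosis; the
## configured fraction are incident instead (diagnosis appears only in EHR).
generate_selfreport <- function(labels, demographics, wear, incident_frac,
                                seed) {
  n <- nrow(labels)
  with_seed(seed, {
    is_t2d <- labels$group == "t2d"
    incident <- is_t2d & (stats::runif(n) < incident_frac)
    diagnosed <- is_t2d & !incident
    age <- ifelse(is.na(demographics$age), 56, demographics$age)
    age_dx <- ifelse(diagnosed, pmax(35, round(age - stats::runif(n, 1, 10))),
                     NA_real_)
    tibble::tibble(
      participant_id = labels$participant_id,
      diabetes_diagnosed = diagnosed,
      insulin_first_year = ifelse(diagnosed, FALSE, NA),
      age_at_diagnosis = age_dx,
      assessment_date = wear$assessment_date,
      incident = incident
    )
  })
}

#' Generate a synthetic EHR event stream
#'
#' Impaired controls are guaranteed at least one high-severity (class-2)
#' event dated inside the impairment scoring window (6 months before wear
#' start to 1 month after wear end); clean controls receive only
#' severity-0 events in-window (at rate `ehr_rate_benign`) plus possibly
#' out-of-window events of any severity; incident cases get one T2D code
#' dated between assessment and wear start.
#'
#' @param config A [population_config()] (rates are read from it).
#' @param labels Tibble with `participant_id` and `group`.
#' @param wear Wear-period tibble (`assessment_date`, `wear_start`,
#'   `wear_end`).
#' @param selfreport Self-report tibble (for the incident-case flag); may be
#'   `NULL`, in which case no incident codes are emitted.
#' @param seed Integer seed.
#' @return Tibble with columns `participant_id`, `date`, `code`, `class`.
#' @export
generate_ehr <- function(config, labels, wear, selfreport = NULL, seed = 1) {
  map <- default_severity_map()
  benign_classes <- map$class[map$severity == 0 & !map$t2d_code]
  severe_classes <- map$class[map$severity == 2 & !map$t2d_code]
  mid_classes <- map$class[map$severity == 1]
  t2d_class <- map$class[map$t2d_code][1]
  code_for <- stats::setNames(map$code, map$class)

  with_seed(seed + 7L, {
    rows <- list()
    add <- function(id, dates, classes) {
      if (length(dates) == 0) return()
      rows[[length(rows) + 1L]] <<- tibble::tibble(
        participant_id = id, date = as.Date(dates, origin = "1970-01-01"),
        class = classes
      )
    }
    for (i in seq_len(nrow(labels))) {
      id <- labels$participant_id[i]
      grp <- labels$group[i]
      w0 <- lubridate::add_with_rollback(
        wear$wear_start[i], -lubridate::period(6, "months")
      )
      w1 <- lubridate::add_with_rollback(
        wear$wear_end[i], lubridate::period(1, "months")
      )
      in_window <- function(k) w0 + round(stats::runif(k) * as.numeric(w1 - w0))
      out_window <- function(k) w0 - 60 - sample.int(700, k, replace = TRUE)

      if (grp == "impaired_control") {
        k <- 1L + stats::rpois(1, config$ehr_rate_impaired)
        add(id, in_window(k), sample(severe_classes, k, replace = TRUE))
      } else if (grp == "control") {
        k <- stats::rpois(1, config$ehr_rate_benign)
        if (k > 0) add(id, in_window(k), sample(benign_classes, k, replace = TRUE))
      }
      ko <- stats::rpois(1, config$ehr_rate_outwindow)
      if (ko > 0) {
        add(id, out_window(ko),
            sample(c(benign_classes, mid_classes, severe_classes), ko,
                   replace = TRUE))
      }
      if (grp == "t2d" && !is.null(selfreport) && selfreport$incident[i]) {
        span <- as.numeric(wear$wear_start[i] - wear$assessment_date[i])
        add(id, wear$assessment_date[i] + sample.int(max(1, span - 1), 1),
            t2d_class)
      }
    }
    if (length(rows) == 0) {
      return(tibble::tibble(
        participant_id = character(), date = as.Date(character()),
        code = character(), class = character()
      ))
    }
    ehr <- dplyr::bind_rows(rows)
    ehr$code <- unname(code_for[ehr$class])
    dplyr::arrange(
      ehr[, c("participant_id", "date", "code", "class")],
      .data$participant_id, .data$date
    )
  })
}
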