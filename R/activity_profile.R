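#' Activity profile for the synthetic trace generator
#'
#' An `activity_profile` parameterizes the generative model of one group's
#' epoch-labelled activity traces. Each 24-h (noon-to-noon) day is built
#' sleep-first: a nocturnal sleep block is drawn from the onset/duration
#' distributions and optionally fragmented by brief awakenings; the remaining
#' wake time is filled by a semi-Markov process that picks a wake activity and
#' then a bout length from a shifted negative binomial (minimum 1 epoch).
#'
#' Occupancy weights give the *time share* of each wake class within a wake
#' phase (not the bout-pick probability): internally the pick probability of
#' class \eqn{a} is proportional to \eqn{w_a / m_a}, where \eqn{m_a} is the
#' mean bout length, so that by renewal-reward the expected fraction of wake
#' time spent in class \eqn{a} equals \eqn{w_a} exactly.
#'
#' Person-level and day-level lognormal heterogeneity make participants
#' distinguishable individuals rather than i.i.d. draws of one process; all
#' SDs are on the log scale except the sleep-timing SDs (minutes).
#'
#' @param occupancy Named numeric vector of wake-time shares for
#'   `sedentary`, `moderate`, `walking`, `light_tasks`; must be nonnegative
#'   and sum to 1. Used for all three wake phases.
#' @param bout_len_mean Named numeric vector of mean bout lengths (epochs,
#'   >= 1) for the four wake classes.
#' @param bout_len_disp Negative-binomial dispersion (size) of bout lengths;
#'   scalar or named vector.
#' @param sleep_onset_mean,sleep_onset_sd Sleep onset time-of-day: mean and
#'   night-to-night SD, minutes from midnight.
#' @param sleep_dur_mean,sleep_dur_sd Sleep duration mean and night-to-night
#'   SD, minutes.
#' @param frag_rate Expected number of brief awakenings per night (Poisson).
#' @param frag_len_mean Mean length of an awakening, epochs (geometric, >= 1).
#' @param missing_rate Probability that an epoch is recorded as `missing`
#'   (completely at random), in `[0, 1)`.
#' @param person_len_sd Log-scale SD of the person-level multiplier on bout
#'   length means.
#' @param person_occ_conc Concentration of the Dirichlet distribution the
#'   person-level occupancy weights are drawn from (mean = profile weights,
#'   so population occupancy stays calibrated; larger = less between-person
#'   spread).
#' @param person_sleep_sd Person-level SD of sleep duration mean, minutes.
#' @param person_onset_sd Person-level SD of sleep onset mean, minutes.
#' @param person_frag_sd Log-scale SD of the person-level multiplier on the
#'   awakening rate (nightly sleep fragmentation differs strongly between
#'   people).
#' @param day_len_sd Log-scale SD of the day-level multiplier on bout length
#'   means (between-day variability on top of the person level).
#' @return An object of class `activity_profile` (a validated list).
#' @seealso [control_profile()], [t2d_profile()], [generate_trace()]
#' @export
activity_profile <- function(occupancy,
                             bout_len_mean,
                             bout_len_disp = 2,
                             sleep_onset_mean = 23 * 60,
                             sleep_onset_sd = 30,
                             sleep_dur_mean = 480,
                             sleep_dur_sd = 40,
                             frag_rate = 1.5,
                             frag_len_mean = 2,
                             missing_rate = 0.02,
                             person_len_sd = 0.35,
                             person_occ_conc = 40,
                             person_sleep_sd = 40,
                             person_onset_sd = 45,
                             person_frag_sd = 0.6,
                             day_len_sd = 0.10) {
  wk <- wake_levels()
  occupancy <- as_wake_matrix(occupancy, "occupancy")
  bout_len_mean <- as_wake_matrix(bout_len_mean, "bout_len_mean")
  bout_len_disp <- as_wake_matrix(bout_len_disp, "bout_len_disp")
  prof <- structure(
    list(
      occupancy = occupancy,
      bout_len_mean = bout_len_mean,
      bout_len_disp = bout_len_disp,
      sleep_onset_mean = sleep_onset_mean,
      sleep_onset_sd = sleep_onset_sd,
      sleep_dur_mean = sleep_dur_mean,
      sleep_dur_sd = sleep_dur_sd,
      frag_rate = frag_rate,
      frag_len_mean = frag_len_mean,
      missing_rate = missing_rate,
      person_len_sd = person_len_sd,
      person_occ_conc = person_occ_conc,
      person_sleep_sd = person_sleep_sd,
      person_onset_sd = person_onset_sd,
      person_frag_sd = person_frag_sd,
      day_len_sd = day_len_sd
    ),
    class = "activity_profile"
  )
  validate_profile(prof)
  prof
}

## Profile parameters for wake classes are 4 x 3 matrices
## (activity x morning/afternoon/evening). Scalars and named vectors are
## recycled across phases so the common phase-invariant case stays terse.
as_wake_matrix <- function(x, what) {
  wk <- wake_levels()
  ph <- wake_phases()
  if (is.matrix(x)) {
    if (!setequal(rownames(x), wk)) {
      stop("activity_profile: ", what, " matrix rows must be ",
           paste(wk, collapse = ", "))
    }
    m <- x[wk, , drop = FALSE]
    if (ncol(m) != 3L) stop("activity_profile: ", what, " needs 3 phase columns")
    colnames(m) <- ph
    return(m)
  }
  if (length(x) == 1L) x <- stats::setNames(rep(x, length(wk)), wk)
  if (is.null(names(x)) || !setequal(names(x), wk)) {
    stop("activity_profile: ", what, " must be named with ",
         paste(wk, collapse = ", "))
  }
  matrix(x[wk], nrow = length(wk), ncol = 3L, dimnames = list(wk, ph))
}

validate_profile <- function(p) {
  wk <- wake_levels()
  if (anyNA(p$occupancy) || any(p$occupancy < 0)) {
    stop("activity_profile: occupancy weights must be nonnegative and named ",
         paste(wk, collapse = ", "))
  }
  if (any(abs(colSums(p$occupancy) - 1) > 1e-8)) {
    stop("activity_profile: occupancy weights must sum to 1 within each wake phase")
  }
  if (anyNA(p$bout_len_mean) || any(p$bout_len_mean < 1)) {
    stop("activity_profile: mean bout lengths must be >= 1 epoch")
  }
  if (any(p$bout_len_disp <= 0)) stop("activity_profile: dispersion must be > 0")
  sds <- c(p$sleep_onset_sd, p$sleep_dur_sd, p$person_len_sd,
           p$person_sleep_sd, p$person_onset_sd, p$person_frag_sd,
           p$day_len_sd)
  if (any(sds < 0)) stop("activity_profile: SDs must be >= 0")
  if (p$person_occ_conc <= 0) {
    stop("activity_profile: person_occ_conc must be > 0")
  }
  if (p$sleep_dur_mean <= 0 || p$sleep_dur_mean >= MINUTES_PER_DAY) {
    stop("activity_profile: sleep duration mean must lie in (0, 1440) minutes")
  }
  if (p$missing_rate < 0 || p$missing_rate >= 1) {
    stop("activity_profile: missing_rate must be in [0, 1)")
  }
  if (p$frag_rate < 0 || p$frag_len_mean < 1) {
    stop("activity_profile: fragmentation parameters out of range")
  }
  invisible(p)
}

#' Default control activity profile
#'
#' Calibrated so that the expected 24-h occupancy reproduces the activity mix
#' reported for the UK-Biobank-style accelerometry population: about 42%
#' sedentary, 38% asleep, 10% walking, 5% moderate and 5% light tasks.
#' Calibration is analytic: sleep share is set by the sleep-duration mean
#' (inflated by the expected awakening minutes, which are relabelled
#' sedentary), and each wake class's share of the remaining wake time is its
#' occupancy weight (see [activity_profile()] for why this is exact in
#' expectation).
#'
#' @param sleep_share,sedentary_share,walking_share,moderate_share,light_share
#'   Target 24-h occupancy fractions; must sum to 1.
#' @param ... Further arguments passed to [activity_profile()].
#' @return An `activity_profile`.
#' @export
control_profile <- function(sleep_share = 0.38,
                            sedentary_share = 0.42,
                            walking_share = 0.10,
                            moderate_share = 0.05,
                            light_share = 0.05,
                            ...) {
  shares <- c(sleep_share, sedentary_share, walking_share, moderate_share,
              light_share)
  if (abs(sum(shares) - 1) > 1e-8) stop("target shares must sum to 1")
  frag_rate <- 1.5
  frag_len_mean <- 2
  ## awakenings replace sleep epochs with sedentary ones; compensate so the
  ## realized sleep share still hits the target
  frag_minutes <- frag_rate * frag_len_mean / EPOCHS_PER_MINUTE
  sleep_dur_mean <- sleep_share * MINUTES_PER_DAY + frag_minutes
  wake_share <- 1 - sleep_share
  occ <- c(
    sedentary = sedentary_share,
    moderate = moderate_share,
    walking = walking_share,
    light_tasks = light_share
  ) / wake_share
  activity_profile(
    occupancy = occ,
    bout_len_mean = c(
      sedentary = 20, moderate = 6, walking = 4, light_tasks = 6
    ),
    sleep_dur_mean = sleep_dur_mean,
    frag_rate = frag_rate,
    frag_len_mean = frag_len_mean,
    ...
  )
}

#' Apply group effect multipliers to a profile
#'
#' Produces a modified profile from a reference one, e.g. the T2D group's
#' profile from the control profile. Length multipliers scale mean bout
#' lengths; occupancy multipliers scale the wake-time shares (then
#' renormalized); `frag` scales the awakening rate and `onset_sd` the
#' night-to-night onset SD.
#'
#' @param profile An `activity_profile`.
#' @param multipliers Named list with any of: `sedentary_len`, `moderate_len`,
#'   `walking_len`, `light_tasks_len`, `sedentary_occ`, `moderate_occ`,
#'   `walking_occ`, `light_tasks_occ`, `frag`, `onset_sd`, `sleep_dur`.
#'   Missing entries default to 1 (no effect).
#' @return A new `activity_profile`.
#' @export
apply_multipliers <- function(profile, multipliers = list()) {
  m <- function(name) if (is.null(multipliers[[name]])) 1 else multipliers[[name]]
  wk <- wake_levels()
  len <- profile$bout_len_mean
  occ <- profile$occupancy
  for (a in wk) {
    len[a, ] <- pmax(1, len[a, ] * m(paste0(a, "_len")))
    occ[a, ] <- occ[a, ] * m(paste0(a, "_occ"))
  }
  occ <- sweep(occ, 2, colSums(occ), "/")
  prof <- profile
  prof$bout_len_mean <- len
  prof$occupancy <- occ
  prof$frag_rate <- profile$frag_rate * m("frag")
  prof$sleep_onset_sd <- profile$sleep_onset_sd * m("onset_sd")
  prof$sleep_dur_mean <- min(
    MINUTES_PER_DAY - 1, profile$sleep_dur_mean * m("sleep_dur")
  )
  validate_profile(prof)
  prof
}

#' Default T2D-group profile
#'
#' The control profile with the default case-group effect multipliers
#' applied: longer sedentary bouts, reduced walking and moderate occupancy,
#' more fragmented and less regular sleep.
#'
#' @param base Reference profile (default [control_profile()]).
#' @param multipliers Effect multipliers, defaulting to
#'   [default_t2d_multipliers()].
#' @return An `activity_profile`.
#' @export
t2d_profile <- function(base = control_profile(),
                        multipliers = default_t2d_multipliers()) {
  apply_multipliers(base, multipliers)
}

#' @rdname t2d_profile
#' @export
default_t2d_multipliers <- function() {
  list(
    sedentary_len = 1.3,
    walking_occ = 0.80,
    moderate_occ = 0.80,
    frag = 2,
    onset_sd = 1.25
  )
}

#' Default impaired-control profile multipliers
#'
#' Nondiabetic controls with physical-activity-impairing conditions sit
#' between clean controls and the case group: extra sedentary occupancy and
#' bout length, reduced walking, somewhat fragmented sleep.
#'
#' @return Named list of multipliers.
#' @export
default_impaired_multipliers <- function() {
  list(
    sedentary_len = 1.2,
    sedentary_occ = 1.10,
    walking_occ = 0.75,
    moderate_occ = 0.75,
    frag = 1.5
  )
}
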