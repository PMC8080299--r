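## Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## Deterministically spawn n sub-seeds (< 2^31) from one master seed so
## per-participant streams are reproducible and independent of ordering.
spawn_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Generate a synthetic epoch-labelled activity trace
#'
#' Simulates one participant's wear-time label sequence at 30-s cadence.
#' Each noon-to-noon day receives one nocturnal sleep block drawn from the
#' profile's onset/duration distributions, optionally fragmented by brief
#' awakenings (relabelled sedentary); wake time is then filled by a
#' semi-Markov draw — pick a wake class, draw a bout length from a shifted
#' negative binomial, repeat — with pick probabilities calibrated so the
#' expected wake-time share of each class equals its occupancy weight.
#' Finally a fraction of epochs is set to `missing` completely at random.
#'
#' @param profile An [activity_profile()].
#' @param days Number of wear days (>= 1); the trace has `days * 2880` epochs.
#' @param seed Integer seed; identical `(profile, days, seed)` gives an
#'   identical trace. The caller's RNG state is untouched.
#' @param start Start timestamp of the first epoch; defaults to local noon so
#'   analysis days align with generation days.
#' @param participant_id Identifier stored on the series.
#' @return An [epoch_series()].
#' @export
generate_trace <- function(profile, days, seed,
                           start = "2019-03-04 12:00:00",
                           participant_id = "p1") {
  validate_profile(profile)
  if (!is.numeric(days) || length(days) != 1L || days < 1) {
    stop("generate_trace: days must be a positive integer")
  }
  days <- as.integer(days)
  labels <- with_seed(seed, {
    person <- draw_person_effects(profile)
    out <- vector("list", days)
    for (d in seq_len(days)) out[[d]] <- generate_day(profile, person)
    lab <- unlist(out, use.names = FALSE)
    if (profile$missing_rate > 0) {
      miss <- stats::runif(length(lab)) < profile$missing_rate
      lab[miss] <- missing_label()
    }
    lab
  })
  epoch_series(labels, start, participant_id)
}

## Person-level heterogeneity: lognormal multipliers on bout-length means,
## Dirichlet-distributed occupancy weights centred on the profile weights
## (mean-preserving, so the population occupancy stays calibrated), and
## Gaussian shifts of the sleep onset/duration means. One draw per activity
## is shared across wake phases so a person is consistently (in)active.
draw_person_effects <- function(p) {
  wk <- wake_levels()
  len_mult <- exp(stats::rnorm(length(wk), 0, p$person_len_sd))
  len <- pmax(p$bout_len_mean * len_mult, 1)
  base_w <- rowMeans(p$occupancy)
  g <- stats::rgamma(length(wk), shape = p$person_occ_conc * base_w, rate = 1)
  g[g <= 0] <- 1e-12
  occ_mult <- g / base_w  # relative deviation from the mean weights
  occ <- p$occupancy * occ_mult
  occ <- sweep(occ, 2, colSums(occ), "/")
  list(
    len = len,
    occ = occ,
    dur_mean = min(MINUTES_PER_DAY - 60,
                   max(120, p$sleep_dur_mean + stats::rnorm(1, 0, p$person_sleep_sd))),
    onset_mean = p$sleep_onset_mean + stats::rnorm(1, 0, p$person_onset_sd),
    frag_rate = p$frag_rate * exp(stats::rnorm(1, 0, p$person_frag_sd))
  )
}

generate_day <- function(p, person) {
  n <- EPOCHS_PER_DAY
  lab <- character(n)

  ## --- sleep anchor block ---
  onset_min <- person$onset_mean + stats::rnorm(1, 0, p$sleep_onset_sd)
  dur_min <- person$dur_mean + stats::rnorm(1, 0, p$sleep_dur_sd)
  dur_min <- min(MINUTES_PER_DAY - 30, max(60, dur_min))
  since_noon <- (onset_min - 720) %% MINUTES_PER_DAY
  onset_idx <- as.integer(round(since_noon * EPOCHS_PER_MINUTE)) + 1L
  onset_idx <- min(max(onset_idx, 1L), n)
  dur_ep <- max(2L, as.integer(round(dur_min * EPOCHS_PER_MINUTE)))
  end_idx <- min(n, onset_idx + dur_ep - 1L)
  lab[onset_idx:end_idx] <- "sleep"

  ## brief awakenings inside the block (relabelled sedentary); block interior
  ## only, so onset/offset are preserved
  k <- stats::rpois(1, person$frag_rate)
  block_len <- end_idx - onset_idx + 1L
  if (k > 0 && block_len > 10L) {
    pos <- sample((onset_idx + 2L):(end_idx - 2L), k, replace = TRUE)
    lens <- 1L + stats::rgeom(k, prob = 1 / p$frag_len_mean)
    for (i in seq_len(k)) {
      j <- pos[i]:min(pos[i] + lens[i] - 1L, end_idx - 1L)
      lab[j] <- "sedentary"
    }
  }

  ## --- wake fill, phase-aware ---
  ## Wake epochs are ordered circularly from the sleep end: the post-sleep
  ## segment is early wake (morning first), the pre-sleep segment is late
  ## wake counted back from the next onset (evening last).
  day_len_mult <- exp(stats::rnorm(1, 0, p$day_len_sd))
  wake_total <- n - block_len
  if (wake_total > 0L) {
    fill_segment <- function(idx, wake_pos) {
      # wake_pos: circular wake position (1..wake_total) of each epoch in idx
      third <- wake_total / 3
      phase_id <- pmin(3L, 1L + (wake_pos - 1) %/% third)
      for (ph in unique(phase_id)) {
        sub <- idx[phase_id == ph]
        if (length(sub) > 0) {
          lab[sub] <<- draw_wake_bouts(
            length(sub),
            occ = person$occ[, ph],
            len = pmax(person$len[, ph] * day_len_mult, 1),
            disp = p$bout_len_disp[, ph]
          )
        }
      }
    }
    post <- if (end_idx < n) (end_idx + 1L):n else integer(0)
    pre <- if (onset_idx > 1L) 1L:(onset_idx - 1L) else integer(0)
    if (length(post) > 0) fill_segment(post, seq_along(post))
    if (length(pre) > 0) {
      fill_segment(pre, wake_total - length(pre) + seq_along(pre))
    }
  }
  lab
}

## Fill L epochs with wake bouts. Pick probability of class a is
## occ_a / len_a (normalized): with mean bout length len_a this makes the
## expected time share of class a equal occ_a (renewal-reward).
draw_wake_bouts <- function(L, occ, len, disp) {
  wk <- names(occ)
  pick <- occ / len
  pick <- pick / sum(pick)
  mean_len <- sum(pick * len)
  out <- character(0)
  filled <- 0L
  while (filled < L) {
    nb <- max(8L, ceiling(2 * (L - filled) / mean_len))
    acts <- sample(wk, nb, replace = TRUE, prob = pick)
    lens <- 1L + stats::rnbinom(nb, size = disp[acts], mu = pmax(0, len[acts] - 1))
    cum <- cumsum(lens)
    take <- which(cum >= (L - filled))[1]
    if (is.na(take)) {
      out <- c(out, rep(acts, lens))
      filled <- filled + cum[nb]
    } else {
      lens[take] <- lens[take] - (cum[take] - (L - filled))
      out <- c(out, rep(acts[seq_len(take)], lens[seq_len(take)]))
      filled <- L
    }
  }
  out[seq_len(L)]
}
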