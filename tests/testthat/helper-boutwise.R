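# Shared fixtures and independent oracles, built in code at test time.

NOON_START <- "2019-03-04 12:00:00"

# Degenerate profile: fixed sleep 23:00-07:00, no fragmentation, no missing
# epochs, no person/day heterogeneity (person_occ_conc huge => Dirichlet
# collapses onto the profile weights).
degenerate_profile <- function(onset = 23 * 60, dur = 480,
                               missing_rate = 0, ...) {
  activity_profile(
    occupancy = c(sedentary = 0.42, moderate = 0.05, walking = 0.10,
                  light_tasks = 0.05) / 0.62,
    bout_len_mean = c(sedentary = 20, moderate = 6, walking = 4,
                      light_tasks = 6),
    sleep_onset_mean = onset, sleep_onset_sd = 0,
    sleep_dur_mean = dur, sleep_dur_sd = 0,
    frag_rate = 0, missing_rate = missing_rate,
    person_len_sd = 0, person_occ_conc = 1e9, person_sleep_sd = 0,
    person_onset_sd = 0, person_frag_sd = 0, day_len_sd = 0, ...
  )
}

# Build one noon-to-noon day of labels (2880 epochs) from (label, minutes)
# segments; minutes are wall-clock durations starting at 12:00.
day_labels <- function(...) {
  segs <- list(...)
  lab <- unlist(lapply(segs, function(s) rep(s[[1]], s[[2]] * 2)))
  stopifnot(length(lab) == 2880)
  lab
}

make_series <- function(labels, start = NOON_START, id = "p1") {
  epoch_series(labels, start, participant_id = id)
}

# Independent run-length-encoding oracle: a plain loop, no rle().
rle_oracle <- function(labels) {
  out <- list()
  i <- 1
  n <- length(labels)
  while (i <= n) {
    j <- i
    while (j < n && labels[j + 1] == labels[i]) j <- j + 1
    if (labels[i] != "missing") {
      out[[length(out) + 1]] <- data.frame(
        activity = labels[i], start = i - 1L, length = j - i + 1L
      )
    }
    i <- j + 1
  }
  if (length(out) == 0) {
    return(data.frame(activity = character(), start = integer(),
                      length = integer()))
  }
  do.call(rbind, out)
}

# Brute-force best nearly-continuous sleep block: enumerate every (i, j)
# range of sleep bouts, keep those whose internal gaps are all <= tol,
# score by total sleep epochs, prefer the earliest start on ties.
best_block_oracle <- function(labels, tol) {
  r <- rle_oracle(c(labels))
  sl <- r[r$activity == "sleep", , drop = FALSE]
  if (nrow(sl) == 0) return(NULL)
  best <- NULL
  for (i in seq_len(nrow(sl))) {
    for (j in i:nrow(sl)) {
      ok <- TRUE
      if (j > i) {
        for (k in i:(j - 1)) {
          gap <- sl$start[k + 1] - (sl$start[k] + sl$length[k])
          if (gap > tol) { ok <- FALSE; break }
        }
      }
      if (!ok) next
      cand <- list(start = sl$start[i] + 1L,
                   end = sl$start[j] + sl$length[j],
                   sleep_epochs = sum(sl$length[i:j]))
      if (is.null(best) || cand$sleep_epochs > best$sleep_epochs) best <- cand
    }
  }
  best
}

# Independent per-epoch tally oracle for the daily feature matrix.
daily_features_oracle <- function(labels, minutes, phases) {
  ph <- phase_of_minute(phases, minutes)
  grid <- expand.grid(activity = activity_levels(), phase = phase_levels(),
                      stringsAsFactors = FALSE)
  res <- grid
  res$n_bouts <- 0; res$pct_time <- NA_real_; res$mean_len <- 0
  for (g in seq_len(nrow(grid))) {
    a <- grid$activity[g]; p <- grid$phase[g]
    in_cell <- labels == a & ph == p
    nonmiss <- sum(labels != "missing" & ph == p)
    # count bouts: runs of in_cell that are contiguous in index AND not
    # interrupted by phase change or other labels
    nb <- 0L; total <- 0L; i <- 1
    n <- length(labels)
    while (i <= n) {
      if (in_cell[i]) {
        j <- i
        while (j < n && in_cell[j + 1]) j <- j + 1
        nb <- nb + 1L; total <- total + (j - i + 1L); i <- j + 1
      } else i <- i + 1
    }
    res$n_bouts[g] <- nb
    res$pct_time[g] <- if (nonmiss > 0) 100 * total / nonmiss else NA_real_
    res$mean_len[g] <- if (nb > 0) total / nb else 0
  }
  res
}

# Hand-rolled rank-based AUC (Wilcoxon formula), independent of pROC.
auc_oracle <- function(y, p) {
  r <- rank(p)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Small deterministic demographics-like table for imputation tests.
random_demo_table <- function(n, missing_rate, seed) {
  labels <- tibble::tibble(participant_id = sprintf("Q%03d", 1:n),
                           group = "control")
  generate_demographics(labels, missing_rate = missing_rate, seed = seed)
}

# Naive all-pairs kNN imputation oracle mirroring the documented semantics:
# standardized numeric distance with pairwise-skipped dimensions, mean for
# numeric, alphabetical-tie mode for categoricals. Double loop throughout.
impute_oracle <- function(table, k) {
  vars <- setdiff(names(table), "participant_id")
  num_vars <- vars[vapply(table[vars], is.numeric, logical(1))]
  z <- scale(as.matrix(table[num_vars]))
  n <- nrow(table)
  dist_ij <- function(i, j) {
    s <- 0; m <- 0
    for (c in seq_along(num_vars)) {
      if (!is.na(z[i, c]) && !is.na(z[j, c])) {
        s <- s + (z[i, c] - z[j, c])^2; m <- m + 1
      }
    }
    if (m == 0) Inf else sqrt(s / m)
  }
  out <- table
  for (v in vars) {
    for (i in which(is.na(table[[v]]))) {
      d <- rep(Inf, n)
      for (j in seq_len(n)) {
        if (j != i && !is.na(table[[v]][j])) d[j] <- dist_ij(i, j)
      }
      nb <- order(d)[seq_len(k)]
      nb <- nb[is.finite(d[nb])]
      if (length(nb) == 0) next
      vals <- table[[v]][nb]
      out[[v]][i] <- if (v %in% num_vars) mean(vals) else {
        tab <- table(vals)
        names(tab)[which.max(tab)]
      }
    }
  }
  out
}
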