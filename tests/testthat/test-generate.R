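test_that("a degenerate profile yields exactly one contiguous sleep block at the configured onset", {
  prof <- degenerate_profile(onset = 23 * 60, dur = 480)
  s <- generate_trace(prof, days = 1, seed = 1)
  expect_length(s$labels, 2880L)
  bouts <- extract_bouts(s)
  sleep <- bouts[bouts$activity == "sleep", ]
  expect_equal(nrow(sleep), 1L)
  expect_equal(sleep$length, 960L)
  # trace starts at noon, so 23:00 is 11 h = 1320 epochs in (0-based)
  expect_equal(sleep$start, 1320L)
})

test_that("trace generation is deterministic in the seed and conserves length", {
  prof <- control_profile()
  a <- generate_trace(prof, days = 3, seed = 7)
  b <- generate_trace(prof, days = 3, seed = 7)
  c <- generate_trace(prof, days = 3, seed = 8)
  expect_identical(a$labels, b$labels)
  expect_false(identical(a$labels, c$labels))
  expect_length(a$labels, 3L * 2880L)
  expect_error(generate_trace(prof, days = 0, seed = 1), "days")
})

test_that("empirical occupancy recovers the configured activity mix", {
  prof <- control_profile()
  shares <- sapply(1:60, function(sd) {
    s <- generate_trace(prof, days = 2, seed = sd)
    tab <- table(factor(s$labels, levels = activity_levels()))
    as.numeric(tab / sum(tab))
  })
  mix <- rowMeans(shares) * 100
  names(mix) <- activity_levels()
  # direct epoch-count oracle vs the configured marginals, 2 pp tolerance
  expect_lt(abs(mix[["sleep"]] - 38), 2)
  expect_lt(abs(mix[["sedentary"]] - 42), 2)
  expect_lt(abs(mix[["walking"]] - 10), 2)
})

test_that("missing epochs appear at the configured completely-at-random rate", {
  prof <- control_profile(missing_rate = 0.1)
  s <- generate_trace(prof, days = 7, seed = 3)
  rate <- mean(s$labels == missing_label())
  expect_lt(abs(rate - 0.1), 3 * sqrt(0.1 * 0.9 / length(s$labels)) + 0.005)
})

test_that("population generation produces exact group counts and one shared id set", {
  cfg <- population_config(n_t2d = 8, n_control = 10, n_impaired_control = 4,
                           days = 1, seed = 99)
  pop <- generate_population(cfg)
  expect_equal(unname(table(pop$labels$group)[c("t2d", "control", "impaired_control")]),
               c(8L, 10L, 4L), ignore_attr = TRUE)
  ids <- pop$labels$participant_id
  expect_setequal(names(pop$traces), ids)
  expect_setequal(pop$demographics$participant_id, ids)
  expect_setequal(pop$selfreport$participant_id, ids)
  expect_setequal(pop$wear$participant_id, ids)
  expect_true(all(pop$ehr$participant_id %in% ids))
  expect_true(all(vapply(pop$traces, length, integer(1)) == 2880L))

  # all-controls config
  cfg0 <- population_config(n_t2d = 0, n_control = 3, n_impaired_control = 0,
                            days = 1, seed = 5)
  pop0 <- generate_population(cfg0)
  expect_equal(nrow(pop0$labels), 3L)
  expect_true(all(pop0$labels$group == "control"))
})

test_that("identical config and seed give a byte-identical population", {
  cfg <- population_config(n_t2d = 3, n_control = 3, n_impaired_control = 2,
                           days = 1, seed = 123)
  expect_identical(serialize(generate_population(cfg), NULL),
                   serialize(generate_population(cfg), NULL))
})

test_that("T2D effect multipliers lengthen sedentary bouts", {
  ctrl <- control_profile()
  case <- t2d_profile(ctrl)
  mean_sed_len <- function(prof, seeds) {
    mean(sapply(seeds, function(sd) {
      b <- extract_bouts(generate_trace(prof, days = 2, seed = sd))
      mean(b$length[b$activity == "sedentary"])
    }))
  }
  x <- sapply(1:40, function(sd) {
    b <- extract_bouts(generate_trace(ctrl, days = 2, seed = sd))
    mean(b$length[b$activity == "sedentary"])
  })
  y <- sapply(101:140, function(sd) {
    b <- extract_bouts(generate_trace(case, days = 2, seed = sd))
    mean(b$length[b$activity == "sedentary"])
  })
  expect_lt(t.test(y, x, alternative = "greater")$p.value, 0.01)
})

test_that("null multipliers leave the case profile identical to the control profile", {
  ctrl <- control_profile()
  null_prof <- apply_multipliers(ctrl, list())
  expect_identical(null_prof, ctrl)
})

test_that("EHR generation honours group construction contracts", {
  cfg <- population_config(n_t2d = 6, n_control = 30, n_impaired_control = 6,
                           days = 1, seed = 17)
  pop <- generate_population(cfg)
  map <- default_severity_map()
  sev <- setNames(map$severity, map$class)
  win <- dplyr::transmute(
    pop$wear, participant_id,
    w0 = lubridate::add_with_rollback(wear_start, -lubridate::period(6, "months")),
    w1 = lubridate::add_with_rollback(wear_end, lubridate::period(1, "months"))
  )
  ev <- dplyr::left_join(pop$ehr, win, by = "participant_id")
  ev$in_window <- ev$date >= ev$w0 & ev$date <= ev$w1
  ev$severity <- sev[ev$class]

  for (id in pop$labels$participant_id[pop$labels$group == "impaired_control"]) {
    e <- ev[ev$participant_id == id & ev$in_window, ]
    expect_gte(sum(e$severity == 2), 1)
  }
  for (id in pop$labels$participant_id[pop$labels$group == "control"]) {
    e <- ev[ev$participant_id == id & ev$in_window, ]
    expect_true(all(e$severity == 0))
  }
})

test_that("in-window benign event counts follow the configured Poisson rate", {
  lambda <- 0.9
  cfg <- population_config(n_t2d = 0, n_control = 400, n_impaired_control = 0,
                           days = 1, seed = 31, ehr_rate_benign = lambda,
                           ehr_rate_outwindow = 0)
  labels <- tibble::tibble(participant_id = sprintf("P%04d", 1:400),
                           group = "control")
  wear <- boutwise:::generate_wear_periods(labels$participant_id, seed = 2)
  ehr <- generate_ehr(cfg, labels, wear, selfreport = NULL, seed = 44)
  counts <- table(factor(ehr$participant_id, levels = labels$participant_id))
  m <- mean(counts)
  se <- sqrt(lambda / 400)
  expect_lt(abs(m - lambda), 3 * se)
})

test_that("zero benign event rate yields an event-free control stream", {
  cfg <- population_config(n_t2d = 0, n_control = 10, n_impaired_control = 0,
                           days = 1, seed = 3, ehr_rate_benign = 0,
                           ehr_rate_outwindow = 0)
  pop <- generate_population(cfg)
  expect_equal(nrow(pop$ehr), 0L)
})

test_that("invalid profiles and configs are rejected", {
  expect_error(control_profile(missing_rate = 1), "missing_rate")
  expect_error(
    activity_profile(
      occupancy = c(sedentary = 0.5, moderate = 0.2, walking = 0.2,
                    light_tasks = 0.2),
      bout_len_mean = c(sedentary = 10, moderate = 5, walking = 4,
                        light_tasks = 5)
    ),
    "sum to 1"
  )
  expect_error(population_config(n_t2d = -1), "counts")
})
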