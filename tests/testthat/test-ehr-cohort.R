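mk_wear <- function(ids, wear_start = as.Date("2015-06-01")) {
  tibble::tibble(
    participant_id = ids,
    assessment_date = wear_start - 500,
    wear_start = wear_start,
    wear_end = wear_start + 7
  )
}

mk_selfreport <- function(ids, diagnosed = FALSE, insulin = NA,
                          age_dx = NA_real_) {
  tibble::tibble(
    participant_id = ids,
    diabetes_diagnosed = diagnosed,
    insulin_first_year = insulin,
    age_at_diagnosis = age_dx,
    assessment_date = as.Date("2014-01-17")
  )
}

empty_ehr <- tibble::tibble(
  participant_id = character(), date = as.Date(character()),
  code = character(), class = character()
)

test_that("self-report, insulin and age rules classify T2D status", {
  wear <- mk_wear("A")
  # insulin within first year and diagnosed under 35 -> excluded
  sr <- mk_selfreport("A", diagnosed = TRUE, insulin = TRUE, age_dx = 34)
  expect_equal(identify_t2d(sr, empty_ehr, wear)$t2d_status, "excluded")
  # age 35 at diagnosis is not excluded
  sr35 <- mk_selfreport("A", diagnosed = TRUE, insulin = TRUE, age_dx = 35)
  expect_equal(identify_t2d(sr35, empty_ehr, wear)$t2d_status, "positive")
  # insulin but older: positive
  sr2 <- mk_selfreport("A", diagnosed = TRUE, insulin = FALSE, age_dx = 34)
  expect_equal(identify_t2d(sr2, empty_ehr, wear)$t2d_status, "positive")
  # no self-report, no codes: negative
  sr3 <- mk_selfreport("A")
  expect_equal(identify_t2d(sr3, empty_ehr, wear)$t2d_status, "negative")
})

test_that("incident codes between assessment and wear start are positive", {
  wear <- mk_wear("A")
  sr <- mk_selfreport("A")
  incident <- tibble::tibble(
    participant_id = "A", date = as.Date("2015-01-10"),
    code = "C10F.", class = "t2d_incident"
  )
  expect_equal(identify_t2d(sr, incident, wear)$t2d_status, "positive")

  # dated after wear start: not incident
  late <- dplyr::mutate(incident, date = wear$wear_start + 5)
  expect_equal(identify_t2d(sr, late, wear)$t2d_status, "negative")
  # dated before assessment: not incident
  early <- dplyr::mutate(incident, date = sr$assessment_date - 5)
  expect_equal(identify_t2d(sr, early, wear)$t2d_status, "negative")
})

test_that("missing dates flag a participant unresolvable", {
  wear <- mk_wear("A")
  wear$wear_start <- as.Date(NA)
  sr <- mk_selfreport("A")
  expect_equal(identify_t2d(sr, empty_ehr, wear)$t2d_status, "unresolvable")
})

test_that("severity scoring averages in-window severities only", {
  wear <- mk_wear("A")
  expect_equal(severity_score(empty_ehr, wear)$score, 0)
  expect_equal(severity_score(empty_ehr, wear)$band, "Norm-0")

  one <- tibble::tibble(participant_id = "A", date = wear$wear_start - 10,
                        code = "G66..", class = "stroke")
  s1 <- severity_score(one, wear)
  expect_equal(s1$score, 2)
  expect_equal(s1$band, "Norm-2")

  # severities {2, 1, 0} in-window and {2, 2} out-of-window -> mean 1.0
  ev <- tibble::tibble(
    participant_id = "A",
    date = c(wear$wear_start - 10, wear$wear_start - 20, wear$wear_end + 20,
             wear$wear_start - 400, wear$wear_start - 300),
    class = c("stroke", "back_pain", "routine_checkup", "stroke",
              "hip_fracture")
  )
  ev$code <- "X"
  s <- severity_score(ev, wear)
  expect_equal(s$score, 1.0)
  expect_equal(s$n_events, 3L)
  expect_equal(s$band, "Norm-1")
})

test_that("severity scoring matches a brute-force date-filter oracle", {
  set.seed(5)
  map <- default_severity_map()
  sev <- setNames(map$severity, map$class)
  for (i in 1:300) {
    wear <- mk_wear("A", wear_start = as.Date("2015-01-01") + sample.int(400, 1))
    k <- sample.int(12, 1)
    ev <- tibble::tibble(
      participant_id = "A",
      date = wear$wear_start + sample(-400:100, k, replace = TRUE),
      code = "X",
      class = sample(map$class[!map$t2d_code], k, replace = TRUE)
    )
    got <- severity_score(ev, wear)$score
    # oracle: explicit loop over events with the documented window bounds
    w0 <- lubridate::add_with_rollback(wear$wear_start,
                                       -lubridate::period(6, "months"))
    w1 <- lubridate::add_with_rollback(wear$wear_end,
                                       lubridate::period(1, "months"))
    vals <- c()
    for (j in seq_len(k)) {
      if (ev$date[j] >= w0 && ev$date[j] <= w1) vals <- c(vals, sev[ev$class[j]])
    }
    want <- if (length(vals) == 0) 0 else mean(vals)
    expect_equal(got, unname(want))
  }
})

test_that("band thresholds are half-open with inclusive upper band", {
  expect_equal(assign_band(0), "Norm-0")
  expect_equal(assign_band(0.49999), "Norm-0")
  expect_equal(assign_band(0.5), "Norm-1")
  expect_equal(assign_band(1.49999), "Norm-1")
  expect_equal(assign_band(1.5), "Norm-2")
  expect_equal(assign_band(2), "Norm-2")
  expect_error(assign_band(2.3), "out of")
})

test_that("cohort assembly partitions every participant exactly once", {
  cfg <- population_config(n_t2d = 10, n_control = 20, n_impaired_control = 8,
                           days = 1, seed = 77)
  pop <- generate_population(cfg)
  cohort <- build_cohort(pop$selfreport, pop$ehr, pop$wear)
  expect_equal(nrow(cohort), 38L)
  expect_equal(anyDuplicated(cohort$participant_id), 0L)
  expect_false(anyNA(cohort$label))
  expect_equal(sum(table(cohort$label)), 38L)

  truth <- pop$labels$group[match(cohort$participant_id,
                                  pop$labels$participant_id)]
  # noise-free severity classes: impaired controls all land in Norm-2,
  # clean controls in Norm-0, and every generated case is identified
  expect_true(all(cohort$label[truth == "impaired_control"] == "Norm-2"))
  expect_true(all(cohort$label[truth == "control"] == "Norm-0"))
  expect_true(all(cohort$label[truth == "t2d"] == "T2D"))
})

test_that("training sets half-sample Norm-0 and keep impaired cases", {
  assignments <- tibble::tibble(
    participant_id = c(sprintf("T%02d", 1:10), sprintf("N0_%03d", 1:100),
                       sprintf("N1_%02d", 1:5), sprintf("N2_%02d", 1:20)),
    label = rep(c("T2D", "Norm-0", "Norm-1-excluded", "Norm-2"),
                c(10, 100, 5, 20)),
    score = 0, band = "Norm-0", exclusion_reason = NA_character_
  )
  ts <- build_training_sets(assignments, seed = 4)
  expect_equal(sum(ts$ts1$outcome == 0), 50L)   # floor(100 / 2)
  expect_equal(sum(ts$ts1$outcome == 1), 10L)
  expect_equal(sum(ts$ts2$outcome == 0), 20L)
  expect_setequal(ts$ts2$participant_id[ts$ts2$outcome == 1],
                  sprintf("T%02d", 1:10))
  # Norm-1 nowhere
  expect_false(any(grepl("^N1_", c(ts$ts1$participant_id,
                                   ts$ts2$participant_id))))
  # determinism and the explicit sample-size override
  ts_b <- build_training_sets(assignments, seed = 4)
  expect_identical(ts, ts_b)
  ts_o <- build_training_sets(assignments, seed = 4, n_norm0 = 30)
  expect_equal(sum(ts_o$ts1$outcome == 0), 30L)

  expect_error(build_training_sets(assignments[assignments$label != "T2D", ]),
               "no T2D")
})
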