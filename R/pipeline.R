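#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> wear QC -> bout features -> EHR scoring ->
#' cohort -> training sets -> classification grid -> report. Every stage
#' writes its output under `out_dir`, stage-level row counts are logged, and
#' a manifest (config + seed + config hash) makes the run reproducible:
#' rerunning with the same config yields byte-identical tables.
#'
#' @param config A [default_run_config()] list.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with the in-memory stage outputs
#'   (`population`, `features`, `cohort`, `training_sets`, `results`,
#'   `summary`).
#' @export
run_pipeline <- function(config = default_run_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, code) {
    message("[", name, "] ...")
    tryCatch(force(code), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  pop <- stage("simulate", {
    pc <- population_config(
      n_t2d = config$n_t2d, n_control = config$n_control,
      n_impaired_control = config$n_impaired_control,
      days = config$days, seed = config$seed
    )
    generate_population(pc)
  })
  message("[simulate] ", nrow(pop$labels), " participants, ",
          config$days, " days each")
  readr::write_csv(pop$demographics, file.path(out_dir, "demographics.csv"))
  readr::write_csv(pop$ehr, file.path(out_dir, "ehr_events.csv"))
  readr::write_csv(pop$labels, file.path(out_dir, "labels_truth.csv"))
  if (isTRUE(config$write_traces)) {
    write_traces_long(pop$traces, file.path(out_dir, "traces_long.csv.gz"))
  }

  feats <- stage("features", {
    features_table(pop$traces,
                   gap_tolerance_epochs = config$gap_tolerance_epochs,
                   qc_hours = config$qc_hours)
  })
  message("[features] ", nrow(feats$features), "/", length(pop$traces),
          " passed QC")
  readr::write_csv(feats$features, file.path(out_dir, "bout_features.csv"))
  readr::write_csv(feats$qc, file.path(out_dir, "wear_qc.csv"))

  cohort <- stage("cohort", {
    build_cohort(pop$selfreport, pop$ehr, pop$wear,
                 band_thresholds = config$band_thresholds,
                 window_before_months = config$window_before_months,
                 window_after_months = config$window_after_months)
  })
  readr::write_csv(cohort, file.path(out_dir, "cohort.csv"))
  message("[cohort] ", paste(names(table(cohort$label)),
                             table(cohort$label), collapse = ", "))

  tsets <- stage("cohort", build_training_sets(cohort, seed = config$seed))
  readr::write_csv(dplyr::bind_rows(tsets),
                   file.path(out_dir, "training_sets.csv"))

  demo_imp <- stage("impute", {
    impute_knn(pop$demographics, k = config$impute_k)
  })

  results <- stage("train", {
    run_grid(tsets, feats$features, demo_imp,
             algorithms = config$algorithms,
             feature_sets = config$feature_sets,
             folds = config$folds, seed = config$seed,
             mode = config$mode, train_fraction = config$train_fraction)
  })

  summ <- stage("report", {
    s <- grid_summary(results)
    readr::write_csv(s$auc, file.path(out_dir, "results_auc.csv"))
    readr::write_csv(s$f1, file.path(out_dir, "results_f1.csv"))
    readr::write_csv(s$long, file.path(out_dir, "results_long.csv"))
    roc <- purrr::map_dfr(results, function(r) {
      dplyr::mutate(r$roc_points, training_set = r$training_set,
                    feature_set = r$feature_set, algorithm = r$algorithm)
    })
    readr::write_csv(roc, file.path(out_dir, "roc_points.csv"))
    groups <- split(
      feats$features,
      pop$labels$group[match(feats$features$participant_id,
                             pop$labels$participant_id)]
    )
    write_distribution_report(groups, out_dir)
    s
  })

  manifest <- list(
    config = unclass(config),
    seed = config$seed,
    config_hash = config_hash(config),
    n_participants = nrow(pop$labels),
    n_models = length(results)
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(list(population = pop, features = feats, cohort = cohort,
                 training_sets = tsets, results = results, summary = summ))
}

## Stable fingerprint of a config: serialized YAML fed through a modular
## polynomial hash (no extra digest dependency needed for a manifest).
config_hash <- function(config) {
  bytes <- utf8ToInt(yaml::as.yaml(unclass(config)))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}

#' Distribution report of sleep bout features by group
#'
#' Writes binned histogram counts (CSV) and plots for three daily-average
#' sleep summaries per group: percentage of the 24-h day asleep, mean sleep
#' bout length, and number of sleep bouts. Bin breaks are shared across
#' groups so the histograms are comparable; per group, bin counts sum to
#' group size.
#'
#' @param groups Named list (>= 2 entries) of bout-feature tibbles
#'   ([features_table()]`$features`), one per population group.
#' @param out_dir Output directory.
#' @param bins Number of bins (default 20).
#' @return Invisibly, the histogram tibble.
#' @export
write_distribution_report <- function(groups, out_dir, bins = 20) {
  if (length(groups) < 2) stop("write_distribution_report: need >= 2 groups")
  if (any(vapply(groups, nrow, integer(1)) == 0)) {
    stop("write_distribution_report: empty group")
  }
  summaries <- purrr::imap_dfr(groups, function(f, g) {
    occ <- occupancy_24h(f)
    sleep_pct <- occ$occupancy_pct[occ$activity == "sleep"]
    tibble::tibble(
      group = g,
      participant_id = f$participant_id,
      sleep_pct = sleep_pct,
      sleep_bout_len = f$sleep_sleep_mean_len,
      sleep_bouts = f$sleep_sleep_n_bouts + f$sleep_morning_n_bouts +
        f$sleep_afternoon_n_bouts + f$sleep_evening_n_bouts
    )
  })
  hist_tbl <- purrr::map_dfr(
    c("sleep_pct", "sleep_bout_len", "sleep_bouts"),
    function(v) {
      x <- summaries[[v]]
      breaks <- seq(min(x), max(x), length.out = bins + 1)
      breaks[1] <- breaks[1] - 1e-9
      purrr::imap_dfr(split(summaries[[v]], summaries$group), function(xs, g) {
        counts <- as.integer(table(cut(xs, breaks, include.lowest = TRUE)))
        tibble::tibble(
          feature = v, group = g,
          bin_lo = utils::head(breaks, -1), bin_hi = breaks[-1],
          count = counts
        )
      })
    }
  )
  readr::write_csv(hist_tbl, file.path(out_dir, "distributions.csv"))
  p <- ggplot2::ggplot(
    tidyr::pivot_longer(summaries, c("sleep_pct", "sleep_bout_len",
                                     "sleep_bouts")),
    ggplot2::aes(x = .data$value, fill = .data$group)
  ) +
    ggplot2::geom_histogram(bins = bins, alpha = 0.6,
                            position = "identity") +
    ggplot2::facet_wrap(~name, scales = "free") +
    ggplot2::labs(x = NULL, y = "participants") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(file.path(out_dir, "distributions.png"), p,
                  width = 9, height = 3.2, dpi = 120)
  invisible(hist_tbl)
}
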