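# Small separable-ish synthetic matrix shared by several blocks.
make_xy <- function(n = 80, p = 6, delta = 2, seed = 1) {
  set.seed(seed)
  y <- rep(c(0L, 1L), each = n / 2)
  X <- matrix(rnorm(n * p), n, p) + delta * y
  colnames(X) <- paste0("f", seq_len(p))
  rownames(X) <- sprintf("r%03d", seq_len(n))
  list(X = X, y = y)
}

test_that("feature assembly produces the documented column sets", {
  cfg <- population_config(n_t2d = 6, n_control = 6, n_impaired_control = 0,
                           days = 1, seed = 50, demo_missing_rate = 0)
  pop <- generate_population(cfg)
  # 1-day traces skip QC here; build the feature table directly
  rows <- lapply(pop$traces, function(s) {
    fx <- extract_features(s)
    row <- tibble::as_tibble(as.list(fx$features))
    row$participant_id <- s$participant_id
    row
  })
  feats <- dplyr::bind_rows(rows)

  act <- assemble_features(feats, pop$demographics, "activity_only")
  expect_equal(ncol(act), 60L)
  expect_identical(colnames(act), feature_names())

  socio <- assemble_features(feats, pop$demographics, "socio_only")
  expect_equal(ncol(socio), 17L)  # 9 numeric + (1 + 3 + 2 + 2) dummies

  comb <- assemble_features(feats, pop$demographics, "combined")
  expect_setequal(colnames(comb), union(colnames(act), colnames(socio)))
  expect_equal(nrow(comb), 12L)
  expect_false(anyNA(comb))

  expect_error(
    assemble_features(feats, pop$demographics, "combined", ids = "nobody"),
    "absent"
  )
})

test_that("cross-validation separates separable data and not permuted labels", {
  d <- make_xy(n = 80, delta = 2.5)
  for (alg in c("random_forest", "logistic_regression", "gradient_boosting")) {
    r <- crossval_eval(d$X, d$y, alg, folds = 5, seed = 3)
    expect_gte(r$auc, 0.99)
  }
  set.seed(9)
  y_perm <- sample(d$y)
  r0 <- crossval_eval(d$X, y_perm, "logistic_regression", folds = 10, seed = 3)
  expect_lt(abs(r0$auc - 0.5), 3 * r0$auc_se + 1e-12)
})

test_that("reported AUCs equal a hand-coded rank-based oracle per fold", {
  d <- make_xy(n = 60, delta = 1)
  r <- crossval_eval(d$X, d$y, "logistic_regression", folds = 6, seed = 11)
  for (f in seq_len(6)) {
    pr <- r$predictions[r$predictions$fold == f, ]
    expect_equal(r$auc_by_fold[f], auc_oracle(pr$y, pr$p), tolerance = 1e-12)
  }
  expect_equal(r$auc, mean(r$auc_by_fold), tolerance = 1e-12)
})

test_that("per-class metrics recompute from stored predictions and F1 is the harmonic mean", {
  d <- make_xy(n = 70, delta = 1, seed = 4)
  r <- crossval_eval(d$X, d$y, "gradient_boosting", folds = 7, seed = 2)
  cm <- r$class_metrics
  pr <- r$predictions
  for (cls in c(1L, 0L)) {
    yhat <- as.integer(pr$p >= 0.5)
    tp <- sum(yhat == cls & pr$y == cls)
    prec <- tp / sum(yhat == cls)
    rec <- tp / sum(pr$y == cls)
    row <- cm[cm$class == as.character(cls), ]
    expect_equal(row$precision, prec, tolerance = 1e-12)
    expect_equal(row$recall, rec, tolerance = 1e-12)
    expect_equal(row$f1, 2 * prec * rec / (prec + rec), tolerance = 1e-12)
  }
})

test_that("cross-validation is deterministic under a fixed seed", {
  d <- make_xy(n = 60, delta = 1)
  for (alg in c("random_forest", "logistic_regression", "gradient_boosting")) {
    a <- crossval_eval(d$X, d$y, alg, folds = 5, seed = 21)
    b <- crossval_eval(d$X, d$y, alg, folds = 5, seed = 21)
    expect_identical(a$auc_by_fold, b$auc_by_fold)
    expect_identical(a$predictions, b$predictions)
  }
})

test_that("the stratified holdout keeps the 80:20 ratio and is reproducible", {
  d <- make_xy(n = 100, delta = 1.5)
  r <- holdout_eval(d$X, d$y, "logistic_regression", train_fraction = 0.8,
                    seed = 6)
  expect_equal(r$n, 20L)
  expect_equal(sum(r$predictions$y == 1), 10L)  # stratified
  r2 <- holdout_eval(d$X, d$y, "logistic_regression", train_fraction = 0.8,
                     seed = 6)
  expect_identical(r$predictions, r2$predictions)
  expect_equal(r$pooled_auc, auc_oracle(r$predictions$y, r$predictions$p),
               tolerance = 1e-12)
})

test_that("degenerate single-class inputs are rejected", {
  d <- make_xy(n = 20, delta = 1)
  expect_error(crossval_eval(d$X, rep(1L, 20), "random_forest"), "both classes")
  expect_error(holdout_eval(d$X, rep(0L, 20), "random_forest"), "both classes")
})

test_that("the grid emits the full tagged Cartesian product in fixed order", {
  cfg <- population_config(n_t2d = 15, n_control = 40, n_impaired_control = 10,
                           days = 1, seed = 60, demo_missing_rate = 0)
  pop <- generate_population(cfg)
  rows <- lapply(pop$traces, function(s) {
    fx <- extract_features(s)
    row <- tibble::as_tibble(as.list(fx$features))
    row$participant_id <- s$participant_id
    row
  })
  feats <- dplyr::bind_rows(rows)
  cohort <- build_cohort(pop$selfreport, pop$ehr, pop$wear)
  tsets <- build_training_sets(cohort, seed = 1)

  res <- run_grid(tsets, feats, pop$demographics, folds = 3, seed = 8)
  expect_length(res, 18L)
  tags <- t(vapply(res, function(r) c(r$training_set, r$feature_set,
                                      r$algorithm), character(3)))
  got <- apply(tags, 1, paste, collapse = "|")
  want <- apply(
    expand.grid(c("random_forest", "logistic_regression", "gradient_boosting"),
                c("activity_only", "socio_only", "combined"),
                c("TS1", "TS2"))[, 3:1],
    1, paste, collapse = "|"
  )
  expect_identical(sort(got), sort(want))
  # documented nesting order: training set outermost, algorithm innermost
  expect_identical(got[1:3], paste("TS1", "activity_only",
                                   c("random_forest", "logistic_regression",
                                     "gradient_boosting"), sep = "|"))

  # restricting to one training set yields 9 results
  res9 <- run_grid(tsets["ts1"], feats, pop$demographics, folds = 3, seed = 8)
  expect_length(res9, 9L)

  summ <- grid_summary(res)
  expect_equal(nrow(summ$long), 18L)
  expect_equal(dim(summ$auc), c(3L, 7L))
})
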