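ALGORITHMS <- c("random_forest", "logistic_regression", "gradient_boosting")
FEATURE_SETS <- c("activity_only", "socio_only", "combined")

## Documented categorical levels of the covariate table; first level is the
## dropped reference in one-hot encoding.
demo_levels <- function() {
  list(
    sex = c("Female", "Male"),
    ethnic_group = c("White", "Asian", "Black", "Other"),
    alcohol_status = c("Never", "Previous", "Current"),
    smoking_status = c("Never", "Previous", "Current")
  )
}

#' Assemble a model matrix for one feature set
#'
#' Builds the numeric design matrix for `activity_only` (the 60 bout
#' features), `socio_only` (the 13 covariates, categoricals one-hot encoded
#' with the reference level dropped: 9 numeric + 8 dummy = 17 columns) or
#' `combined` (their union, 77 columns). Tables must be id-aligned; rows are
#' matched on `participant_id`.
#'
#' @param features Bout feature tibble ([features_table()]`$features`).
#' @param demographics Imputed covariate tibble ([impute_knn()]).
#' @param feature_set One of `"activity_only"`, `"socio_only"`, `"combined"`.
#' @param ids Participant ids to include (default: all shared ids).
#' @return Numeric matrix with participant ids as rownames.
#' @export
assemble_features <- function(features, demographics,
                              feature_set = c("combined", "activity_only",
                                              "socio_only"),
                              ids = NULL) {
  feature_set <- match.arg(feature_set)
  if (is.null(ids)) {
    ids <- intersect(features$participant_id, demographics$participant_id)
  }
  missing_ids <- setdiff(
    ids, switch(feature_set,
                activity_only = features$participant_id,
                socio_only = demographics$participant_id,
                combined = intersect(features$participant_id,
                                     demographics$participant_id))
  )
  if (length(missing_ids) > 0) {
    stop("assemble_features: id(s) absent from input tables: ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  }

  act <- function() {
    m <- as.matrix(features[match(ids, features$participant_id),
                            feature_names()])
    rownames(m) <- ids
    m
  }
  socio <- function() {
    d <- demographics[match(ids, demographics$participant_id), ]
    if (anyNA(d[demographic_columns()])) {
      stop("assemble_features: covariates contain missing values; impute first")
    }
    lv <- demo_levels()
    num <- setdiff(demographic_columns(), names(lv))
    m <- as.matrix(d[num])
    for (v in names(lv)) {
      for (level in lv[[v]][-1]) {
        m <- cbind(m, as.numeric(d[[v]] == level))
        colnames(m)[ncol(m)] <- paste(v, level, sep = "_")
      }
    }
    rownames(m) <- ids
    m
  }
  switch(feature_set,
         activity_only = act(),
         socio_only = socio(),
         combined = cbind(act(), socio()))
}

## Stratified fold ids: classes are split separately so every fold holds
## both classes (as evenly as possible).
stratified_folds <- function(y, folds, seed) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
    fold
  })
}

fit_predict <- function(X_train, y_train, X_test, algorithm, seed) {
  set.seed(seed)
  if (algorithm == "random_forest") {
    fit <- randomForest::randomForest(x = X_train, y = factor(y_train,
                                                              levels = c(0, 1)))
    stats::predict(fit, X_test, type = "prob")[, "1"]
  } else if (algorithm == "logistic_regression") {
    ## z-score using training-fold statistics only (no leakage); ridge
    ## penalty matched to the common library default (inverse-regularization
    ## strength C = 1, i.e. lambda = 1/n in glmnet's parameterization)
    mu <- colMeans(X_train)
    sdev <- apply(X_train, 2, stats::sd)
    sdev[sdev == 0] <- 1
    Ztr <- scale(X_train, mu, sdev)
    Zte <- scale(X_test, mu, sdev)
    fit <- suppressWarnings(  # small-class warning on tiny demo folds
      glmnet::glmnet(Ztr, y_train, family = "binomial", alpha = 0,
                     lambda = 1 / nrow(Ztr), standardize = FALSE)
    )
    as.numeric(stats::predict(fit, Zte, type = "response"))
  } else if (algorithm == "gradient_boosting") {
    fit <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", nthread = 1,
                    seed = seed %% .Machine$integer.max),
      data = xgboost::xgb.DMatrix(X_train, label = y_train, nthread = 1),
      nrounds = 100, verbose = 0
    )
    stats::predict(fit, xgboost::xgb.DMatrix(X_test, nthread = 1))
  } else {
    stop("unknown algorithm: ", algorithm)
  }
}

auc_score <- function(y, p) {
  as.numeric(pROC::auc(pROC::roc(
    response = y, predictor = p, levels = c(0, 1), direction = "<",
    quiet = TRUE
  )))
}

## Precision / recall / F1 for both classes at a 0.5 threshold.
## F1 is the harmonic mean of the reported precision and recall by
## construction. Undefined ratios (empty denominator) report 0.
class_metrics <- function(y, p, threshold = 0.5) {
  yhat <- as.integer(p >= threshold)
  one <- function(cls) {
    tp <- sum(yhat == cls & y == cls)
    precision <- if (sum(yhat == cls) > 0) tp / sum(yhat == cls) else 0
    recall <- if (sum(y == cls) > 0) tp / sum(y == cls) else 0
    f1 <- if (precision + recall > 0) {
      2 * precision * recall / (precision + recall)
    } else 0
    tibble::tibble(class = as.character(cls), precision = precision,
                   recall = recall, f1 = f1)
  }
  dplyr::bind_rows(one(1L), one(0L))
}

new_eval_result <- function(algorithm, mode, auc_by_fold, pooled_y, pooled_p,
                            seed, folds, fold_of = NULL,
                            feature_set = NA_character_,
                            training_set = NA_character_) {
  se <- stats::sd(auc_by_fold) / sqrt(length(auc_by_fold))
  roc <- pROC::roc(response = pooled_y, predictor = pooled_p,
                   levels = c(0, 1), direction = "<", quiet = TRUE)
  structure(
    list(
      algorithm = algorithm,
      feature_set = feature_set,
      training_set = training_set,
      mode = mode,
      auc = mean(auc_by_fold),
      auc_se = se,
      auc_ci = mean(auc_by_fold) + c(-1, 1) * 1.96 * se,
      auc_by_fold = auc_by_fold,
      pooled_auc = as.numeric(pROC::auc(roc)),
      class_metrics = class_metrics(pooled_y, pooled_p),
      roc_points = tibble::tibble(
        fpr = rev(1 - roc$specificities), tpr = rev(roc$sensitivities)
      ),
      predictions = tibble::tibble(
        fold = if (is.null(fold_of)) rep(1L, length(pooled_y)) else fold_of,
        y = pooled_y, p = pooled_p
      ),
      n = length(pooled_y),
      folds = folds,
      seed = seed
    ),
    class = "eval_result"
  )
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf(
    "<eval_result> %s | %s | %s (%s): AUC %.3f (95%% CI %.3f-%.3f), n=%d\n",
    x$training_set, x$feature_set, x$algorithm, x$mode,
    x$auc, x$auc_ci[1], x$auc_ci[2], x$n
  ))
  print(as.data.frame(x$class_metrics), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Cross-validated evaluation of one classifier
#'
#' Stratified k-fold cross-validation: per-fold AUC on the held-out fold,
#' reported as the fold mean with a normal-approximation 95% CI
#' (mean ± 1.96 SE over folds). Per-class precision/recall/F1 and the ROC
#' curve are computed from the pooled held-out predictions, so F1 is exactly
#' the harmonic mean of the reported precision and recall.
#'
#' @param X Numeric model matrix.
#' @param y Binary outcome vector (0/1), aligned to `X` rows.
#' @param algorithm `"random_forest"`, `"logistic_regression"` or
#'   `"gradient_boosting"`.
#' @param folds Number of folds (default 10).
#' @param seed Integer seed (folds and fits).
#' @return An `eval_result` object.
#' @export
crossval_eval <- function(X, y, algorithm = ALGORITHMS, folds = 10, seed = 1) {
  algorithm <- match.arg(algorithm)
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("crossval_eval: both classes required")
  fold <- stratified_folds(y, folds, seed)
  fit_seeds <- spawn_seeds(seed, folds)
  auc_by_fold <- numeric(folds)
  pooled_p <- numeric(length(y))
  for (f in seq_len(folds)) {
    te <- fold == f
    p <- fit_predict(X[!te, , drop = FALSE], y[!te], X[te, , drop = FALSE],
                     algorithm, fit_seeds[f])
    pooled_p[te] <- p
    auc_by_fold[f] <- auc_score(y[te], p)
  }
  new_eval_result(algorithm, "cv", auc_by_fold, y, pooled_p, seed, folds,
                  fold_of = fold)
}

#' Single stratified holdout evaluation
#'
#' One stratified train/test split (default 80:20); AUC, per-class metrics
#' and the ROC curve are computed on the held-out test set. The AUC CI is
#' not available from a single split and is reported as `NA`.
#'
#' @inheritParams crossval_eval
#' @param train_fraction Fraction of each class used for training.
#' @return An `eval_result` object (`mode = "holdout"`).
#' @export
holdout_eval <- function(X, y, algorithm = ALGORITHMS, train_fraction = 0.8,
                         seed = 1) {
  algorithm <- match.arg(algorithm)
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("holdout_eval: both classes required")
  test <- with_seed(seed, {
    te <- logical(length(y))
    for (cl in unique(y)) {
      idx <- which(y == cl)
      n_te <- round((1 - train_fraction) * length(idx))
      te[sample(idx, n_te)] <- TRUE
    }
    te
  })
  p <- fit_predict(X[!test, , drop = FALSE], y[!test],
                   X[test, , drop = FALSE], algorithm,
                   spawn_seeds(seed, 1))
  res <- new_eval_result(algorithm, "holdout", auc_score(y[test], p),
                         y[test], p, seed, folds = 1L)
  res$auc_se <- NA_real_
  res$auc_ci <- c(NA_real_, NA_real_)
  res
}

#' Run the full 18-model classification grid
#'
#' Trains and evaluates every combination of 2 training sets (TS1: cases vs
#' half-sampled Norm-0; TS2: cases vs Norm-2) x 3 feature sets
#' (activity_only, socio_only, combined) x 3 algorithms (random forest,
#' logistic regression, gradient boosting), in that nesting order
#' (training set outermost, algorithm innermost).
#'
#' @param training_sets List with tibbles `ts1`, `ts2`
#'   ([build_training_sets()]).
#' @param features Bout feature tibble.
#' @param demographics Imputed covariate tibble.
#' @param algorithms,feature_sets Optional subsets of the grid axes.
#' @param folds CV folds.
#' @param seed Master seed; each grid cell gets its own spawned sub-seed.
#' @param mode `"cv"` (headline, fold-averaged AUC) or `"holdout"` (80:20).
#' @param train_fraction Holdout training fraction.
#' @return List of `eval_result` objects (18 for the full grid), tagged with
#'   `training_set` and `feature_set`.
#' @export
run_grid <- function(training_sets, features, demographics,
                     algorithms = ALGORITHMS, feature_sets = FEATURE_SETS,
                     folds = 10, seed = 1, mode = c("cv", "holdout"),
                     train_fraction = 0.8) {
  mode <- match.arg(mode)
  algorithms <- match.arg(algorithms, ALGORITHMS, several.ok = TRUE)
  feature_sets <- match.arg(feature_sets, FEATURE_SETS, several.ok = TRUE)
  tags <- toupper(names(training_sets))
  if (is.null(tags) || !all(tags %in% c("TS1", "TS2"))) {
    stop("run_grid: training_sets must be a named list with elements ts1/ts2")
  }
  cells <- expand.grid(
    algorithm = algorithms, feature_set = feature_sets,
    training_set = tags, stringsAsFactors = FALSE
  )[, c("training_set", "feature_set", "algorithm")]
  cell_seeds <- spawn_seeds(seed, nrow(cells))
  results <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    ts <- training_sets[[which(tags == cells$training_set[i])]]
    ids <- ts$participant_id
    X <- tryCatch(
      assemble_features(features, demographics, cells$feature_set[i],
                        ids = intersect(
                          ids, intersect(features$participant_id,
                                         demographics$participant_id)
                        )),
      error = function(e) {
        stop("run_grid failed at cell [", cells$training_set[i], ", ",
             cells$feature_set[i], ", ", cells$algorithm[i], "]: ",
             conditionMessage(e))
      }
    )
    y <- ts$outcome[match(rownames(X), ts$participant_id)]
    r <- if (mode == "cv") {
      crossval_eval(X, y, cells$algorithm[i], folds, cell_seeds[i])
    } else {
      holdout_eval(X, y, cells$algorithm[i], train_fraction, cell_seeds[i])
    }
    r$training_set <- cells$training_set[i]
    r$feature_set <- cells$feature_set[i]
    results[[i]] <- r
  }
  results
}

#' Summarise grid results as tables
#'
#' @param results A [run_grid()] result list.
#' @return List with `auc` (one row per algorithm, one column per
#'   feature set x training set) and `f1` (per class), mirroring the usual
#'   reporting layout, plus `long` (tidy tibble of all metrics).
#' @export
grid_summary <- function(results) {
  long <- purrr::map_dfr(results, function(r) {
    cm <- r$class_metrics
    tibble::tibble(
      training_set = r$training_set, feature_set = r$feature_set,
      algorithm = r$algorithm, mode = r$mode, auc = r$auc,
      auc_lo = r$auc_ci[1], auc_hi = r$auc_ci[2],
      f1_positive = cm$f1[cm$class == "1"],
      f1_negative = cm$f1[cm$class == "0"],
      precision_positive = cm$precision[cm$class == "1"],
      recall_positive = cm$recall[cm$class == "1"],
      n = r$n
    )
  })
  auc <- tidyr::pivot_wider(
    long[, c("algorithm", "feature_set", "training_set", "auc")],
    names_from = c("feature_set", "training_set"), values_from = "auc"
  )
  f1 <- tidyr::pivot_wider(
    tidyr::pivot_longer(
      long[, c("algorithm", "feature_set", "training_set",
               "f1_positive", "f1_negative")],
      c("f1_positive", "f1_negative"),
      names_to = "class", names_prefix = "f1_", values_to = "f1"
    ),
    names_from = c("feature_set", "training_set"), values_from = "f1"
  )
  list(auc = auc, f1 = f1, long = long)
}
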