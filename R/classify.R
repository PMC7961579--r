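#' Random-forest configuration
#'
#' @param n_trees Number of trees (`>= 1`).
#' @param split_criterion Purity measure; only `"gini"` is supported by the
#'   underlying forest implementation.
#' @param mtry Features tried per split; `NULL` means `sqrt(p)`.
#' @param cv_folds Stratified cross-validation folds (`>= 2`).
#' @param cv_repeats Number of CV repetitions.
#' @param positive_class Label treated as positive for sensitivity /
#'   specificity (default the CTC-candidate class).
#' @param n_permutations Permutations per feature for the held-out
#'   permutation importance.
#' @param class_weighting `"none"` or `"balanced"` (inverse class frequency
#'   weights).
#' @param seed Integer seed; the full train/evaluate procedure is
#'   deterministic given `(matrix, config)`.
#' @return A list of class `rf_config`.
#' @export
rf_config <- function(n_trees = 500, split_criterion = "gini", mtry = NULL,
                      cv_folds = 5, cv_repeats = 10,
                      positive_class = "CTC_candidate", n_permutations = 5,
                      class_weighting = c("none", "balanced"), seed = 1) {
  if (n_trees < 1) stop("n_trees must be >= 1")
  if (cv_folds < 2) stop("cv_folds must be >= 2")
  if (cv_repeats < 1) stop("cv_repeats must be >= 1")
  if (!identical(split_criterion, "gini")) {
    stop("only the 'gini' split criterion is supported")
  }
  class_weighting <- match.arg(class_weighting)
  structure(
    list(
      n_trees = as.integer(n_trees), split_criterion = split_criterion,
      mtry = mtry, cv_folds = as.integer(cv_folds),
      cv_repeats = as.integer(cv_repeats), positive_class = positive_class,
      n_permutations = as.integer(n_permutations),
      class_weighting = class_weighting, seed = as.integer(seed)
    ),
    class = "rf_config"
  )
}

#' Classification metrics from confusion counts
#'
#' `accuracy = (TP + TN) / (TP + TN + FP + FN)`, `sensitivity = TP / (TP +
#' FN)`, `specificity = TN / (TN + FP)`. Metrics with a zero denominator are
#' returned as `NA` and flagged in the `undefined` element.
#'
#' @param TP,FP,TN,FN Non-negative confusion counts (positive class =
#'   predicted/true positive).
#' @return A list with `accuracy`, `sensitivity`, `specificity`, the counts,
#'   and `undefined` (character vector of metrics with empty denominators).
#' @export
evaluate_counts <- function(TP, FP, TN, FN) {
  counts <- c(TP = TP, FP = FP, TN = TN, FN = FN)
  if (any(counts < 0)) stop("confusion counts must be >= 0")
  if (sum(counts) == 0) stop("confusion counts sum to zero")
  undefined <- character(0)
  sens <- if (TP + FN > 0) TP / (TP + FN) else {
    undefined <- c(undefined, "sensitivity")
    NA_real_
  }
  spec <- if (TN + FP > 0) TN / (TN + FP) else {
    undefined <- c(undefined, "specificity")
    NA_real_
  }
  list(
    accuracy = (TP + TN) / sum(counts),
    sensitivity = sens, specificity = spec,
    TP = TP, FP = FP, TN = TN, FN = FN, undefined = undefined
  )
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (lvl in levels(y)) {
    ii <- which(y == lvl)
    fold[ii] <- sample(rep_len(seq_len(k), length(ii)))
  }
  fold
}

feature_columns <- function(matrix) {
  setdiff(names(matrix), c("cell_id", "class_label", "laser_power"))
}

#' Cross-validated random-forest evaluation
#'
#' Repeated stratified k-fold cross-validation of a random forest on a
#' feature matrix. Within each training fold, missing feature values are
#' median-imputed (with missingness indicators) using that fold's training
#' rows only. Metrics are averaged over held-out folds; confusion counts are
#' accumulated over all held-out predictions. Held-out permutation
#' importances are averaged over the folds of the first repeat.
#'
#' @param matrix A `feature_matrix` (see [featurize_cohort()]) with a
#'   `class_label` column containing at least two classes.
#' @param config An [rf_config()].
#' @param features Optional character vector restricting the feature columns
#'   used.
#' @param importance Compute permutation importances (slower).
#' @return A list of class `classification_report`: `accuracy`,
#'   `sensitivity`, `specificity` (fold means), `counts`, `per_fold`
#'   (data.frame), `importance` (data.frame `feature`, `mean_drop`,
#'   `sd_drop`, `rank`), `config`, `n`, `classes`.
#' @export
train_and_evaluate <- function(matrix, config = rf_config(), features = NULL,
                               importance = TRUE) {
  y <- factor(matrix$class_label)
  if (nlevels(y) < 2) stop("at least two classes are required")
  if (is.null(features)) features <- feature_columns(matrix)
  X <- as.data.frame(matrix)[, features, drop = FALSE]
  pos <- config$positive_class
  if (!pos %in% levels(y)) pos <- levels(y)[1]
  per_fold <- list()
  counts <- c(TP = 0, FP = 0, TN = 0, FN = 0)
  imp_acc <- list()
  withr::with_seed(config$seed, {
    # draw all fold assignments up front so they are identical for any
    # feature subset evaluated under the same config (paired comparisons)
    folds <- lapply(seq_len(config$cv_repeats), function(r) {
      stratified_folds(y, config$cv_folds)
    })
    for (r in seq_len(config$cv_repeats)) {
      fold <- folds[[r]]
      for (k in seq_len(config$cv_folds)) {
        test_idx <- which(fold == k)
        train_idx <- which(fold != k)
        imp <- impute_median(X[train_idx, , drop = FALSE], X[test_idx, , drop = FALSE])
        fit <- rf_fit(imp$train, y[train_idx], config)
        pred <- stats::predict(fit, imp$test)
        cm <- confusion_binary(y[test_idx], pred, pos)
        counts <- counts + cm
        m <- evaluate_counts(cm["TP"], cm["FP"], cm["TN"], cm["FN"])
        per_fold[[length(per_fold) + 1L]] <- data.frame(
          repeat_ = r, fold = k, accuracy = m$accuracy,
          sensitivity = m$sensitivity, specificity = m$specificity
        )
        if (importance && r == 1L) {
          imp_acc[[length(imp_acc) + 1L]] <- permutation_drops(
            fit, imp$test, y[test_idx],
            n_permutations = config$n_permutations,
            restrict = names(X)
          )
        }
      }
    }
  })
  per_fold <- do.call(rbind, per_fold)
  imp_df <- NULL
  if (length(imp_acc)) {
    drops <- do.call(rbind, imp_acc)
    agg_m <- tapply(drops$drop, drops$feature, mean)
    agg_s <- tapply(drops$drop, drops$feature, stats::sd)
    imp_df <- data.frame(
      feature = names(agg_m), mean_drop = as.numeric(agg_m),
      sd_drop = as.numeric(agg_s), stringsAsFactors = FALSE
    )
    imp_df <- rank_importance(imp_df)
  }
  structure(
    list(
      accuracy = mean(per_fold$accuracy),
      sensitivity = mean(per_fold$sensitivity, na.rm = TRUE),
      specificity = mean(per_fold$specificity, na.rm = TRUE),
      counts = as.list(counts),
      per_fold = per_fold, importance = imp_df, config = config,
      n = nrow(matrix), classes = levels(y), positive_class = pos
    ),
    class = "classification_report"
  )
}

rf_fit <- function(X, y, config) {
  mtry <- config$mtry
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  classwt <- NULL
  if (config$class_weighting == "balanced") {
    tab <- table(y)
    classwt <- as.numeric(sum(tab) / (length(tab) * tab))
    names(classwt) <- names(tab)
  }
  randomForest::randomForest(
    x = X, y = y, ntree = config$n_trees, mtry = min(mtry, ncol(X)),
    classwt = classwt
  )
}

confusion_binary <- function(truth, pred, positive) {
  tp <- sum(pred == positive & truth == positive)
  fp <- sum(pred == positive & truth != positive)
  tn <- sum(pred != positive & truth != positive)
  fn <- sum(pred != positive & truth == positive)
  c(TP = tp, FP = fp, TN = tn, FN = fn)
}

permutation_drops <- function(model, X_test, y_test, n_permutations, restrict) {
  base_acc <- mean(stats::predict(model, X_test) == y_test)
  feats <- intersect(restrict, names(X_test))
  rows <- lapply(feats, function(nm) {
    drops <- vapply(seq_len(n_permutations), function(j) {
      Xp <- X_test
      Xp[[nm]] <- sample(Xp[[nm]])
      base_acc - mean(stats::predict(model, Xp) == y_test)
    }, numeric(1))
    data.frame(feature = nm, drop = drops, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

rank_importance <- function(df) {
  ord <- order(-df$mean_drop, df$feature) # ties broken by name
  df <- df[ord, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' Held-out permutation importance of a fitted model
#'
#' Model-agnostic importance: the mean drop in held-out accuracy when one
#' feature column is randomly permuted, averaged over `n_permutations`
#' permutations, ranked in descending order (ties broken by feature name for
#' determinism).
#'
#' @param model A fitted classifier with a `predict` method.
#' @param X_test,y_test Held-out features and labels.
#' @param n_permutations Permutations per feature.
#' @param seed Integer seed.
#' @return A data.frame with `feature`, `mean_drop`, `sd_drop`, `rank`.
#' @export
permutation_importance <- function(model, X_test, y_test, n_permutations = 10,
                                   seed = 1) {
  y_test <- factor(y_test)
  drops <- withr::with_seed(
    seed,
    permutation_drops(model, X_test, y_test, n_permutations, names(X_test))
  )
  agg_m <- tapply(drops$drop, drops$feature, mean)
  agg_s <- tapply(drops$drop, drops$feature, stats::sd)
  rank_importance(data.frame(
    feature = names(agg_m), mean_drop = as.numeric(agg_m),
    sd_drop = as.numeric(agg_s), stringsAsFactors = FALSE
  ))
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf(
    "<classification_report> n = %d, %d-fold CV x %d: accuracy %.3f, sensitivity %.3f, specificity %.3f (positive: %s)\n",
    x$n, x$config$cv_folds, x$config$cv_repeats,
    x$accuracy, x$sensitivity, x$specificity, x$positive_class
  ))
  if (!is.null(x$importance)) {
    top <- utils::head(x$importance, 3)
    cat(
      "  top features:",
      paste(sprintf("%s (%.3f)", top$feature, top$mean_drop), collapse = ", "),
      "\n"
    )
  }
  invisible(x)
}

#' Progressive feature-group input experiment
#'
#' Evaluates the classifier on growing prefixes of an ordered list of feature
#' groups (e.g. morphology only, then + relative deformation, then +
#' elliptic deformation, then + shape restoration), using identical CV fold
#' assignments for every prefix so that accuracy changes are paired.
#'
#' @param matrix A `feature_matrix`.
#' @param ordered_groups Named list of character vectors of feature names.
#' @param config An [rf_config()].
#' @return A data.frame with one row per prefix: `step`, `features_added`,
#'   `n_features`, `accuracy`, `sensitivity`, `specificity`.
#' @export
progressive_input <- function(matrix, ordered_groups, config = rf_config()) {
  if (length(ordered_groups) == 0) stop("empty feature group list")
  all_feats <- feature_columns(matrix)
  for (g in ordered_groups) {
    missing <- setdiff(g, all_feats)
    if (length(missing)) {
      stop("unknown features in group: ", paste(missing, collapse = ", "))
    }
  }
  rows <- lapply(seq_along(ordered_groups), function(i) {
    feats <- unique(unlist(ordered_groups[seq_len(i)]))
    rep <- train_and_evaluate(matrix, config,
      features = feats,
      importance = FALSE
    )
    data.frame(
      step = i,
      features_added = names(ordered_groups)[i],
      n_features = length(feats),
      accuracy = rep$accuracy, sensitivity = rep$sensitivity,
      specificity = rep$specificity, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
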