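#' Cross-validation scheme
#'
#' Folds always partition subjects, never movements: all of a subject's
#' movements and its feature row stay on one side of every split.
#'
#' @param kind `"leave_one_out"` (alias `"loocv"`), `"repeated_kfold"` or
#'   `"nested_kfold"` (inner grid-search loop).
#' @param n_folds folds per repeat; treated as a hyperparameter (default 4).
#' @param n_repeats repeats of the whole k-fold process (default 10);
#'   ignored for leave-one-out.
#' @param shuffle shuffle subjects before each repeat's fold assignment.
#' @param seed seed fixing fold assignment and per-fold model seeds.
#' @return list of class `cv_scheme`.
#' @export
cv_scheme <- function(kind = c("leave_one_out", "loocv", "repeated_kfold",
                               "nested_kfold"),
                      n_folds = 4, n_repeats = 10, shuffle = TRUE,
                      seed = 1) {
  kind <- match.arg(kind)
  if (kind == "loocv") kind <- "leave_one_out"
  stopifnot(n_folds >= 2, n_repeats >= 1)
  structure(list(kind = kind, n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats), shuffle = shuffle,
                 seed = as.integer(seed)),
            class = "cv_scheme")
}

## stratified fold assignment for one repeat: named vector subject -> fold
assign_folds <- function(subjects, groups, n_folds, shuffle) {
  fold <- stats::setNames(integer(length(subjects)), subjects)
  for (g in unique(groups)) {
    ids <- subjects[groups == g]
    if (shuffle) ids <- sample(ids)
    fold[ids] <- rep_len(seq_len(n_folds), length(ids))
  }
  fold
}

#' Fit feature-wise normalization on training data only
#'
#' Standard feature-wise normalization (center to mean 0, scale to SD 1)
#' with parameters estimated on the training fold only, so no information
#' from held-out subjects leaks into preprocessing. Zero-SD (constant)
#' training features are mapped to 0 with a warning.
#'
#' @param x numeric matrix or data frame of training features.
#' @return list of class `feature_norm` with `center`, `scale`, `constant`.
#' @export
normalize_fit <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) == 0L) stop("empty training set")
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  constant <- !is.finite(scale) | scale == 0
  if (any(constant)) {
    warning(sum(constant), " zero-SD feature(s) mapped to 0")
    scale[constant] <- 1
  }
  structure(list(center = center, scale = scale, constant = constant),
            class = "feature_norm")
}

#' Apply fitted normalization parameters
#'
#' @param params a `feature_norm` from [normalize_fit()].
#' @param x matrix/data frame with the same columns as the training set.
#' @return normalized numeric matrix.
#' @export
normalize_apply <- function(params, x) {
  x <- as.matrix(x)
  out <- sweep(sweep(x, 2, params$center, `-`), 2, params$scale, `/`)
  if (any(params$constant)) out[, params$constant] <- 0
  out
}

feature_cols <- function(df) {
  setdiff(names(df), c("subject_id", "group", "gesture"))
}

#' Run a subject-level cross-validated evaluation
#'
#' Per fold: normalization is fitted on the training subjects only, class
#' weights are computed from the training labels, the configured model is
#' fitted (`"net"` on the session feature table, `"gbm"` on the
#' per-movement profile table) and the held-out subjects are predicted —
#' profile models through the per-movement average rule
#' ([predict_session_average()]). A subject appearing on both sides of a
#' split is a hard error. Predictions are pooled over folds and repeats
#' into an [eval_report].
#'
#' For `kind = "nested_kfold"`, each outer training fold first runs
#' [grid_search()] on an inner split to choose the configuration
#' (tuning never sees the outer held-out subjects).
#'
#' @param data feature table (for `family = "net"`) or profile table
#'   (`family = "gbm"`), as a data frame with `subject_id` and `group`.
#' @param family `"net"` or `"gbm"`.
#' @param scheme a [cv_scheme()].
#' @param groups optional character vector restricting to a pair (or any
#'   subset) of group labels.
#' @param net,gbm model configurations (defaults used when `NULL`).
#' @param grid parameter grid for the nested scheme (defaults to
#'   [default_grid()]).
#' @param positive positive class for sensitivity/specificity; defaults to
#'   the clinically affected group of a pair (last in TD < ASD < DCD
#'   order).
#' @return an object of class `eval_report`.
#' @export
run_cv <- function(data, family = c("net", "gbm"),
                   scheme = cv_scheme("leave_one_out"), groups = NULL,
                   net = NULL, gbm = NULL, grid = NULL, positive = NULL) {
  family <- match.arg(family)
  net <- net %||% net_config()
  gbm <- gbm %||% gbm_config()
  df <- as.data.frame(data)
  if (!is.null(groups)) df <- df[df$group %in% groups, , drop = FALSE]
  if (nrow(df) == 0L) stop("no rows after group restriction")
  fcols <- feature_cols(df)
  keep <- vapply(df[fcols], function(v) all(is.finite(v)), logical(1))
  if (any(!keep)) {
    warning("dropping ", sum(!keep),
            " feature column(s) with non-finite values")
    fcols <- fcols[keep]
  }
  subj <- unique(df[c("subject_id", "group")])
  lvls <- sort(unique(subj$group))
  if (is.null(positive))
    positive <- lvls[order(match(lvls, GROUP_LEVELS))][length(lvls)]
  n_sub <- nrow(subj)
  loo <- scheme$kind == "leave_one_out"
  n_repeats <- if (loo) 1L else scheme$n_repeats
  n_folds <- if (loo) n_sub else scheme$n_folds

  true_all <- character(0); pred_all <- character(0)
  per_fold <- NULL
  with_seed(scheme$seed, function() {
    for (r in seq_len(n_repeats)) {
      fold <- if (loo)
        stats::setNames(seq_len(n_sub), subj$subject_id)
      else assign_folds(subj$subject_id, subj$group, n_folds,
                        scheme$shuffle)
      for (f in seq_len(n_folds)) {
        test_ids <- names(fold)[fold == f]
        train_ids <- names(fold)[fold != f]
        if (length(intersect(train_ids, test_ids)))
          stop("leakage: overlapping train/test subjects")
        tr_lab <- subj$group[subj$subject_id %in% train_ids]
        if (any(table(factor(tr_lab, levels = lvls)) < 1)) {
          warning("fold ", f, " (repeat ", r,
                  ") lacks a class in training; skipped")
          next
        }
        tr <- df[df$subject_id %in% train_ids, , drop = FALSE]
        te <- df[df$subject_id %in% test_ids, , drop = FALSE]
        cw <- compute_class_weights(tr$group)
        norm <- withCallingHandlers(
          normalize_fit(tr[fcols]),
          warning = function(w) invokeRestart("muffleWarning"))
        xtr <- normalize_apply(norm, tr[fcols])
        xte <- normalize_apply(norm, te[fcols])
        fit_seed <- derive_seed(scheme$seed, r * 1000L + f)
        if (family == "net") {
          cfg <- net
          if (scheme$kind == "nested_kfold") {
            gs <- grid_search(grid %||% default_grid("net"), tr,
                              family = "net",
                              scheme = cv_scheme("repeated_kfold",
                                                 n_folds = max(2, n_folds - 1),
                                                 n_repeats = 1,
                                                 seed = fit_seed))
            cfg <- gs$best_config
          }
          cfg$seed <- fit_seed
          model <- fit_session_net(xtr, tr$group, cfg, cw)
          probs <- predict(model, xte)
          pred <- colnames(probs)[max.col(probs, ties.method = "first")]
          true <- te$group
          ids <- te$subject_id
        } else {
          cfg <- gbm
          if (scheme$kind == "nested_kfold") {
            gs <- grid_search(grid %||% default_grid("gbm"), tr,
                              family = "gbm",
                              scheme = cv_scheme("repeated_kfold",
                                                 n_folds = max(2, n_folds - 1),
                                                 n_repeats = 1,
                                                 seed = fit_seed))
            cfg <- gs$best_config
          }
          cfg$seed <- fit_seed
          model <- fit_profile_gbm(xtr, tr$group, tr$subject_id, cfg, cw,
                                   holdout_subjects = te$subject_id)
          mv_probs <- predict(model, xte)
          ids <- unique(te$subject_id)
          pred <- character(length(ids)); true <- character(length(ids))
          for (k in seq_along(ids)) {
            rows <- te$subject_id == ids[k]
            avg <- predict_session_average(mv_probs[rows, , drop = FALSE])
            pred[k] <- names(avg)[which.max(avg)]
            true[k] <- te$group[rows][1]
          }
        }
        true_all <<- c(true_all, true)
        pred_all <<- c(pred_all, pred)
        per_fold <<- rbind(per_fold,
                           data.frame(repeat_ = r, fold = f,
                                      n_test = length(ids),
                                      accuracy = mean(pred == true)))
      }
    }
  })
  cm <- table(factor(true_all, levels = lvls),
              factor(pred_all, levels = lvls))
  cmat <- matrix(as.integer(cm), nrow = length(lvls),
                 dimnames = list(lvls, lvls))
  eval_report(cmat, per_fold = per_fold, scheme = scheme, family = family,
              positive = positive)
}

#' Default hyperparameter grids
#'
#' Spans the configured ranges: units {20, 30, 40} x learning rate
#' {0.001, 0.003, 0.01} for the network; trees {500, 1000} for the GBM.
#'
#' @param family `"net"` or `"gbm"`.
#' @return data frame grid for [grid_search()].
#' @export
default_grid <- function(family = c("net", "gbm")) {
  family <- match.arg(family)
  if (family == "net")
    expand.grid(units = c(20, 30, 40),
                learning_rate = c(0.001, 0.003, 0.01))
  else
    expand.grid(n_trees = c(500, 1000))
}

#' Construct an evaluation report
#'
#' @param confusion square confusion matrix, rows = true (clinical) group,
#'   columns = predicted group.
#' @param per_fold optional per-fold score table.
#' @param scheme,family provenance echo.
#' @param positive positive class for the 2-class metrics.
#' @return object of class `eval_report` with the confusion matrix,
#'   accuracy, sensitivity, specificity and above-chance figures.
#' @export
eval_report <- function(confusion, per_fold = NULL, scheme = NULL,
                        family = NULL, positive = NULL) {
  m <- confusion_metrics(confusion, positive = positive)
  structure(c(list(confusion = confusion), m,
              list(per_fold = per_fold, scheme = scheme, family = family,
                   positive = positive)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>",
      if (!is.null(x$family)) paste0("family=", x$family), "\n")
  print(x$confusion)
  cat(sprintf("accuracy %.3f", x$accuracy))
  if (is.finite(x$sensitivity))
    cat(sprintf(" | sensitivity %.2f | specificity %.2f (positive = %s)",
                x$sensitivity, x$specificity, x$positive %||% "?"))
  cat(sprintf("\nabove chance: %.1f%% (exact), %.1f%% (rounded inputs)\n",
              100 * x$above_chance, 100 * x$above_chance_rounded))
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy is `trace / total`. For two classes, sensitivity is
#' `TP / (TP + FN)` and specificity `TN / (TN + FP)` for the designated
#' positive class (for K > 2 they are one-vs-rest if a positive class is
#' given, otherwise `NA`). Above-chance accuracy is
#' `(accuracy - chance) / chance` with `chance = 1/K`; it is reported both
#' exactly and with accuracy and chance first rounded to two digits (the
#' convention under which 0.574 on three balancedish groups prints as 73%
#' above chance).
#'
#' @param confusion square non-negative integer matrix (rows = true).
#' @param positive row/column name (or index) of the positive class.
#' @param chance chance accuracy level (default `1/K`).
#' @return list: `accuracy`, `sensitivity`, `specificity`, `above_chance`,
#'   `above_chance_rounded`.
#' @export
confusion_metrics <- function(confusion, positive = NULL, chance = NULL) {
  cm <- as.matrix(confusion)
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square")
  if (any(cm < 0)) stop("negative confusion counts")
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  k <- nrow(cm)
  chance <- chance %||% (1 / k)
  acc <- sum(diag(cm)) / total
  sens <- spec <- NA_real_
  if (!is.null(positive) || k == 2) {
    pos <- positive %||% rownames(cm)[2] %||% 2
    i <- if (is.character(pos)) match(pos, rownames(cm)) else pos
    if (is.na(i)) stop("positive class not found in confusion matrix")
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    tn <- total - tp - fn - fp
    sens <- tp / (tp + fn)
    spec <- tn / (tn + fp)
  }
  list(accuracy = acc, sensitivity = sens, specificity = spec,
       above_chance = (acc - chance) / chance,
       above_chance_rounded = (round(acc, 2) - round(chance, 2)) /
         round(chance, 2))
}
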