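#' Balanced inverse-frequency class weights
#'
#' Group imbalance is offset by weighting each class by
#' `N_total / (K * N_c)`: larger groups get weights below 1, smaller groups
#' above 1, and the weighted sample size equals the true sample size
#' (`sum_c w_c * N_c = N_total`).
#'
#' @param labels factor or character vector of class labels.
#' @return named numeric vector of per-class weights.
#' @export
compute_class_weights <- function(labels) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2) stop("need at least 2 classes present")
  counts <- table(labels)
  if (any(counts == 0)) stop("class with 0 members: ",
                             paste(names(counts)[counts == 0],
                                   collapse = ", "))
  n <- length(labels); k <- nlevels(labels)
  w <- as.numeric(n / (k * counts))
  stats::setNames(w, names(counts))
}

#' Gradient-boosting configuration for the profile representation
#'
#' Boosted trees over the per-movement bin profiles: 500-1000 shallow trees
#' (depth 2), learning rate 0.1, row subsample 0.8 and `log2(p)` feature
#' columns per tree.
#'
#' @param n_trees boosting rounds, in `[500, 1000]`.
#' @param learning_rate shrinkage (0.1).
#' @param subsample row subsampling fraction (0.8).
#' @param max_depth tree depth (2).
#' @param seed RNG seed for subsampling.
#' @return list of class `gbm_config`.
#' @export
gbm_config <- function(n_trees = 500, learning_rate = 0.1, subsample = 0.8,
                       max_depth = 2, seed = 1) {
  stopifnot(n_trees >= 500, n_trees <= 1000, learning_rate > 0,
            subsample > 0, subsample <= 1, max_depth >= 1)
  structure(list(n_trees = as.integer(n_trees),
                 learning_rate = learning_rate, subsample = subsample,
                 max_depth = as.integer(max_depth), seed = as.integer(seed)),
            class = "gbm_config")
}

#' Fit the per-movement gradient boosting model
#'
#' Every movement (profile row) is an independent training sample carrying
#' its session's label; the subject ids are required so the model can
#' refuse a train set that shares a subject with a supplied held-out set —
#' all of a session's movements must stay on one side of any split.
#'
#' @param x numeric matrix (movements x profile features).
#' @param y labels, one per movement (a session's movements all share its
#'   label).
#' @param subject_ids subject id per movement.
#' @param config a [gbm_config()].
#' @param class_weights named per-class weights, or `NULL`.
#' @param holdout_subjects subject ids of the intended test side; any
#'   overlap with `subject_ids` is a leakage error.
#' @return object of class `kinetap_gbm` with a `predict` method returning
#'   per-movement class probabilities.
#' @export
fit_profile_gbm <- function(x, y, subject_ids, config = gbm_config(),
                            class_weights = NULL,
                            holdout_subjects = character()) {
  leaked <- intersect(unique(subject_ids), unique(holdout_subjects))
  if (length(leaked))
    stop("leakage: subject(s) ", paste(leaked, collapse = ", "),
         " present in both train and test sides of the split")
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("non-finite profile values")
  y <- droplevels(as.factor(y))
  K <- nlevels(y)
  if (K < 2) stop("need at least 2 classes")
  w <- if (is.null(class_weights)) rep(1, nrow(x))
       else unname(class_weights[as.character(y)])
  p <- ncol(x)
  colsample <- max(1 / p, floor(log2(p)) / p)
  params <- list(
    objective = if (K == 2) "binary:logistic" else "multi:softprob",
    eta = config$learning_rate,
    max_depth = config$max_depth,
    subsample = config$subsample,
    colsample_bytree = colsample,
    nthread = 1,
    seed = config$seed)
  if (K > 2) params$num_class <- K
  dtrain <- xgboost::xgb.DMatrix(x, label = as.integer(y) - 1L, weight = w)
  booster <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = config$n_trees, verbose = 0)
  structure(list(booster = booster, levels = levels(y), config = config,
                 n_features = p),
            class = "kinetap_gbm")
}

#' @export
predict.kinetap_gbm <- function(object, newdata,
                                type = c("prob", "class"), ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  raw <- predict(object$booster, xgboost::xgb.DMatrix(x))
  K <- length(object$levels)
  probs <- if (K == 2) cbind(1 - raw, raw)
           else matrix(raw, ncol = K, byrow = TRUE)
  colnames(probs) <- object$levels
  if (type == "class")
    factor(object$levels[max.col(probs, ties.method = "first")],
           levels = object$levels)
  else probs
}

#' @export
print.kinetap_gbm <- function(x, ...) {
  cat(sprintf(
    "<kinetap_gbm> %d trees, depth %d, eta %.2g -> %d classes (%d features)\n",
    x$config$n_trees, x$config$max_depth, x$config$learning_rate,
    length(x$levels), x$n_features))
  invisible(x)
}

#' Average per-movement predictions into a session prediction
#'
#' A profile model emits one probability vector per movement; the session's
#' final prediction is the arithmetic mean of those vectors (the argmax of
#' the mean is the predicted class). The mean of probability vectors is a
#' probability vector, and the result is invariant to the order of a
#' session's movements.
#'
#' @param probs matrix of per-movement class probabilities (movements x
#'   classes).
#' @return numeric vector: the averaged class-probability vector.
#' @export
predict_session_average <- function(probs) {
  probs <- as.matrix(probs)
  if (nrow(probs) == 0L) stop("no movement predictions to average")
  colMeans(probs)
}

#' Exhaustive grid search over classifier configurations
#'
#' Evaluates every configuration by subject-level cross-validation and
#' selects the best by mean validation accuracy; ties are broken by the
#' smaller model (fewer units / trees), then by the lower learning rate.
#'
#' @param grid data frame of configurations: columns `units` and
#'   `learning_rate` for `family = "net"`, `n_trees` (and optionally
#'   `learning_rate`) for `family = "gbm"`.
#' @param data feature table (net) or profile table (gbm).
#' @param family `"net"` or `"gbm"`.
#' @param scheme inner [cv_scheme()] used to score configurations.
#' @param groups optional pair of group labels to restrict to.
#' @return list with `best` (the winning configuration row), `best_config`
#'   (as a config object) and `scores` (one row per configuration x repeat
#'   x fold).
#' @export
grid_search <- function(grid, data, family = c("net", "gbm"),
                        scheme = cv_scheme("repeated_kfold", n_folds = 3,
                                           n_repeats = 1),
                        groups = NULL) {
  family <- match.arg(family)
  grid <- as.data.frame(grid)
  if (nrow(grid) == 0L) stop("empty parameter grid")
  scores <- NULL
  means <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- config_from_row(family, grid[i, , drop = FALSE])
    rep_i <- run_cv(data, family = family, scheme = scheme, groups = groups,
                    net = if (family == "net") cfg,
                    gbm = if (family == "gbm") cfg)
    pf <- rep_i$per_fold
    pf$config <- i
    scores <- rbind(scores, pf)
    means[i] <- mean(pf$accuracy)
  }
  size <- if (family == "net") grid$units else grid$n_trees
  lr <- if ("learning_rate" %in% names(grid)) grid$learning_rate
        else rep(0, nrow(grid))
  ord <- order(-means, size, lr)
  best_i <- ord[1]
  list(best = cbind(grid[best_i, , drop = FALSE],
                    mean_accuracy = means[best_i]),
       best_config = config_from_row(family, grid[best_i, , drop = FALSE]),
       scores = scores)
}

config_from_row <- function(family, row) {
  if (family == "net") {
    net_config(units = row$units %||% 30,
               learning_rate = row$learning_rate %||% 0.01,
               seed = row$seed %||% 1)
  } else {
    gbm_config(n_trees = row$n_trees %||% 500,
               learning_rate = row$learning_rate %||% 0.1,
               seed = row$seed %||% 1)
  }
}
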