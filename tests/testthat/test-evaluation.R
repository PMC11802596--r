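test_that("normalization is fitted on training data only", {
  set.seed(8)
  train <- matrix(rnorm(40 * 6, 2, 3), ncol = 6)
  params <- normalize_fit(train)
  ztr <- normalize_apply(params, train)
  expect_equal(unname(colMeans(ztr)), rep(0, 6), tolerance = 1e-10)
  expect_equal(unname(apply(ztr, 2, sd)), rep(1, 6), tolerance = 1e-10)

  const <- cbind(train[, 1:2], 7)
  expect_warning(pc <- normalize_fit(const), "zero-SD")
  expect_equal(unname(normalize_apply(pc, const)[, 3]), rep(0, 40))

  # a shifted test fold must NOT come out centered: no leakage
  test <- matrix(rnorm(10 * 6, 10, 3), ncol = 6)
  zte <- normalize_apply(params, test)
  expect_true(all(abs(colMeans(zte)) > 1))
  expect_error(normalize_fit(train[0, ]), "empty")
})

test_that("leave-one-out predicts every subject exactly once", {
  set.seed(30)
  df <- data.frame(subject_id = sprintf("S%02d", 1:18),
                   group = rep(c("TD", "ASD"), each = 9),
                   matrix(rnorm(18 * 8, rep(c(0, 3), each = 9)), 18),
                   check.names = FALSE)
  r <- run_cv(df, family = "net", scheme = cv_scheme("leave_one_out",
                                                     seed = 1))
  expect_equal(nrow(r$per_fold), 18L)
  expect_true(all(r$per_fold$n_test == 1))
  expect_equal(unname(rowSums(r$confusion)), c(9L, 9L))
  expect_equal(sum(r$confusion), 18L)
})

test_that("confusion metrics reproduce hand-computed and published cases", {
  # three-group confusion matrix: rows TD/ASD/DCD
  cm <- matrix(c(14, 2, 4, 5, 11, 2, 5, 5, 6), nrow = 3, byrow = TRUE,
               dimnames = list(c("TD", "ASD", "DCD"),
                               c("TD", "ASD", "DCD")))
  m <- confusion_metrics(cm)
  expect_equal(m$accuracy, 31 / 54)
  expect_equal(round(100 * m$accuracy), 57)
  expect_equal(round(100 * m$above_chance_rounded), 73)

  ident <- diag(c(10, 10))
  mi <- confusion_metrics(ident, positive = 1)
  expect_equal(mi$accuracy, 1)
  expect_equal(mi$sensitivity, 1)
  expect_equal(mi$specificity, 1)

  m2 <- confusion_metrics(matrix(c(8, 2, 3, 7), 2, byrow = TRUE),
                          positive = 1)
  expect_equal(m2$sensitivity, 0.8)
  expect_equal(m2$specificity, 0.7)
  expect_equal(m2$accuracy, 0.75)

  expect_error(confusion_metrics(matrix(0, 2, 2)), "empty")
  expect_error(confusion_metrics(matrix(1, 2, 3)), "square")
})

test_that("group tests route by normality and behave at the null", {
  set.seed(44)
  base <- rep(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10), 3)
  df <- data.frame(subject_id = sprintf("S%02d", 1:30),
                   group = rep(c("TD", "ASD", "DCD"), each = 10),
                   identical_feat = base,
                   normal_feat = rnorm(30, rep(c(0, 0, 3), each = 10)),
                   skewed_feat = rexp(30)^3,
                   constant_feat = 5,
                   check.names = FALSE)
  res <- feature_group_tests(df)
  r <- function(f) res[res$feature == f, ]
  # identical distributions across groups: Kruskal-Wallis statistic 0, p = 1
  expect_equal(r("identical_feat")$p_omnibus, 1, tolerance = 1e-9)
  expect_equal(r("normal_feat")$method, "anova/t")
  expect_lt(r("normal_feat")$p_omnibus, 0.01)
  expect_equal(r("skewed_feat")$method, "kruskal/mann-whitney")
  expect_true(r("constant_feat")$skipped)
  pcols <- grep("^p_", names(res), value = TRUE)
  pv <- unlist(res[pcols])
  expect_true(all(pv[!is.na(pv)] >= 0 & pv[!is.na(pv)] <= 1))
})

test_that("Kendall correlations give tau-b with hand-counted cases", {
  feats <- data.frame(subject_id = sprintf("S%d", 1:4),
                      group = rep("TD", 4),
                      up = c(1, 2, 3, 4), down = c(4, 3, 2, 1),
                      swap = c(1, 3, 2, 4), check.names = FALSE)
  cov <- data.frame(subject_id = sprintf("S%d", 1:4), age = c(1, 2, 3, 4))
  res <- feature_covariate_correlations(feats, cov, by_group = FALSE)
  tau <- function(f) res$tau[res$feature == f]
  expect_equal(tau("up"), 1)
  expect_equal(tau("down"), -1)
  # (1,3,2,4) vs (1,2,3,4): 5 concordant, 1 discordant -> (5-1)/6
  expect_equal(tau("swap"), 2 / 3, tolerance = 1e-9)

  cov$flat <- 1
  res2 <- feature_covariate_correlations(feats, cov, by_group = FALSE)
  expect_true(all(res2$flagged[res2$covariate == "flat"]))
  expect_true(all(is.na(res2$tau[res2$covariate == "flat"])))
})

test_that("subject-level splits never divide a session's movements", {
  set.seed(66)
  pt <- do.call(rbind, lapply(1:10, function(i)
    data.frame(subject_id = sprintf("S%02d", i),
               group = if (i <= 5) "TD" else "ASD", gesture = 1:5,
               matrix(rnorm(5 * 4, if (i <= 5) 0 else 4), 5),
               check.names = FALSE)))
  # run_cv must complete without tripping its internal guard ...
  r <- run_cv(pt, family = "gbm",
              scheme = cv_scheme("repeated_kfold", n_folds = 2,
                                 n_repeats = 1, seed = 5))
  expect_equal(sum(r$confusion), 10)
  # ... and the guard must fire on a constructed violation
  x <- as.matrix(pt[, -(1:3)])
  expect_error(
    fit_profile_gbm(x, pt$group, pt$subject_id,
                    holdout_subjects = c("S03", "S99")),
    "leakage: subject")
})
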