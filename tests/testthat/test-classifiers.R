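test_that("class weights are balanced inverse frequencies", {
  expect_equal(compute_class_weights(rep(c("A", "B"), each = 10)),
               c(A = 1, B = 1))
  w <- compute_class_weights(rep(c("A", "B"), times = c(20, 16)))
  expect_equal(w, c(A = 0.9, B = 1.125))
  # weighted sample size identity, arbitrary labels
  set.seed(3)
  lab <- sample(c("TD", "ASD", "DCD"), 57, replace = TRUE,
                prob = c(0.5, 0.3, 0.2))
  w <- compute_class_weights(lab)
  expect_equal(sum(w[lab]), length(lab))
  expect_error(compute_class_weights(factor(rep("A", 5),
                                            levels = c("A", "B"))),
               "0 members|2 classes")
})

test_that("the session net fits separable blobs and is seed-deterministic", {
  set.seed(10)
  x <- rbind(matrix(rnorm(20 * 5, 0), ncol = 5),
             matrix(rnorm(20 * 5, 4), ncol = 5))
  y <- rep(c("a", "b"), each = 20)
  norm <- normalize_fit(x)
  xn <- normalize_apply(norm, x)
  fit <- fit_session_net(xn, y, net_config(seed = 5))
  expect_equal(mean(predict(fit, xn, type = "class") == y), 1)
  fit2 <- fit_session_net(xn, y, net_config(seed = 5))
  expect_identical(predict(fit, xn), predict(fit2, xn))
  xb <- xn; xb[1, 1] <- NA
  expect_error(fit_session_net(xb, y), "non-finite")
})

test_that("shuffled labels give chance-level cross-validated accuracy", {
  set.seed(77)
  df <- data.frame(subject_id = sprintf("S%02d", 1:30),
                   group = sample(rep(c("TD", "ASD"), each = 15)),
                   matrix(rnorm(30 * 20), 30), check.names = FALSE)
  r <- run_cv(df, family = "net",
              scheme = cv_scheme("repeated_kfold", n_folds = 3,
                                 n_repeats = 2, seed = 2))
  # 95% binomial band around 0.5 for 60 pooled predictions
  expect_gt(r$accuracy, 0.5 - 1.96 * sqrt(0.25 / 60) - 0.05)
  expect_lt(r$accuracy, 0.5 + 1.96 * sqrt(0.25 / 60) + 0.05)
})

test_that("the profile GBM separates disjoint groups and guards leakage", {
  set.seed(4)
  n_sub <- 12; mv <- 8
  mk <- function(shift, g, off) {
    do.call(rbind, lapply(1:n_sub, function(i)
      data.frame(subject_id = sprintf("%s%02d", g, i + off), group = g,
                 gesture = 1:mv,
                 matrix(rnorm(mv * 6, shift), mv), check.names = FALSE)))
  }
  pt <- rbind(mk(0, "TD", 0), mk(5, "ASD", 0))
  r <- run_cv(pt, family = "gbm",
              scheme = cv_scheme("repeated_kfold", n_folds = 2,
                                 n_repeats = 1, seed = 3))
  expect_equal(r$accuracy, 1)
  x <- as.matrix(pt[, -(1:3)])
  expect_error(fit_profile_gbm(x, pt$group, pt$subject_id,
                               holdout_subjects = "TD01"),
               "leakage")
  expect_error(fit_profile_gbm(x, rep("TD", nrow(x)), pt$subject_id),
               "2 classes")
})

test_that("session predictions are movement-order-invariant averages", {
  p <- rbind(c(0.8, 0.2), c(0.6, 0.4))
  expect_equal(unname(predict_session_average(p)), c(0.7, 0.3))
  same <- rbind(c(0.3, 0.7), c(0.3, 0.7), c(0.3, 0.7))
  expect_equal(unname(predict_session_average(same)), c(0.3, 0.7))
  set.seed(2)
  m <- matrix(runif(40), 10); m <- m / rowSums(m)
  expect_equal(sum(predict_session_average(m)), 1)
  expect_equal(predict_session_average(m),
               predict_session_average(m[sample(10), ]))
  expect_error(predict_session_average(m[0, , drop = FALSE]), "no movement")
})

test_that("weighted training matches training on duplicated minority data", {
  set.seed(50)
  x <- rbind(matrix(rnorm(20 * 4, 0), ncol = 4),
             matrix(rnorm(10 * 4, 2.5), ncol = 4))
  y <- rep(c("maj", "min"), times = c(20, 10))
  cw <- compute_class_weights(y)   # proportional to {1, 2}
  xd <- rbind(x, x[y == "min", ])
  yd <- c(y, rep("min", 10))
  f_w <- fit_session_net(x, y, net_config(seed = 9), class_weights = cw)
  f_d <- fit_session_net(xd, yd, net_config(seed = 9))
  grid <- matrix(rnorm(50 * 4, 1.2), ncol = 4)
  agree <- mean(predict(f_w, grid, type = "class") ==
                  predict(f_d, grid, type = "class"))
  expect_gte(agree, 0.9)
})

test_that("grid search selects the dominant configuration and breaks ties", {
  set.seed(15)
  df <- data.frame(subject_id = sprintf("S%02d", 1:24),
                   group = rep(c("TD", "ASD"), each = 12),
                   matrix(rnorm(24 * 6,
                                rep(c(0, 3), each = 12)), 24),
                   check.names = FALSE)
  one <- grid_search(data.frame(units = 30, learning_rate = 0.01), df,
                     family = "net")
  expect_equal(one$best$units, 30)
  # decayed lr 0.001/sqrt(t) cannot leave the initialization basin in time;
  # lr 0.01 dominates on this separable task
  gs <- grid_search(expand.grid(units = 20,
                                learning_rate = c(0.001, 0.01)), df,
                    family = "net",
                    scheme = cv_scheme("repeated_kfold", n_folds = 3,
                                       n_repeats = 2, seed = 4))
  expect_equal(gs$best$learning_rate, 0.01)
  expect_equal(nrow(gs$scores), 2 * 3 * 2)
  # perfect ties resolve to the smaller model, then the lower rate
  tie <- grid_search(expand.grid(units = c(40, 20),
                                 learning_rate = c(0.01, 0.003)), df,
                     family = "net",
                     scheme = cv_scheme("repeated_kfold", n_folds = 3,
                                        n_repeats = 1, seed = 4))
  if (length(unique(tie$scores$accuracy)) == 1) {
    expect_equal(tie$best$units, 20)
    expect_equal(tie$best$learning_rate, 0.003)
  }
  expect_error(grid_search(data.frame(), df, family = "net"), "empty")
})
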