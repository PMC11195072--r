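# Classification harness: normalization, balanced accuracy, weighting,
# CV mechanics and leakage guards.

test_that("robust sigmoid normalization is monotone, bounded on train, outlier-resistant", {
  train <- c(0:9, 1e6)
  tf <- robust_sigmoid_normalize(train)
  v <- tf(train)
  expect_true(all(v >= 0 & v <= 1))
  # rank order preserved (strictly away from float saturation of the
  # sigmoid tails, weakly everywhere)
  x <- c(-50, -1, 0, 2.5, 9, 500, 2e6)
  expect_true(all(diff(tf(x)) >= 0))
  expect_true(all(diff(tf(c(-50, -1, 0, 2.5, 9))) > 0))
  # the non-outlier spread survives, unlike min-max scaling
  minmax <- (0:9 - min(train)) / (max(train) - min(train))
  expect_lt(diff(range(minmax)), 1e-4)
  expect_gt(diff(range(tf(0:9))), 0.5)
  # train median sits mid-range after rescale
  expect_gt(tf(median(train)), 0.2)
  expect_lt(tf(median(train)), 0.8)

  # zero IQR falls back to a mean/SD sigmoid rather than collapsing
  tr2 <- c(rep(5, 8), 0, 10)
  tf2 <- robust_sigmoid_normalize(tr2)
  expect_true(all(diff(tf2(c(0, 5, 10))) > 0))
  # constant column maps to 0.5
  expect_equal(robust_sigmoid_normalize(rep(3, 5))(c(1, 3, 9)),
               rep(0.5, 3))
  expect_error(robust_sigmoid_normalize(numeric(0)), "empty")
})

test_that("balanced accuracy averages sensitivity and specificity", {
  truth <- factor(c(rep("control", 4), rep("case", 4)),
                  levels = c("control", "case"))
  expect_equal(balanced_accuracy(truth, truth)$balanced_accuracy, 1)
  # constant single-class prediction = chance
  const <- factor(rep("control", 8), levels = c("control", "case"))
  expect_equal(balanced_accuracy(truth, const)$balanced_accuracy, 0.5)
  # TP=3, FN=1, TN=2, FP=2 -> (0.75 + 0.5)/2
  pred <- factor(c("control", "control", "case", "case",
                   "case", "case", "case", "control"),
                 levels = c("control", "case"))
  ba <- balanced_accuracy(truth, pred)
  expect_equal(ba$balanced_accuracy, 0.625)
  expect_equal(ba$sensitivity, 0.75)
  expect_equal(ba$specificity, 0.5)
  # symmetric under class relabeling
  truth_sw <- factor(as.character(truth), levels = c("case", "control"))
  pred_sw <- factor(as.character(pred), levels = c("case", "control"))
  expect_equal(balanced_accuracy(truth_sw, pred_sw)$balanced_accuracy, 0.625)
  expect_error(balanced_accuracy(const, const), "both classes")
})

test_that("CV schemes are stratified, shared and reproducible", {
  set.seed(31)
  y <- factor(rep(c("control", "case"), times = c(42, 18)))
  sch <- make_cv_scheme(y, k = 10, r = 10, seed = 5)
  expect_equal(dim(sch$assignments), c(60, 10))
  # per-fold class counts within 1 of perfect stratification
  for (j in 1:10) {
    tb <- table(sch$assignments[, j], y)
    expect_true(all(abs(tb[, "case"] - 1.8) <= 1))
    expect_true(all(abs(tb[, "control"] - 4.2) <= 1))
  }
  # identical for the same seed, different across seeds
  sch2 <- make_cv_scheme(y, k = 10, r = 10, seed = 5)
  expect_identical(sch$assignments, sch2$assignments)
  sch3 <- make_cv_scheme(y, k = 10, r = 10, seed = 6)
  expect_false(identical(sch$assignments, sch3$assignments))
  expect_error(make_cv_scheme(factor(rep(c("a", "b"), c(5, 55))), k = 10),
               "stratification")
})

test_that("the linear classifier separates separable data and honors class weights", {
  set.seed(32)
  X <- rbind(matrix(rnorm(40, mean = -2), 20, 2),
             matrix(rnorm(40, mean = 2), 20, 2))
  colnames(X) <- c("u", "v")
  y <- factor(rep(c("control", "case"), each = 20))
  m <- fit_linear_classifier(X, y, classifier_spec())
  expect_equal(unname(mtsrep:::.fold_accuracy(y, predict_labels(m, X))$balanced_accuracy), 1)

  # imbalanced overlapping toy set: inverse-frequency weighting must
  # reduce minority-class errors relative to unweighted fitting
  set.seed(33)
  n_maj <- 90; n_min <- 10
  Xi <- rbind(matrix(rnorm(2 * n_maj, mean = 0), n_maj, 2),
              matrix(rnorm(2 * n_min, mean = 1.2), n_min, 2))
  colnames(Xi) <- c("u", "v")
  yi <- factor(rep(c("control", "case"), times = c(n_maj, n_min)),
               levels = c("control", "case"))
  m_w <- fit_linear_classifier(Xi, yi, classifier_spec())
  m_u <- fit_linear_classifier(Xi, yi,
                               classifier_spec(class_weighting = "none"))
  err_min_w <- mean(predict_labels(m_w, Xi)[yi == "case"] != "case")
  err_min_u <- mean(predict_labels(m_u, Xi)[yi == "case"] != "case")
  expect_lt(err_min_w, err_min_u)
})

test_that("repeated CV yields k*r accuracies and stays at chance under the null", {
  set.seed(34)
  y <- factor(rep(c("control", "case"), each = 20))
  X <- matrix(rnorm(40 * 6), 40, 6, dimnames = list(NULL, paste0("c", 1:6)))
  sch <- make_cv_scheme(y, k = 10, r = 10, seed = 2)
  cv <- run_repeated_cv(X, y, sch)
  expect_equal(nrow(cv$folds), 100)
  expect_true(all(cv$folds$balanced_accuracy >= 0 &
                    cv$folds$balanced_accuracy <= 1))
  # labels independent of X: mean stays within 3 SE of 0.5
  se <- sd(cv$folds$balanced_accuracy) / sqrt(10)  # ~r effective replicates
  expect_lt(abs(mean(cv$folds$balanced_accuracy) - 0.5), max(3 * se, 0.08))

  # shared-splits contract: two models under one scheme see identical folds
  X2 <- matrix(rnorm(40 * 3), 40, 3, dimnames = list(NULL, paste0("d", 1:3)))
  fd1 <- prepare_fold_data(X, sch); fd2 <- prepare_fold_data(X2, sch)
  expect_identical(lapply(fd1, `[[`, "te_idx"), lapply(fd2, `[[`, "te_idx"))
})

test_that("no imbalance collapse: 70/30 null data stays near chance with weighting", {
  set.seed(35)
  y <- factor(rep(c("control", "case"), times = c(42, 18)))
  X <- matrix(rnorm(60 * 5), 60, 5, dimnames = list(NULL, paste0("c", 1:5)))
  sch <- make_cv_scheme(y, k = 10, r = 5, seed = 3)
  cv <- run_repeated_cv(X, y, sch)
  expect_lt(abs(mean(cv$folds$balanced_accuracy) - 0.5), 0.08)
  # sensitivity not sacrificed wholesale to the majority class
  expect_gt(mean(cv$folds$sensitivity), 0.25)
})

test_that("missing cells are imputed from the training fold and never leak", {
  set.seed(36)
  y <- factor(rep(c("control", "case"), each = 15))
  X <- matrix(rnorm(30 * 4), 30, 4, dimnames = list(NULL, paste0("c", 1:4)))
  X[sample(length(X), 20)] <- NA
  sch <- make_cv_scheme(y, k = 5, r = 2, seed = 4)
  cv <- run_repeated_cv(X, y, sch)
  expect_equal(nrow(cv$folds), 10)
  expect_false(anyNA(cv$folds$balanced_accuracy))
})

test_that("leakage guard: test rows influence no fitted component", {
  set.seed(37)
  y <- factor(rep(c("control", "case"), each = 10))
  X <- matrix(rnorm(20 * 3), 20, 3, dimnames = list(NULL, paste0("c", 1:3)))
  sch <- make_cv_scheme(y, k = 5, r = 1, seed = 9)
  fd <- prepare_fold_data(X, sch)
  # corrupting a fold's test rows wildly must leave that fold's fitted
  # (training-side) matrices untouched
  for (i in seq_along(fd)) {
    Xc <- X
    te <- fd[[i]]$te_idx
    Xc[te, ] <- 1e6 * matrix(rnorm(length(te) * 3), ncol = 3)
    f2 <- prepare_fold_data(Xc, sch)[[i]]
    expect_identical(fd[[i]]$Xtr, f2$Xtr)
  }
})
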