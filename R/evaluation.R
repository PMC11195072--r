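# Cross-validated classification harness: outlier-robust sigmoidal
# normalization, inverse-probability-weighted linear SVM, balanced
# accuracy, repeated stratified CV with shared splits.

#' Outlier-robust sigmoidal normalization
#'
#' Fits, on training values only, the scaled outlier-robust sigmoid
#' y = 1 / (1 + exp(-(x - median) / (IQR / 1.349))), followed by a linear
#' rescale so the transformed training values span [0, 1]. The fitted
#' transform is then applied unchanged to test values, which may land
#' outside [0, 1] (they are deliberately not clipped, preserving
#' monotonicity in the tails). A zero training IQR falls back to a
#' mean/SD sigmoid; a constant training column maps everything to 0.5.
#'
#' @param train_column numeric training values (non-empty; NAs ignored
#'   when fitting).
#' @return a function mapping numeric vectors through the fitted
#'   transform.
#' @export
robust_sigmoid_normalize <- function(train_column) {
  v <- train_column[is.finite(train_column)]
  if (length(v) == 0) stop("empty training column")
  ctr <- stats::median(v)
  scl <- stats::IQR(v) / 1.349
  if (scl <= 0) {
    ctr <- mean(v)
    scl <- stats::sd(v)
  }
  if (!is.finite(scl) || scl <= 0) return(function(x) rep(0.5, length(x)))
  s_tr <- 1 / (1 + exp(-(v - ctr) / scl))
  lo <- min(s_tr); hi <- max(s_tr)
  if (hi - lo <= 0) return(function(x) rep(0.5, length(x)))
  function(x) (1 / (1 + exp(-(x - ctr) / scl)) - lo) / (hi - lo)
}

#' Balanced accuracy
#'
#' The mean of sensitivity and specificity; 50\% is chance level for any
#' class imbalance (a constant single-class predictor scores exactly 0.5).
#'
#' @param truth factor (or vector) with exactly two classes present; the
#'   second factor level is treated as the positive ("case") class.
#' @param predicted predicted labels on the same levels.
#' @return list with \code{balanced_accuracy}, \code{sensitivity},
#'   \code{specificity}.
#' @export
balanced_accuracy <- function(truth, predicted) {
  truth <- as.factor(truth)
  if (nlevels(droplevels(truth)) != 2)
    stop("truth must contain both classes")
  lv <- levels(truth)
  pos <- lv[2]; neg <- lv[1]
  predicted <- factor(as.character(predicted), levels = lv)
  sens <- mean(predicted[truth == pos] == pos)
  spec <- mean(predicted[truth == neg] == neg)
  list(balanced_accuracy = (sens + spec) / 2,
       sensitivity = sens, specificity = spec)
}

#' Classifier specification
#'
#' @param C regularization strength of the linear maximum-margin
#'   classifier (default 1).
#' @param class_weighting \code{"inverse_frequency"} (per-sample weights
#'   proportional to the inverse frequency of the sample's class) or
#'   \code{"none"}.
#' @return object of class \code{classifier_spec}.
#' @export
classifier_spec <- function(C = 1, class_weighting = c("inverse_frequency",
                                                       "none")) {
  stopifnot(C > 0)
  structure(list(C = C, class_weighting = match.arg(class_weighting)),
            class = "classifier_spec")
}

#' Fit the linear maximum-margin classifier
#'
#' Linear SVM (hinge loss, squared-norm penalty, cost \code{C}) with
#' optional inverse-probability class weights; deterministic given its
#' inputs.
#'
#' @param X_train numeric matrix (already normalized and imputed).
#' @param y_train factor with two levels present.
#' @param spec a \code{\link{classifier_spec}}.
#' @return fitted model usable with \code{\link{predict_labels}}.
#' @export
fit_linear_classifier <- function(X_train, y_train, spec = classifier_spec()) {
  y_train <- droplevels(as.factor(y_train))
  if (nlevels(y_train) != 2) stop("need both classes in the training data")
  cw <- NULL
  if (spec$class_weighting == "inverse_frequency") {
    tb <- table(y_train)
    cw <- as.numeric(length(y_train) / (2 * tb))
    names(cw) <- names(tb)
  }
  e1071::svm(x = X_train, y = y_train, kernel = "linear", cost = spec$C,
             scale = FALSE, class.weights = cw)
}

#' Predict class labels from a fitted classifier
#' @param model fitted classifier from \code{\link{fit_linear_classifier}}.
#' @param X numeric matrix with the training columns.
#' @return factor of predicted labels.
#' @export
predict_labels <- function(model, X) stats::predict(model, X)

#' Repeated stratified cross-validation scheme
#'
#' Builds the shared fold assignments used by every model compared under
#' the same seed and dataset: per repeat, each class's participants are
#' shuffled (seeded) and dealt round-robin into k folds, so per-fold class
#' counts differ from perfect stratification by at most one participant.
#'
#' @param y label vector of length N.
#' @param k folds per repeat (default 10).
#' @param r repeats (default 10).
#' @param seed integer RNG seed.
#' @return object of class \code{cv_scheme}: list with \code{k}, \code{r},
#'   \code{seed}, \code{n}, and \code{assignments}, an N x r integer
#'   matrix of fold ids.
#' @export
make_cv_scheme <- function(y, k = 10, r = 10, seed = 1) {
  y <- as.factor(y)
  n <- length(y)
  if (any(table(y) < k))
    stop("stratification impossible: a class has fewer than k members")
  assignments <- matrix(NA_integer_, n, r)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (j in seq_len(r)) {
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      assignments[idx, j] <- rep_len(seq_len(k), length(idx))
    }
  }
  structure(list(k = k, r = r, seed = seed, n = n,
                 assignments = assignments, labels = y),
            class = "cv_scheme")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Precompute imputed, normalized fold data
#'
#' For each of the k*r folds: train-fold median imputation per column,
#' then the robust sigmoid transform fitted on training rows and applied
#' to train and test rows. Label-independent, so the result can be reused
#' across label permutations.
#'
#' @param X numeric matrix or \code{design_matrix}.
#' @param scheme a \code{\link{make_cv_scheme}} result.
#' @return list of k*r fold entries with \code{Xtr}, \code{Xte},
#'   \code{tr_idx}, \code{te_idx}, \code{rep}, \code{fold}.
#' @export
prepare_fold_data <- function(X, scheme) {
  if (inherits(X, "design_matrix")) X <- X$X
  stopifnot(nrow(X) == scheme$n)
  out <- vector("list", scheme$k * scheme$r)
  pos <- 0
  for (j in seq_len(scheme$r)) {
    fa <- scheme$assignments[, j]
    for (f in seq_len(scheme$k)) {
      pos <- pos + 1
      te <- which(fa == f); tr <- which(fa != f)
      Xtr <- X[tr, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
      for (cc in seq_len(ncol(X))) {
        col <- Xtr[, cc]
        if (anyNA(col)) {
          med <- stats::median(col, na.rm = TRUE)
          if (!is.finite(med)) med <- 0
          col[is.na(col)] <- med
          Xtr[, cc] <- col
        }
        tf <- robust_sigmoid_normalize(Xtr[, cc])
        Xtr[, cc] <- tf(Xtr[, cc])
        cte <- Xte[, cc]
        if (anyNA(cte)) cte[is.na(cte)] <-
            stats::median(col, na.rm = TRUE)
        Xte[, cc] <- tf(cte)
      }
      out[[pos]] <- list(Xtr = Xtr, Xte = Xte, tr_idx = tr, te_idx = te,
                         rep = j, fold = f)
    }
  }
  out
}

# Fold-level accuracy: mean recall over the classes present in truth.
# Equals balanced accuracy when both classes are present; under label
# permutations a small test fold can be single-class, in which case the
# recall of that class is used (the convention of standard ML toolkits).
.fold_accuracy <- function(truth, predicted) {
  truth <- as.factor(truth)
  lv <- levels(truth)
  predicted <- factor(as.character(predicted), levels = lv)
  rec <- vapply(lv, function(cl) mean(predicted[truth == cl] == cl),
                numeric(1))
  pres <- table(truth) > 0
  list(balanced_accuracy = mean(rec[pres]),
       sensitivity = rec[[2]], specificity = rec[[1]])
}

# evaluate one fold; optionally in a train-fitted PCA space
.eval_fold <- function(fd, y, spec, return_train = FALSE, n_pcs = NULL) {
  ytr <- y[fd$tr_idx]; yte <- y[fd$te_idx]
  Xtr <- fd$Xtr; Xte <- fd$Xte
  if (!is.null(n_pcs)) {
    pc <- stats::prcomp(Xtr, center = TRUE, scale. = FALSE, rank. = n_pcs)
    Xtr <- pc$x[, seq_len(min(n_pcs, ncol(pc$x))), drop = FALSE]
    Xte <- stats::predict(pc, Xte)[, seq_len(ncol(Xtr)), drop = FALSE]
  }
  model <- fit_linear_classifier(Xtr, ytr, spec)
  te <- .fold_accuracy(yte, predict_labels(model, Xte))
  out <- list(balanced_accuracy = te$balanced_accuracy,
              sensitivity = te$sensitivity, specificity = te$specificity)
  if (return_train) {
    tr <- .fold_accuracy(ytr, predict_labels(model, Xtr))
    out$train_balanced_accuracy <- tr$balanced_accuracy
  }
  out
}

#' Run repeated stratified cross-validation for one model
#'
#' For each of the k*r folds: impute by train-fold median, fit the robust
#' sigmoid normalization on the training rows, transform train and test,
#' fit the weighted linear classifier, predict the test fold, and record
#' balanced accuracy. No test-fold information enters any fitted
#' component.
#'
#' @param X a \code{design_matrix} or numeric matrix (rows = participants
#'   in scheme order).
#' @param y binary label vector.
#' @param scheme a \code{\link{make_cv_scheme}} result (shared across all
#'   compared models).
#' @param spec a \code{\link{classifier_spec}}.
#' @param return_train also record resubstitution (in-sample) balanced
#'   accuracy per fold, used by fold-wise model selection.
#' @param n_pcs if non-NULL, reduce each normalized training fold to this
#'   many principal components (PCA fit on training rows only) before
#'   classification.
#' @param fold_data optional precomputed \code{\link{prepare_fold_data}}
#'   result for \code{X} (reused across label permutations).
#' @return object of class \code{cv_result}: data.frame \code{folds} with
#'   k*r rows (repeat, fold, balanced_accuracy, sensitivity, specificity,
#'   and optionally train_balanced_accuracy), plus \code{model} identity,
#'   the scheme parameters and realized mean train/test sizes.
#' @export
run_repeated_cv <- function(X, y, scheme, spec = classifier_spec(),
                            return_train = FALSE, n_pcs = NULL,
                            fold_data = NULL) {
  model_id <- if (inherits(X, "design_matrix"))
    paste0(X$kind, if (nzchar(X$unit_id)) paste0(":", X$unit_id) else "")
  else "matrix"
  if (is.null(fold_data)) fold_data <- prepare_fold_data(X, scheme)
  y <- as.factor(y)
  rows <- lapply(fold_data, function(fd) {
    ev <- .eval_fold(fd, y, spec, return_train, n_pcs)
    c(rep = fd$rep, fold = fd$fold, unlist(ev))
  })
  df <- as.data.frame(do.call(rbind, rows))
  names(df)[1:2] <- c("repeat_", "fold")
  n_te <- mean(vapply(fold_data, function(fd) length(fd$te_idx), numeric(1)))
  structure(list(folds = df, model = model_id, k = scheme$k, r = scheme$r,
                 seed = scheme$seed, n_train = scheme$n - n_te,
                 n_test = n_te),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s: %d folds, balanced accuracy %.3f +/- %.3f\n",
              x$model, nrow(x$folds), mean(x$folds$balanced_accuracy),
              stats::sd(x$folds$balanced_accuracy)))
  invisible(x)
}

#' Mean out-of-sample balanced accuracy of a CV result
#' @param result a \code{cv_result}.
#' @return scalar mean over the k*r fold accuracies.
#' @export
mean_balanced_accuracy <- function(result) {
  mean(result$folds$balanced_accuracy)
}
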