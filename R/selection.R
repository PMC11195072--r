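# Fold-wise best-model selection within a representation family, and PCA
# reduction.

#' Fold-wise best-model selection by in-sample training accuracy
#'
#' For every one of the k*r folds, each candidate model (e.g. one brain
#' region, or one time-series feature) is fit on the training fold; the
#' unit with the best in-sample (resubstitution) training balanced
#' accuracy is selected, and its out-of-sample test balanced accuracy is
#' retained for that fold. Training accuracies equal within 1e-12 count
#' as tied; ties contribute the mean of the tied units' test accuracies.
#' Selection never sees test rows or test labels.
#'
#' @param family named list of \code{design_matrix} objects (the
#'   candidate units).
#' @param y binary label vector.
#' @param scheme shared \code{\link{make_cv_scheme}} result.
#' @param spec a \code{\link{classifier_spec}}.
#' @return object of class \code{selection_result}: data.frame
#'   \code{folds} with k*r rows (repeat, fold, chosen,
#'   balanced_accuracy), \code{selection_freq} (per-unit fraction of
#'   folds won, ties fractional), and \code{kind}.
#' @export
select_best_by_training <- function(family, y, scheme,
                                    spec = classifier_spec()) {
  stopifnot(length(family) >= 1)
  if (is.null(names(family)) || any(!nzchar(names(family))))
    names(family) <- vapply(family, function(m)
      if (nzchar(m$unit_id)) m$unit_id else m$kind, character(1))
  res <- lapply(family, function(m)
    run_repeated_cv(m, y, scheme, spec, return_train = TRUE))
  .combine_selection(res, family[[1]]$kind)
}

.combine_selection <- function(res, kind, train_col = "train_balanced_accuracy") {
  units <- names(res)
  nf <- nrow(res[[1]]$folds)
  train_m <- sapply(res, function(r) r$folds[[train_col]])
  test_m <- sapply(res, function(r) r$folds$balanced_accuracy)
  chosen <- character(nf); acc <- numeric(nf)
  freq <- stats::setNames(numeric(length(units)), units)
  for (f in seq_len(nf)) {
    tr <- train_m[f, ]
    tied <- which(tr >= max(tr) - 1e-12)
    chosen[f] <- paste(units[tied], collapse = ",")
    acc[f] <- mean(test_m[f, tied])
    freq[tied] <- freq[tied] + 1 / length(tied)
  }
  structure(list(folds = data.frame(repeat_ = res[[1]]$folds$repeat_,
                                    fold = res[[1]]$folds$fold,
                                    chosen = chosen,
                                    balanced_accuracy = acc),
                 selection_freq = freq / nf, kind = kind,
                 k = res[[1]]$k, r = res[[1]]$r, seed = res[[1]]$seed,
                 n_train = res[[1]]$n_train, n_test = res[[1]]$n_test),
            class = c("selection_result"))
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> kind = %s: mean selected accuracy %.3f\n",
              x$kind, mean(x$folds$balanced_accuracy)))
  top <- sort(x$selection_freq, decreasing = TRUE)
  top <- top[top > 0]
  cat("  selection frequency:",
      paste(names(top), sprintf("%.2f", top), collapse = ", "), "\n")
  invisible(x)
}

#' Fold-wise SPI selection via a 10-PC training heuristic
#'
#' For very wide coupling matrices, resubstitution training accuracy
#' saturates at 100\% and cannot rank SPIs. Instead, within each training
#' fold a PCA is fit (on training rows of the normalized matrix, per SPI)
#' and the in-sample training balanced accuracy is measured in the space
#' of the first \code{n_pcs} components; the winning SPI is then refit on
#' its full feature space on the training fold, and its full-space
#' out-of-sample accuracy is recorded. Ties take the mean of the tied
#' SPIs' full-space test accuracies.
#'
#' @param family named list of \code{design_matrix} objects, one per SPI.
#' @param y binary label vector.
#' @param scheme shared \code{\link{make_cv_scheme}} result.
#' @param spec a \code{\link{classifier_spec}}.
#' @param n_pcs number of principal components for the selection space
#'   (default 10).
#' @return a \code{selection_result} (see
#'   \code{\link{select_best_by_training}}).
#' @export
select_best_spi_by_pca <- function(family, y, scheme,
                                   spec = classifier_spec(), n_pcs = 10) {
  stopifnot(length(family) >= 1)
  if (is.null(names(family)) || any(!nzchar(names(family))))
    names(family) <- vapply(family, function(m) m$unit_id, character(1))
  y <- as.factor(y)
  res <- lapply(family, function(m) {
    if (ncol(m$X) < n_pcs)
      stop("SPI matrix '", m$unit_id, "' has fewer than ", n_pcs, " columns")
    fd <- prepare_fold_data(m, scheme)
    full <- run_repeated_cv(m, y, scheme, spec, fold_data = fd)
    pc_train <- vapply(fd, function(f)
      .eval_fold(f, y, spec, return_train = TRUE,
                 n_pcs = n_pcs)$train_balanced_accuracy, numeric(1))
    full$folds$pc_train <- pc_train
    full
  })
  .combine_selection(res, family[[1]]$kind, train_col = "pc_train")
}

#' Reduce a design matrix to its leading principal components
#'
#' Columns are first passed through the robust sigmoid normalization
#' (fitted on all rows -- use the \code{n_pcs} argument of
#' \code{\link{run_repeated_cv}} for the leakage-free fold-wise variant
#' inside cross-validation), then decomposed; the leading components,
#' ordered by explained variance, become the new columns.
#'
#' @param X a \code{design_matrix}.
#' @param n_pcs number of components to retain (default 25).
#' @param normalize apply the robust sigmoid per column first
#'   (default TRUE).
#' @return a \code{design_matrix} of the same kind with \code{n_pcs}
#'   columns named PC1.. and an \code{explained_variance} attribute
#'   (fractions, non-increasing).
#' @export
pca_reduce <- function(X, n_pcs = 25, normalize = TRUE) {
  M <- X$X
  for (cc in seq_len(ncol(M))) {
    col <- M[, cc]
    if (anyNA(col)) {
      med <- stats::median(col, na.rm = TRUE)
      col[is.na(col)] <- if (is.finite(med)) med else 0
    }
    M[, cc] <- if (normalize) robust_sigmoid_normalize(col)(col) else col
  }
  n_pcs <- min(n_pcs, nrow(M), ncol(M))
  pc <- stats::prcomp(M, center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(n_pcs), drop = FALSE]
  colnames(scores) <- paste0("PC", seq_len(n_pcs))
  rownames(scores) <- rownames(X$X)
  out <- new_design_matrix(scores, X$kind, X$unit_id)
  attr(out, "explained_variance") <- (pc$sdev^2 / sum(pc$sdev^2))[
    seq_len(n_pcs)]
  out
}
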