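# Permutation nulls with Gaussian tail approximation, FDR correction,
# corrected resampled t-tests and similarity indices.

#' Permutation null distribution of mean balanced accuracy
#'
#' Refits the full repeated-CV harness under randomly shuffled labels:
#' each null sample is the mean out-of-sample balanced accuracy of one
#' complete repeated-CV run for one label permutation. The observed fold
#' splits are reused (the normalization and imputation are
#' label-independent, so the per-fold design matrices are precomputed
#' once and shared across permutations).
#'
#' @param X a \code{design_matrix} or numeric matrix.
#' @param y binary label vector.
#' @param scheme a \code{\link{make_cv_scheme}} result.
#' @param spec a \code{\link{classifier_spec}}.
#' @param n_perm number of label permutations (default 1000).
#' @param seed integer seed for the permutation stream.
#' @param fold_data optional precomputed \code{\link{prepare_fold_data}}.
#' @return object of class \code{null_distribution}: \code{samples}
#'   (n_perm null mean balanced accuracies), fitted \code{mu} and
#'   \code{sigma} (sample moments), \code{n_perm}, \code{seed}.
#' @export
permutation_null <- function(X, y, scheme, spec = classifier_spec(),
                             n_perm = 1000, seed = 1, fold_data = NULL) {
  stopifnot(n_perm >= 2)
  y <- as.factor(y)
  if (nlevels(droplevels(y)) != 2) stop("degenerate label vector")
  if (is.null(fold_data)) fold_data <- prepare_fold_data(X, scheme)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  perms <- replicate(n_perm, sample(seq_along(y)), simplify = FALSE)
  samples <- vapply(perms, function(pp) {
    yb <- y[pp]
    mean(vapply(fold_data, function(fd)
      .eval_fold(fd, yb, spec)$balanced_accuracy, numeric(1)))
  }, numeric(1))
  structure(list(samples = samples, mu = mean(samples),
                 sigma = stats::sd(samples), n_perm = n_perm, seed = seed),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution> n = %d, mu = %.4f, sigma = %.4f\n",
              x$n_perm, x$mu, x$sigma))
  invisible(x)
}

#' One-tailed Gaussian-tail p-value against a permutation null
#'
#' Approximates the null CDF with a Gaussian fitted to the permutation
#' samples' two moments: p = 1 - Phi((observed - mu) / sigma), the
#' probability of a null balanced accuracy at least as large as the
#' observed one. This makes very small p-values measurable without
#' prohibitively many permutations.
#'
#' @param observed observed mean balanced accuracy.
#' @param null a \code{\link{permutation_null}} result (or any list with
#'   \code{mu}, \code{sigma}).
#' @return one-tailed p-value in [0, 1].
#' @export
gaussian_tail_pvalue <- function(observed, null) {
  stopifnot(null$sigma > 0)
  1 - stats::pnorm((observed - null$mu) / null$sigma)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment with an explicit
#' family size (e.g. the number of regions, features or SPIs tested
#' within a disorder).
#'
#' @param pvalues numeric vector of raw p-values.
#' @param m family size (default \code{length(pvalues)}).
#' @return adjusted p-values, monotone and capped at 1.
#' @export
bh_adjust <- function(pvalues, m = length(pvalues)) {
  stats::p.adjust(pvalues, method = "BH", n = m)
}

#' Corrected resampled t-test for repeated k-fold CV
#'
#' Paired comparison of two models' per-fold balanced accuracies with the
#' variance correction for the overlap of training sets across folds:
#' t = mean(d) / sqrt((1/(k r) + n2/n1) var(d)), with d the fold-wise
#' accuracy differences, n1/n2 the realized mean train/test sizes, and
#' df = k r - 1 (two-tailed).
#'
#' @param a,b \code{cv_result} objects sharing the same fold scheme.
#' @return object of class \code{comparison_result}: \code{t_corr},
#'   \code{df}, \code{p_two_tailed}, \code{k}, \code{r}, \code{n1},
#'   \code{n2}.
#' @export
corrected_resampled_ttest <- function(a, b) {
  if (a$k != b$k || a$r != b$r || a$seed != b$seed ||
      nrow(a$folds) != nrow(b$folds))
    stop("CV results use mismatched schemes")
  d <- a$folds$balanced_accuracy - b$folds$balanced_accuracy
  kr <- a$k * a$r
  n1 <- a$n_train; n2 <- a$n_test
  v <- stats::var(d)
  m <- mean(d)
  if (v == 0) {
    t <- if (m == 0) 0 else sign(m) * Inf
  } else {
    t <- m / sqrt((1 / kr + n2 / n1) * v)
  }
  df <- kr - 1
  p <- 2 * stats::pt(-abs(t), df = df)
  structure(list(t_corr = t, df = df, p_two_tailed = p,
                 k = a$k, r = a$r, n1 = n1, n2 = n2),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> T_corr = %.3f (df = %d), p = %.4g\n",
              x$t_corr, x$df, x$p_two_tailed))
  invisible(x)
}

#' Absolute Spearman similarity of two items
#'
#' The similarity index between two features (or two SPIs): the absolute
#' Spearman rank correlation of their values concatenated across all
#' units (regions or pairs) and all included participants.
#'
#' @param values_a,values_b matched numeric vectors, length >= 3.
#' @return |rho| in [0, 1].
#' @export
similarity_index <- function(values_a, values_b) {
  stopifnot(length(values_a) == length(values_b), length(values_a) >= 3)
  abs(stats::cor(values_a, values_b, method = "spearman",
                 use = "pairwise.complete.obs"))
}

#' Pairwise similarity matrix over a set of items
#'
#' @param value_list named list of matched numeric vectors (one per item,
#'   e.g. one per feature, each concatenated over units x participants).
#' @return symmetric matrix of absolute Spearman correlations with unit
#'   diagonal.
#' @export
similarity_matrix <- function(value_list) {
  m <- length(value_list)
  out <- matrix(1, m, m, dimnames = list(names(value_list),
                                         names(value_list)))
  if (m < 2) return(out)
  for (i in 1:(m - 1)) for (j in (i + 1):m) {
    out[i, j] <- out[j, i] <-
      similarity_index(value_list[[i]], value_list[[j]])
  }
  out
}
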