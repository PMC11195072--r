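# Programmatic fixtures shared across the test files.

# tiny labeled dataset with iid noise series
tiny_dataset <- function(N = 6, R = 3, T = 40, seed = 1, tr = 2) {
  set.seed(seed)
  tabs <- replicate(N, matrix(rnorm(T * R), T, R), simplify = FALSE)
  meta <- data.frame(participant_id = sprintf("p%02d", 1:N),
                     diagnosis = rep(c("control", "case"), length.out = N),
                     age = sample(20:60, N, replace = TRUE),
                     sex = rep(0:1, length.out = N),
                     site = "s1",
                     mean_fd = runif(N, 0.05, 0.2))
  ts_dataset(tabs, sprintf("r%d", 1:R), meta$participant_id, tr, meta = meta)
}

# feature tensor filled with reproducible noise, for shape/projection tests
fake_feature_tensor <- function(N, R, seed = 1) {
  set.seed(seed)
  fn <- feature_names()
  vals <- array(rnorm(N * R * length(fn)), c(N, R, length(fn)),
                dimnames = list(sprintf("p%02d", 1:N), sprintf("r%d", 1:R), fn))
  structure(list(values = vals, feature_names = fn),
            class = "feature_tensor")
}

# design matrix around given matrix
dm <- function(X, kind = "feature", unit = "u") {
  if (is.null(colnames(X))) colnames(X) <- paste0("c", seq_len(ncol(X)))
  mtsrep:::new_design_matrix(X, kind, unit)
}

# minimal hand-built cv_result for inference tests
fake_cv_result <- function(ba, k = 10, r = 10, seed = 1,
                           n_train = 90, n_test = 10) {
  structure(list(folds = data.frame(repeat_ = rep(seq_len(r), each = k),
                                    fold = rep(seq_len(k), r),
                                    balanced_accuracy = ba),
                 model = "fake", k = k, r = r, seed = seed,
                 n_train = n_train, n_test = n_test),
            class = "cv_result")
}
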