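# Configuration and end-to-end orchestration.

#' Default pipeline configuration
#'
#' @return named list with every module-level setting: \code{tr_seconds},
#'   \code{fd_threshold_mm}, \code{seed}, \code{features} (all 25),
#'   \code{spis} (all 14), \code{cv} (folds, repeats), \code{nulls}
#'   (n, seed), \code{fdr_alpha}.
#' @export
default_config <- function() {
  list(tr_seconds = 2, fd_threshold_mm = 0.55, seed = 1,
       features = feature_names(), spis = spi_catalog()$spi,
       cv = list(folds = 10, repeats = 10),
       nulls = list(n = 1000, seed = NULL),
       fdr_alpha = 0.05)
}

#' Load a pipeline configuration from YAML
#'
#' Unspecified keys are filled from \code{\link{default_config}}; every
#' seed is explicit after loading (the null-permutation seed defaults to
#' \code{seed + 1} when absent).
#'
#' @param path YAML file path; NULL returns the defaults.
#' @return configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    # YAML 1.1 parses a bare key `n` as the boolean FALSE; map it back
    if (!is.null(user$nulls))
      names(user$nulls)[names(user$nulls) %in% c("FALSE", "n")] <- "n"
    for (k in names(user)) {
      if (is.list(cfg[[k]]) && is.list(user[[k]]))
        cfg[[k]][names(user[[k]])] <- user[[k]]
      else cfg[[k]] <- user[[k]]
    }
  }
  if (is.null(cfg$nulls$seed)) cfg$nulls$seed <- cfg$seed + 1
  stopifnot(cfg$tr_seconds > 0, cfg$cv$folds >= 2, cfg$cv$repeats >= 1)
  cfg
}

# SPI values reduced to one vector per participant-pair on the common
# unordered pair set (directed SPIs: mean of the two directions), for
# cross-SPI similarity.
.spi_common_values <- function(spi_tensor, spi) {
  e <- spi_tensor[[spi]]
  if (!e$directed) return(as.vector(e$values))
  pr <- e$pairs
  up <- pr$i < pr$j
  key <- paste(pmin(pr$i, pr$j), pmax(pr$i, pr$j))
  fwd <- e$values[, up, drop = FALSE]
  rev_idx <- match(key[up], key[!up])
  bwd <- e$values[, which(!up)[rev_idx], drop = FALSE]
  as.vector((fwd + bwd) / 2)
}

#' Run the full representation comparison
#'
#' End-to-end orchestration on one dataset: quality control, both feature
#' tensors, all five representation families, repeated-CV evaluation of
#' every model under shared fold splits, permutation-null calibrated
#' p-values with Benjamini-Hochberg correction per family, corrected
#' resampled t-tests of coupling-only versus coupling-plus-local models
#' per SPI, fold-wise selection per family, and similarity matrices.
#'
#' @param dataset a \code{ts_dataset}.
#' @param config configuration list (see \code{\link{load_config}}).
#' @param out_dir optional directory: tidy CSV outputs and a
#'   machine-readable run manifest are written there.
#' @param nulls compute permutation nulls and p-values (default TRUE;
#'   disabling skips the most expensive stage).
#' @return list with elements \code{qc}, \code{cv} (per-model results),
#'   \code{summary} (tidy per-model data.frame), \code{comparisons},
#'   \code{selection}, \code{similarity}, \code{scheme}, \code{config}.
#' @export
run_full_comparison <- function(dataset, config = default_config(),
                                out_dir = NULL, nulls = TRUE) {
  qc <- apply_qc(dataset, config$fd_threshold_mm)
  ds <- qc$dataset
  y <- diagnosis_labels(ds)
  scheme <- make_cv_scheme(y, k = config$cv$folds, r = config$cv$repeats,
                           seed = config$seed)
  spec <- classifier_spec()

  feats <- compute_feature_tensor(ds)
  spis <- compute_spi_tensor(ds, config$spis)

  models <- list()
  fams <- list(region = character(), feature = character(),
               fc = character(), fc_combo = character())
  for (r in ds$region_labels) {
    models[[paste0("region:", r)]] <- build_region(feats, r)
    fams$region <- c(fams$region, paste0("region:", r))
  }
  for (f in intersect(config$features, feature_names())) {
    models[[paste0("feature:", f)]] <- build_feature(feats, f)
    fams$feature <- c(fams$feature, paste0("feature:", f))
  }
  models[["uni_combo"]] <- build_uni_combo(feats)
  for (s in names(spis)) {
    models[[paste0("fc:", s)]] <- build_fc(spis, s)
    models[[paste0("fc_combo:", s)]] <- build_fc_combo(spis, s, feats)
    fams$fc <- c(fams$fc, paste0("fc:", s))
    fams$fc_combo <- c(fams$fc_combo, paste0("fc_combo:", s))
  }

  cv <- lapply(models, function(m) run_repeated_cv(m, y, scheme, spec))

  summary_df <- data.frame(
    model = names(cv),
    mean_balanced_accuracy = vapply(cv, mean_balanced_accuracy, numeric(1)),
    sd_balanced_accuracy = vapply(cv, function(x)
      stats::sd(x$folds$balanced_accuracy), numeric(1)),
    row.names = NULL)

  if (nulls) {
    nd <- lapply(names(models), function(nm)
      permutation_null(models[[nm]], y, scheme, spec,
                       n_perm = config$nulls$n, seed = config$nulls$seed))
    names(nd) <- names(models)
    summary_df$p <- vapply(names(models), function(nm)
      gaussian_tail_pvalue(summary_df$mean_balanced_accuracy[
        summary_df$model == nm], nd[[nm]]), numeric(1))
    summary_df$p_corr <- NA_real_
    for (fam in names(fams)) {
      sel <- summary_df$model %in% fams[[fam]]
      summary_df$p_corr[sel] <- bh_adjust(summary_df$p[sel])
    }
    sel <- summary_df$model == "uni_combo"
    summary_df$p_corr[sel] <- summary_df$p[sel]
  }

  comparisons <- lapply(names(spis), function(s)
    corrected_resampled_ttest(cv[[paste0("fc_combo:", s)]],
                              cv[[paste0("fc:", s)]]))
  names(comparisons) <- names(spis)

  selection <- list(
    region = select_best_by_training(models[fams$region], y, scheme, spec),
    feature = select_best_by_training(models[fams$feature], y, scheme, spec))
  if (length(fams$fc) > 0 &&
      all(vapply(models[fams$fc], function(m) ncol(m$X) >= 10, logical(1)))) {
    selection$fc <- select_best_spi_by_pca(models[fams$fc], y, scheme, spec)
    selection$fc_combo <- select_best_spi_by_pca(models[fams$fc_combo], y,
                                                 scheme, spec)
  }

  feat_vals <- lapply(feature_names(), function(f)
    as.vector(feats$values[, , f]))
  names(feat_vals) <- feature_names()
  spi_vals <- lapply(names(spis), function(s) .spi_common_values(spis, s))
  names(spi_vals) <- names(spis)
  similarity <- list(feature = similarity_matrix(feat_vals),
                     spi = similarity_matrix(spi_vals))

  out <- list(qc = qc$report, cv = cv, summary = summary_df,
              comparisons = comparisons, selection = selection,
              similarity = similarity, scheme = scheme, config = config)
  if (!is.null(out_dir)) .write_report(out, out_dir)
  out
}

.write_report <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$summary, file.path(out_dir, "model_summary.csv"),
                   row.names = FALSE)
  folds <- do.call(rbind, lapply(names(res$cv), function(nm) {
    df <- res$cv[[nm]]$folds
    cbind(model = nm, df)
  }))
  utils::write.csv(folds, file.path(out_dir, "fold_accuracies.csv"),
                   row.names = FALSE)
  comp <- do.call(rbind, lapply(names(res$comparisons), function(s) {
    x <- res$comparisons[[s]]
    data.frame(spi = s, t_corr = x$t_corr, df = x$df, p = x$p_two_tailed)
  }))
  if (!is.null(comp))
    utils::write.csv(comp, file.path(out_dir, "fc_combo_vs_fc.csv"),
                     row.names = FALSE)
  for (fam in names(res$selection))
    utils::write.csv(res$selection[[fam]]$folds,
                     file.path(out_dir, paste0("selection_", fam, ".csv")),
                     row.names = FALSE)
  manifest <- list(config = res$config,
                   seed = res$scheme$seed,
                   n_models = length(res$cv),
                   version = as.character(utils::packageVersion("mtsrep")),
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
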