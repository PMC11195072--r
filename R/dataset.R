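#' Construct a labeled multivariate time-series dataset
#'
#' The central container consumed by every downstream stage: an
#' \code{N x R x T} numeric array (participants x regions x timepoints)
#' together with participant metadata and the sampling interval.
#'
#' @param data numeric array \code{N x R x T}, or a list of \code{T x R}
#'   matrices (one per participant, rows = timepoints).
#' @param region_labels character vector of length R; must be unique.
#' @param participant_ids character vector of length N; must be unique.
#' @param tr_seconds positive sampling interval in seconds.
#' @param meta data.frame keyed by \code{participant_id} with columns
#'   \code{diagnosis} (exactly two levels over the dataset, e.g.
#'   case/control), \code{age} (years), \code{sex} (0 = male, 1 = female),
#'   \code{site}, and optionally \code{mean_fd} (mm).
#' @param motion optional named list of \code{6 x T} motion-parameter
#'   matrices (rows 1-3 translations in mm, rows 4-6 rotations in radians),
#'   keyed by participant id.
#' @return An object of class \code{ts_dataset}.
#' @export
ts_dataset <- function(data, region_labels, participant_ids, tr_seconds,
                       meta = NULL, motion = NULL) {
  if (is.list(data)) {
    stopifnot(length(data) == length(participant_ids))
    T <- nrow(data[[1]]); R <- ncol(data[[1]])
    arr <- array(NA_real_, c(length(data), R, T))
    for (i in seq_along(data)) {
      m <- as.matrix(data[[i]])
      if (!all(dim(m) == c(T, R)))
        stop("participant '", participant_ids[i], "': expected ", T, "x", R,
             " time series table, got ", nrow(m), "x", ncol(m))
      arr[i, , ] <- t(m)
    }
    data <- arr
  }
  stopifnot(is.array(data), length(dim(data)) == 3)
  N <- dim(data)[1]; R <- dim(data)[2]; T <- dim(data)[3]
  if (N < 1 || R < 1 || T < 1) stop("N, R, T must all be >= 1")
  if (length(region_labels) != R) stop("region_labels length != R")
  if (anyDuplicated(region_labels)) stop("region_labels must be unique")
  if (length(participant_ids) != N) stop("participant_ids length != N")
  if (anyDuplicated(participant_ids)) stop("duplicate participant ids")
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1 || tr_seconds <= 0)
    stop("tr_seconds must be a single positive number")
  if (!is.null(meta)) {
    meta <- as.data.frame(meta)
    if (!"participant_id" %in% names(meta)) stop("meta needs participant_id")
    if (!setequal(meta$participant_id, participant_ids))
      stop("meta participant ids do not match dataset")
    meta <- meta[match(participant_ids, meta$participant_id), , drop = FALSE]
    rownames(meta) <- NULL
    if ("diagnosis" %in% names(meta)) {
      lv <- unique(as.character(meta$diagnosis))
      if (length(lv) > 2) stop("diagnosis must have at most two levels")
    }
    if ("mean_fd" %in% names(meta) &&
        any(!is.na(meta$mean_fd) & meta$mean_fd < 0))
      stop("mean_fd must be >= 0")
  }
  dimnames(data) <- list(participant_ids, region_labels, NULL)
  structure(list(data = data, region_labels = region_labels,
                 participant_ids = participant_ids, tr_seconds = tr_seconds,
                 meta = meta, motion = motion),
            class = "ts_dataset")
}

#' @export
print.ts_dataset <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ts_dataset> %d participants x %d regions x %d timepoints (TR = %gs)\n",
              d[1], d[2], d[3], x$tr_seconds))
  if (!is.null(x$meta) && "diagnosis" %in% names(x$meta)) {
    tb <- table(x$meta$diagnosis)
    cat("  diagnosis:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.ts_dataset <- function(x) dim(x$data)

#' Number of participants, regions and timepoints
#' @param dataset a \code{ts_dataset}.
#' @return named integer vector \code{c(N, R, T)}.
#' @export
dataset_shape <- function(dataset) {
  d <- dim(dataset$data)
  c(N = d[1], R = d[2], T = d[3])
}

#' Extract one participant's time series as a T x R matrix
#' @param dataset a \code{ts_dataset}.
#' @param participant participant id or index.
#' @return numeric matrix, rows = timepoints, columns = regions.
#' @export
participant_matrix <- function(dataset, participant) {
  i <- if (is.character(participant))
    match(participant, dataset$participant_ids) else participant
  if (is.na(i) || i < 1 || i > dim(dataset$data)[1])
    stop("unknown participant: ", participant)
  m <- t(dataset$data[i, , , drop = TRUE])
  if (dim(dataset$data)[2] == 1) m <- matrix(m, ncol = 1)
  colnames(m) <- dataset$region_labels
  m
}

#' Subset a dataset by participants
#' @param dataset a \code{ts_dataset}.
#' @param keep participant ids (character) or indices to retain.
#' @return a \code{ts_dataset} containing only the retained participants,
#'   in their original order.
#' @export
subset_participants <- function(dataset, keep) {
  idx <- if (is.character(keep))
    match(keep, dataset$participant_ids) else as.integer(keep)
  if (anyNA(idx)) stop("unknown participant id(s)")
  idx <- sort(idx)
  ts_dataset(dataset$data[idx, , , drop = FALSE], dataset$region_labels,
             dataset$participant_ids[idx], dataset$tr_seconds,
             meta = if (!is.null(dataset$meta))
               dataset$meta[idx, , drop = FALSE] else NULL,
             motion = if (!is.null(dataset$motion))
               dataset$motion[dataset$participant_ids[idx]] else NULL)
}

#' Binary diagnosis labels of a dataset
#'
#' @param dataset a \code{ts_dataset} with a \code{diagnosis} metadata column.
#' @return factor of length N with two levels; the "case" level is the
#'   level named \code{"case"} if present, otherwise the rarer level.
#' @export
diagnosis_labels <- function(dataset) {
  if (is.null(dataset$meta) || !"diagnosis" %in% names(dataset$meta))
    stop("dataset has no diagnosis metadata")
  y <- as.character(dataset$meta$diagnosis)
  lv <- unique(y)
  if (length(lv) != 2) stop("diagnosis must have exactly two levels")
  pos <- if ("case" %in% lv) "case" else lv[which.min(table(y)[lv])]
  factor(y, levels = c(setdiff(lv, pos), pos))
}

#' Load a dataset from a participant manifest
#'
#' The manifest is a CSV with header
#' \code{participant_id,diagnosis,age,sex,site,mean_fd,timeseries_path};
#' each \code{timeseries_path} points to a wide CSV whose rows are
#' timepoints and whose columns are region labels (header row). Region
#' columns are aligned across participants by header name, not position;
#' the region order of the first participant defines the dataset order.
#' Loading fails atomically on any malformed input.
#'
#' @param manifest_path path to the manifest CSV.
#' @param config pipeline configuration list (see \code{\link{load_config}});
#'   \code{tr_seconds} is required.
#' @return a \code{ts_dataset}, participants in manifest order.
#' @export
load_dataset <- function(manifest_path, config) {
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  req <- c("participant_id", "timeseries_path")
  if (!all(req %in% names(man)))
    stop("manifest must contain columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(man$participant_id))
    stop("duplicate participant ids in manifest")
  base <- dirname(manifest_path)
  tabs <- vector("list", nrow(man))
  regions <- NULL
  for (i in seq_len(nrow(man))) {
    p <- man$timeseries_path[i]
    if (!file.exists(p)) p <- file.path(base, man$timeseries_path[i])
    if (!file.exists(p))
      stop("participant '", man$participant_id[i],
           "': time series file not found: ", man$timeseries_path[i])
    tab <- utils::read.csv(p, stringsAsFactors = FALSE, check.names = FALSE)
    if (!all(vapply(tab, is.numeric, logical(1))))
      stop("participant '", man$participant_id[i], "': non-numeric cells in ", p)
    if (is.null(regions)) {
      regions <- colnames(tab)
      if (anyDuplicated(regions)) stop("duplicate region labels in ", p)
    } else {
      if (!setequal(colnames(tab), regions))
        stop("participant '", man$participant_id[i],
             "': region columns do not match the first participant")
      tab <- tab[, regions, drop = FALSE]
    }
    tabs[[i]] <- as.matrix(tab)
  }
  Ts <- vapply(tabs, nrow, integer(1))
  if (length(unique(Ts)) > 1)
    stop("ragged time dimension across participants: T in {",
         paste(sort(unique(Ts)), collapse = ", "), "}")
  meta_cols <- intersect(c("participant_id", "diagnosis", "age", "sex",
                           "site", "mean_fd"), names(man))
  ts_dataset(tabs, regions, man$participant_id,
             tr_seconds = config$tr_seconds,
             meta = man[, meta_cols, drop = FALSE])
}

#' Write a dataset as manifest + per-participant wide CSVs
#'
#' Inverse of \code{\link{load_dataset}}: writing then re-loading
#' reproduces the data exactly (values serialized at full precision).
#'
#' @param dataset a \code{ts_dataset}.
#' @param dir output directory (created if absent).
#' @return the manifest path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsdir <- file.path(dir, "timeseries")
  dir.create(tsdir, showWarnings = FALSE)
  rel <- character(length(dataset$participant_ids))
  for (i in seq_along(dataset$participant_ids)) {
    id <- dataset$participant_ids[i]
    rel[i] <- file.path("timeseries", paste0(id, ".csv"))
    m <- participant_matrix(dataset, id)
    df <- as.data.frame(format(m, digits = 17, trim = TRUE, scientific = TRUE),
                        check.names = FALSE)
    utils::write.csv(df, file.path(dir, rel[i]), row.names = FALSE,
                     quote = FALSE)
  }
  meta <- dataset$meta
  if (is.null(meta))
    meta <- data.frame(participant_id = dataset$participant_ids)
  meta$timeseries_path <- rel
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(meta, manifest, row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
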