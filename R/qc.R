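#' Framewise displacement from six head-motion parameters
#'
#' Power et al. convention: the FD at frame t is the sum of the absolute
#' frame-to-frame changes of the three translations (mm) plus the three
#' rotations (radians) converted to arc length on a sphere of radius
#' \code{head_radius_mm}. The first frame has FD 0 by definition.
#'
#' @param motion numeric \code{6 x T} matrix: rows 1-3 translations in mm,
#'   rows 4-6 rotations in radians.
#' @param head_radius_mm sphere radius for the rotation-to-mm conversion;
#'   default 50 mm.
#' @return numeric vector of length T, all values >= 0, first value 0.
#' @export
compute_framewise_displacement <- function(motion, head_radius_mm = 50) {
  motion <- as.matrix(motion)
  if (nrow(motion) != 6) stop("motion must be a 6 x T matrix")
  if (ncol(motion) < 2) stop("need at least 2 frames")
  if (any(!is.finite(motion))) stop("non-finite motion values")
  d <- abs(motion[, -1, drop = FALSE] - motion[, -ncol(motion), drop = FALSE])
  fd <- colSums(d[1:3, , drop = FALSE]) +
    head_radius_mm * colSums(d[4:6, , drop = FALSE])
  c(0, fd)
}

#' Quality control: constant-zero and motion exclusion
#'
#' Removes, in order: (1) participants whose every region time series is
#' constant zero (max |x| < 1e-12 in all regions) -- the signature of a
#' failed preprocessing run; (2) participants with mean framewise
#' displacement above \code{fd_threshold_mm}. Mean FD is taken from the
#' \code{mean_fd} metadata column when present, otherwise derived from raw
#' motion traces when available; participants with neither are retained
#' with a warning.
#'
#' @param dataset a \code{ts_dataset}.
#' @param fd_threshold_mm exclusion threshold on mean FD, in mm
#'   (default 0.55).
#' @param head_radius_mm passed to
#'   \code{\link{compute_framewise_displacement}} when FD must be derived.
#' @return list with elements \code{dataset} (the filtered
#'   \code{ts_dataset}) and \code{report} (a \code{qc_report} with
#'   \code{excluded_constant}, \code{excluded_motion},
#'   \code{fd_threshold_mm}).
#' @export
apply_qc <- function(dataset, fd_threshold_mm = 0.55, head_radius_mm = 50) {
  ids <- dataset$participant_ids
  const_zero <- vapply(seq_along(ids), function(i) {
    max(abs(dataset$data[i, , ])) < 1e-12
  }, logical(1))
  excluded_constant <- ids[const_zero]

  mean_fd <- rep(NA_real_, length(ids))
  if (!is.null(dataset$meta) && "mean_fd" %in% names(dataset$meta))
    mean_fd <- as.numeric(dataset$meta$mean_fd)
  derive <- is.na(mean_fd) & !const_zero
  if (any(derive) && !is.null(dataset$motion)) {
    for (i in which(derive)) {
      m <- dataset$motion[[ids[i]]]
      if (!is.null(m))
        mean_fd[i] <- mean(compute_framewise_displacement(m, head_radius_mm))
    }
  }
  no_fd <- is.na(mean_fd) & !const_zero
  if (any(no_fd))
    warning("no mean FD available for ", sum(no_fd),
            " participant(s); motion criterion skipped for them")
  excluded_motion <- ids[!const_zero & !is.na(mean_fd) &
                           mean_fd > fd_threshold_mm]

  keep <- setdiff(ids, c(excluded_constant, excluded_motion))
  if (length(keep) == 0) stop("QC excluded every participant")
  out <- subset_participants(dataset, keep)
  if (!is.null(out$meta) && "diagnosis" %in% names(out$meta) &&
      !is.null(dataset$meta) &&
      length(unique(out$meta$diagnosis)) <
        length(unique(dataset$meta$diagnosis)))
    stop("QC excluded an entire diagnosis class")
  report <- structure(list(excluded_constant = excluded_constant,
                           excluded_motion = excluded_motion,
                           fd_threshold_mm = fd_threshold_mm),
                      class = "qc_report")
  list(dataset = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> FD threshold %.2f mm\n", x$fd_threshold_mm))
  cat("  constant-zero excluded:", length(x$excluded_constant), "\n")
  cat("  motion excluded:      ", length(x$excluded_motion), "\n")
  invisible(x)
}
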