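# Synthetic VAR(1) case-control generator: every pipeline stage is
# testable without restricted clinical data. Cases and controls share a
# stable VAR(1) backbone; group effects are planted as parameter deltas
# on per-region autocorrelation, noise scale, mean offset, or pairwise
# coupling.

#' Specification of a synthetic case-control dataset
#'
#' Defaults mirror a typical single-disorder resting-state cohort:
#' 48 cases vs 116 controls, T = 150 samples at TR = 2 s, and a weakly
#' autocorrelated, uncoupled VAR(1) backbone (diagonal coefficient 0.3,
#' unit noise).
#'
#' @param N_case,N_control group sizes.
#' @param R number of regions.
#' @param T timepoints per series.
#' @param tr_seconds sampling interval (s).
#' @param A R x R VAR(1) coefficient matrix for controls; default
#'   \code{0.3 * I}. Spectral radius must stay below 1 for both groups.
#' @param noise_sd length-R innovation SDs (default 1).
#' @param effects list of planted case-group effects; each element is a
#'   list with \code{target} (region index, pair \code{c(i, j)}, or
#'   \code{"global"}), \code{parameter} (one of \code{"ar_coef"},
#'   \code{"noise_sd"}, \code{"mean_offset"}, \code{"coupling"}) and
#'   \code{delta}.
#' @param motion generate 6-parameter random-walk motion traces and the
#'   derived mean FD (default FALSE; mean FD is then drawn directly).
#' @param burn_in samples discarded before recording (default 200).
#' @param seed integer RNG seed.
#' @return object of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(N_case = 48, N_control = 116, R = 82, T = 150,
                           tr_seconds = 2, A = NULL, noise_sd = 1,
                           effects = list(), motion = FALSE,
                           burn_in = 200, seed = 1) {
  if (is.null(A)) A <- diag(0.3, R)
  stopifnot(nrow(A) == R, ncol(A) == R)
  noise_sd <- rep_len(noise_sd, R)
  stopifnot(all(noise_sd > 0), N_case >= 1, N_control >= 1, T >= 2)
  structure(list(N_case = N_case, N_control = N_control, R = R, T = T,
                 tr_seconds = tr_seconds, A = A, noise_sd = noise_sd,
                 effects = effects, motion = motion, burn_in = burn_in,
                 seed = seed),
            class = "synthetic_spec")
}

spectral_radius <- function(A) max(Mod(eigen(A, only.values = TRUE)$values))

# apply planted effects to (A, noise_sd, mean) for the case group
.case_parameters <- function(spec) {
  A <- spec$A; noise_sd <- spec$noise_sd; mu <- numeric(spec$R)
  for (ef in spec$effects) {
    par <- ef$parameter; tg <- ef$target; dl <- ef$delta
    if (par == "ar_coef") {
      idx <- if (identical(tg, "global")) seq_len(spec$R) else tg
      for (i in idx) A[i, i] <- A[i, i] + dl
    } else if (par == "noise_sd") {
      idx <- if (identical(tg, "global")) seq_len(spec$R) else tg
      noise_sd[idx] <- noise_sd[idx] + dl
    } else if (par == "mean_offset") {
      idx <- if (identical(tg, "global")) seq_len(spec$R) else tg
      mu[idx] <- mu[idx] + dl
    } else if (par == "coupling") {
      stopifnot(length(tg) == 2)
      A[tg[1], tg[2]] <- A[tg[1], tg[2]] + dl
      A[tg[2], tg[1]] <- A[tg[2], tg[1]] + dl
    } else stop("unknown effect parameter: ", par)
  }
  list(A = A, noise_sd = noise_sd, mu = mu)
}

simulate_var1 <- function(A, noise_sd, T, burn_in) {
  R <- nrow(A)
  total <- T + burn_in
  eps <- matrix(stats::rnorm(total * R, sd = rep(noise_sd, each = total)),
                total, R)
  X <- matrix(0, total, R)
  X[1, ] <- eps[1, ]
  for (t in 2:total) X[t, ] <- as.numeric(A %*% X[t - 1, ]) + eps[t, ]
  X[(burn_in + 1):total, , drop = FALSE]
}

#' Generate a synthetic labeled dataset
#'
#' Each participant's series follows x_t = A_group x_{t-1} + eps_t with
#' eps ~ N(0, diag(noise_sd^2)); the first \code{burn_in} samples are
#' discarded so recordings start from the stationary regime. The case
#' group uses the effect-modified parameters. Demographics are drawn from
#' simple configurable distributions (age ~ N(35, 10) truncated to
#' [18, 65], sex ~ Bernoulli(0.5) with 0 = male / 1 = female, two sites).
#' Fully reproducible from the spec seed.
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @return a \code{ts_dataset} with diagnosis labels "control"/"case".
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spectral_radius(spec$A) >= 1)
    stop("control VAR(1) matrix is unstable (spectral radius >= 1)")
  cp <- .case_parameters(spec)
  if (spectral_radius(cp$A) >= 1)
    stop("case VAR(1) matrix is unstable (spectral radius >= 1)")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  N <- spec$N_control + spec$N_case
  diag_lab <- c(rep("control", spec$N_control), rep("case", spec$N_case))
  ids <- sprintf("sub-%03d", seq_len(N))
  tabs <- vector("list", N)
  motion <- if (spec$motion) stats::setNames(vector("list", N), ids) else NULL
  mean_fd <- numeric(N)
  for (i in seq_len(N)) {
    case <- diag_lab[i] == "case"
    A <- if (case) cp$A else spec$A
    sdv <- if (case) cp$noise_sd else spec$noise_sd
    X <- simulate_var1(A, sdv, spec$T, spec$burn_in)
    if (case && any(cp$mu != 0))
      X <- sweep(X, 2, cp$mu, "+")
    tabs[[i]] <- X
    if (spec$motion) {
      m <- rbind(
        t(replicate(3, cumsum(stats::rnorm(spec$T, sd = 0.02)))),
        t(replicate(3, cumsum(stats::rnorm(spec$T, sd = 4e-4)))))
      motion[[ids[i]]] <- m
      mean_fd[i] <- mean(compute_framewise_displacement(m))
    } else {
      mean_fd[i] <- abs(stats::rnorm(1, 0.12, 0.05))
    }
  }
  age <- pmin(pmax(round(stats::rnorm(N, 35, 10)), 18), 65)
  sex <- stats::rbinom(N, 1, 0.5)
  site <- sample(c("site1", "site2"), N, replace = TRUE)
  meta <- data.frame(participant_id = ids, diagnosis = diag_lab,
                     age = age, sex = sex, site = site, mean_fd = mean_fd,
                     stringsAsFactors = FALSE)
  ts_dataset(tabs, region_labels = sprintf("region_%02d", seq_len(spec$R)),
             participant_ids = ids, tr_seconds = spec$tr_seconds,
             meta = meta, motion = motion)
}

#' Stationary covariance of a VAR(1) process
#'
#' Solves the discrete Lyapunov equation Sigma = A Sigma A' + Q with
#' Q = diag(noise_sd^2); the ground truth for variance/correlation
#' recovery tests on simulated data.
#'
#' @param A R x R VAR(1) coefficient matrix (spectral radius < 1).
#' @param noise_sd length-R innovation SDs.
#' @return symmetric positive-definite R x R covariance matrix.
#' @export
expected_stationary_covariance <- function(A, noise_sd) {
  R <- nrow(A)
  noise_sd <- rep_len(noise_sd, R)
  if (spectral_radius(A) >= 1) stop("unstable VAR(1) matrix")
  Q <- diag(noise_sd^2, R)
  vecS <- solve(diag(R * R) - kronecker(A, A), as.vector(Q))
  S <- matrix(vecS, R, R)
  (S + t(S)) / 2
}
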