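#' The 14 statistics of pairwise interactions (SPIs)
#'
#' Each SPI maps a pair of z-scored time series to a scalar. Directed SPIs
#' are computed for all ordered region pairs; undirected SPIs only for
#' unordered pairs (the upper triangle of the coupling matrix).
#'
#' @return data.frame with columns \code{spi} and \code{directed}.
#' @export
spi_catalog <- function() {
  data.frame(
    spi = c("pearson", "DTW", "barycenter_DTW", "coherence_magnitude",
            "PLI", "power_envelope_corr", "phi_star",
            "ANM", "DI", "transfer_entropy", "spectral_GC",
            "PSI_frequency", "PSI_time_frequency", "cointegration"),
    directed = c(rep(FALSE, 7), rep(TRUE, 7)),
    stringsAsFactors = FALSE)
}

#' Pair index for a given number of regions
#'
#' Directed SPIs use all ordered pairs i != j (P = R(R-1), row-major);
#' undirected SPIs use i < j only (P = R(R-1)/2).
#'
#' @param R number of regions.
#' @param directed logical.
#' @return data.frame with integer columns \code{i}, \code{j} in a fixed
#'   deterministic (row-major) order.
#' @export
pair_index <- function(R, directed) {
  stopifnot(R >= 2)
  g <- expand.grid(j = seq_len(R), i = seq_len(R))[, c("i", "j")]
  g <- g[g$i != g$j, , drop = FALSE]
  if (!directed) g <- g[g$i < g$j, , drop = FALSE]
  rownames(g) <- NULL
  g
}

# --- elementary SPIs --------------------------------------------------------

#' Pearson correlation of two z-scored series
#' @param x,y numeric vectors of equal length.
#' @return correlation in [-1, 1]; equals the empirical covariance for
#'   z-scored inputs.
#' @export
pearson_spi <- function(x, y) stats::cor(x, y)

#' Dynamic time warping distance and barycenter statistic
#'
#' DTW is the unconstrained dynamic-programming minimum cumulative
#' |x_i - y_j| alignment cost. The barycenter statistic is the maximum of
#' the DTW barycenter average (DBA) of the two series: 10 refinement
#' iterations starting from the elementwise mean.
#'
#' @param x,y numeric vectors of equal length.
#' @return named vector \code{c(DTW, barycenter_DTW)}.
#' @export
dtw_features <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) > 0)
  d <- dtw_distance_cpp(x, y)
  b <- (x + y) / 2
  series <- list(x, y)
  for (iter in 1:10) {
    acc <- numeric(length(b)); cnt <- numeric(length(b))
    for (s in series) {
      p <- dtw_path_cpp(b, s)
      for (k in seq_len(nrow(p))) {
        acc[p[k, 1]] <- acc[p[k, 1]] + s[p[k, 2]]
        cnt[p[k, 1]] <- cnt[p[k, 1]] + 1
      }
    }
    b_new <- ifelse(cnt > 0, acc / cnt, b)
    if (max(abs(b_new - b)) < 1e-12) { b <- b_new; break }
    b <- b_new
  }
  c(DTW = d, barycenter_DTW = max(b))
}

#' Spectral pairwise statistics
#'
#' Welch cross-spectral statistics (settings shared with the univariate
#' spectral features) and analytic-signal phase statistics over the full
#' band.
#'
#' @param x,y numeric z-scored vectors, length >= 32.
#' @param tr_seconds sampling interval in seconds.
#' @return named vector: \code{coherence_magnitude} (mean |coherency|),
#'   \code{PSI_frequency} (phase slope index, antisymmetric in x and y),
#'   \code{PSI_time_frequency} (PSI averaged over 4 equal time windows),
#'   \code{PLI} (phase lag index), \code{power_envelope_corr}.
#' @export
spectral_spis <- function(x, y, tr_seconds = 1) {
  stopifnot(length(x) == length(y), length(x) >= 32)
  coherency <- function(a, b, seg_len = min(length(a), 64L)) {
    sxy <- welch_cross_spectrum(a, b, tr_seconds, seg_len)$spec
    sxx <- Re(welch_cross_spectrum(a, a, tr_seconds, seg_len)$spec)
    syy <- Re(welch_cross_spectrum(b, b, tr_seconds, seg_len)$spec)
    den <- sqrt(pmax(sxx * syy, 1e-300))
    sxy / den
  }
  psi_of <- function(a, b) {
    C <- coherency(a, b, seg_len = min(length(a), 64L))
    n <- length(C)
    if (n < 2) return(NA_real_)
    sum(Im(Conj(C[-n]) * C[-1]))
  }
  C <- coherency(x, y)
  coh <- mean(Mod(C))
  psi_f <- psi_of(x, y)
  # time-frequency variant: PSI averaged over 4 equal windows
  T <- length(x); wlen <- floor(T / 4)
  psi_tf <- mean(vapply(0:3, function(w) {
    idx <- (w * wlen + 1):((w + 1) * wlen)
    psi_of(x[idx], y[idx])
  }, numeric(1)))
  ax <- analytic_signal(x); ay <- analytic_signal(y)
  cross <- ax * Conj(ay)
  pli <- abs(mean(sign(Im(cross))))
  pec <- stats::cor(Mod(ax), Mod(ay))
  c(coherence_magnitude = coh, PSI_frequency = psi_f,
    PSI_time_frequency = psi_tf, PLI = pli, power_envelope_corr = pec)
}

# residual variance of OLS of resp on columns of pred (no intercept;
# series are centered); ML (1/n) variance
.resid_var <- function(resp, pred) {
  pred <- as.matrix(pred)
  beta <- solve(crossprod(pred), crossprod(pred, resp))
  r <- resp - pred %*% beta
  mean(r^2)
}

.resid_vec <- function(resp, pred) {
  pred <- as.matrix(pred)
  beta <- solve(crossprod(pred), crossprod(pred, resp))
  as.numeric(resp - pred %*% beta)
}

#' Gaussian transfer entropy TE(x -> y)
#'
#' Linear-Gaussian estimator with history length 1 and delay 1:
#' TE = (1/2) ln(sigma^2_restricted / sigma^2_full), comparing the
#' prediction of y_t from y_{t-1} alone against y_{t-1} and x_{t-1}.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return transfer entropy in nats (>= 0 up to numerical tolerance).
#' @export
transfer_entropy_gaussian <- function(x, y) {
  T <- length(y)
  stopifnot(length(x) == T, T >= 3)
  yt <- y[2:T] - mean(y[2:T])
  yp <- y[1:(T - 1)] - mean(y[1:(T - 1)])
  xp <- x[1:(T - 1)] - mean(x[1:(T - 1)])
  v_r <- .resid_var(yt, cbind(yp))
  v_f <- .resid_var(yt, cbind(yp, xp))
  0.5 * log(v_r / v_f)
}

#' Gaussian information-theoretic pairwise statistics
#'
#' Linear (Gaussian) estimators with history 1 and delay 1:
#' \code{transfer_entropy} is TE(x -> y); \code{DI} adds the instantaneous
#' Gaussian mutual information of the innovations (residuals of each
#' series regressed on the joint past); \code{phi_star} is the Gaussian
#' integrated-information proxy under mismatched decoding for the natural
#' bipartition \{x\},\{y\} (symmetric, >= 0 up to tolerance).
#'
#' @param x,y numeric z-scored vectors, length >= 50 recommended.
#' @return named vector \code{c(DI, transfer_entropy, phi_star)}; the two
#'   directed entries refer to the x -> y direction.
#' @export
information_spis <- function(x, y) {
  T <- length(y)
  stopifnot(length(x) == T, T >= 5)
  te <- transfer_entropy_gaussian(x, y)
  yt <- y[2:T] - mean(y[2:T]); xt <- x[2:T] - mean(x[2:T])
  yp <- y[1:(T - 1)] - mean(y[1:(T - 1)])
  xp <- x[1:(T - 1)] - mean(x[1:(T - 1)])
  ex <- .resid_vec(xt, cbind(xp, yp))
  ey <- .resid_vec(yt, cbind(xp, yp))
  rho <- stats::cor(ex, ey)
  mi_inst <- -0.5 * log(max(1 - rho^2, 1e-12))
  c(DI = te + mi_inst, transfer_entropy = te, phi_star = phi_star_gaussian(x, y))
}

#' Gaussian integrated information (Phi*) of a bivariate system
#'
#' Mismatched-decoding form for jointly Gaussian past/future with lag 1
#' and the bipartition \{x\},\{y\}: Phi* = I(past; future) - max_beta
#' I*(beta), where I*(beta) is the information transmitted when decoding
#' with the disconnected (part-wise) model raised to inverse temperature
#' beta. Symmetric in x and y; >= 0 up to numerical tolerance.
#'
#' @param x,y numeric vectors of equal length.
#' @return Phi* in nats.
#' @export
phi_star_gaussian <- function(x, y) {
  T <- length(x)
  stopifnot(length(y) == T, T >= 5)
  P <- cbind(x[1:(T - 1)], y[1:(T - 1)])   # past
  F <- cbind(x[2:T], y[2:T])               # future
  P <- scale(P, scale = FALSE); F <- scale(F, scale = FALSE)
  n <- nrow(P)
  S_X <- crossprod(P) / n
  S_Y <- crossprod(F) / n
  S_XY <- crossprod(P, F) / n              # cov(past, future)
  S_joint <- rbind(cbind(S_X, S_XY), cbind(t(S_XY), S_Y))
  ld <- function(M) determinant(M, logarithm = TRUE)$modulus[1]
  I_full <- 0.5 * (ld(S_X) + ld(S_Y) - ld(S_joint))
  # disconnected model: per-part scalar regressions of future on own past
  a <- diag(S_XY) / diag(S_X)
  c_d <- diag(S_Y) - diag(S_XY)^2 / diag(S_X)
  A_D <- diag(a, 2); C_D <- diag(pmax(c_d, 1e-12), 2)
  Ci <- diag(1 / diag(C_D), 2)
  R <- S_Y - A_D %*% S_XY - t(S_XY) %*% t(A_D) + A_D %*% S_X %*% t(A_D)
  istar <- function(beta) {
    M <- diag(2) + beta * S_X %*% t(A_D) %*% Ci %*% A_D
    Q <- solve(C_D / beta + A_D %*% S_X %*% t(A_D))
    0.5 * (ld(M) + sum(diag(Q %*% S_Y)) - beta * sum(diag(Ci %*% R)))
  }
  opt <- stats::optimize(istar, c(1e-6, 10), maximum = TRUE)
  max(I_full - opt$objective, 0)
}

# --- causal SPIs ------------------------------------------------------------

# distance correlation (V-statistic, double-centered)
distance_correlation <- function(a, b) {
  n <- length(a)
  A <- as.matrix(stats::dist(a)); B <- as.matrix(stats::dist(b))
  ctr <- function(M) M - outer(rowMeans(M), rep(1, n)) -
    outer(rep(1, n), colMeans(M)) + mean(M)
  A <- ctr(A); B <- ctr(B)
  dcov2 <- mean(A * B)
  dvx <- mean(A * A); dvy <- mean(B * B)
  if (dvx <= 0 || dvy <= 0) return(0)
  sqrt(dcov2 / sqrt(dvx * dvy))
}

#' Additive-noise-model statistic for the direction x -> y
#'
#' Fits a kernel ridge regression of y on x (RBF kernel, median-heuristic
#' bandwidth, ridge 0.1) and returns the distance correlation between x
#' and the residuals. Lower values indicate residuals independent of the
#' putative cause, i.e. more consistent with x -> y.
#'
#' @param x,y numeric vectors of equal length.
#' @return distance correlation in [0, 1].
#' @export
anm_statistic <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 10)
  d <- abs(outer(x, x, "-"))
  sigma <- stats::median(d[d > 0])
  if (!is.finite(sigma) || sigma <= 0) sigma <- 1
  K <- exp(-d^2 / (2 * sigma^2))
  alpha <- solve(K + 0.1 * diag(n), y)
  resid <- y - as.numeric(K %*% alpha)
  distance_correlation(x, resid)
}

# bivariate VAR(p) fit by OLS (centered data, no intercept)
fit_var <- function(X, p) {
  T <- nrow(X)
  Yt <- X[(p + 1):T, , drop = FALSE]
  Z <- do.call(cbind, lapply(1:p, function(l) X[(p + 1 - l):(T - l), ,
                                                drop = FALSE]))
  B <- solve(crossprod(Z), crossprod(Z, Yt))
  E <- Yt - Z %*% B
  Sigma <- crossprod(E) / nrow(E)
  A <- lapply(1:p, function(l) t(B[(2 * l - 1):(2 * l), , drop = FALSE]))
  list(A = A, Sigma = Sigma, n = nrow(E))
}

var_bic <- function(X, p) {
  f <- fit_var(X, p)
  n <- f$n
  n * determinant(f$Sigma, logarithm = TRUE)$modulus[1] +
    log(n) * (4 * p)
}

#' Spectral (Geweke) Granger causality x -> y
#'
#' Parametric frequency-domain Granger causality from a bivariate VAR fit
#' (order selected by BIC up to \code{max_order}), averaged over a uniform
#' frequency grid on [0, pi).
#'
#' @param x,y numeric vectors of equal length.
#' @param max_order maximum VAR order considered (default 10).
#' @param n_freq number of frequency-grid points (default 128).
#' @param order optional fixed VAR order (skips BIC selection).
#' @return named list: \code{gc_mean} (mean over frequencies),
#'   \code{gc_freq} (the per-frequency values), \code{order}.
#' @export
spectral_granger <- function(x, y, max_order = 10, n_freq = 128,
                             order = NULL) {
  X <- cbind(x - mean(x), y - mean(y))
  T <- nrow(X)
  pmax_ok <- min(max_order, floor((T - 2) / 4))
  if (is.null(order)) {
    bics <- vapply(1:pmax_ok, function(p) var_bic(X, p), numeric(1))
    order <- which.min(bics)
  }
  f <- fit_var(X, order)
  Sig <- f$Sigma
  # partial covariance of the x-innovation given the y-innovation
  sig_cond <- Sig[1, 1] - Sig[1, 2]^2 / Sig[2, 2]
  omegas <- pi * (seq_len(n_freq) - 0.5) / n_freq
  gc <- vapply(omegas, function(w) {
    Aw <- diag(2) + 0i
    for (l in seq_len(order)) Aw <- Aw - f$A[[l]] * exp(-1i * l * w)
    H <- solve(Aw)
    Syy <- Re((H %*% Sig %*% Conj(t(H)))[2, 2])
    den <- Syy - sig_cond * Mod(H[2, 1])^2
    log(Syy / max(den, 1e-300))
  }, numeric(1))
  list(gc_mean = mean(gc), gc_freq = gc, order = order)
}

# augmented Dickey-Fuller t-statistic (intercept, Schwert lag rule)
adf_statistic <- function(e, lags = NULL) {
  n <- length(e)
  if (is.null(lags)) lags <- max(1L, floor(4 * (n / 100)^0.25))
  de <- diff(e)
  k <- lags
  y <- de[(k + 1):length(de)]
  lag1 <- e[(k + 1):(length(e) - 1)]
  Z <- cbind(1, lag1)
  for (i in 1:k) Z <- cbind(Z, de[(k + 1 - i):(length(de) - i)])
  fit <- stats::lm.fit(Z, y)
  res <- fit$residuals
  s2 <- sum(res^2) / (length(y) - ncol(Z))
  XtXi <- solve(crossprod(Z))
  fit$coefficients[2] / sqrt(s2 * XtXi[2, 2])
}

#' Causal pairwise statistics for the direction x -> y
#'
#' @param x,y numeric vectors of equal length >= 50.
#' @return named vector: \code{ANM} (additive-noise-model residual
#'   dependence), \code{spectral_GC} (mean Geweke frequency-domain Granger
#'   causality), \code{cointegration} (augmented Dickey-Fuller statistic
#'   of the residuals of the OLS regression of y on x; strongly negative
#'   values indicate cointegration).
#' @export
causal_spis <- function(x, y) {
  resid <- stats::lm.fit(cbind(1, x), y)$residuals
  c(ANM = anm_statistic(x, y),
    spectral_GC = spectral_granger(x, y)$gc_mean,
    cointegration = as.numeric(adf_statistic(resid)))
}

# --- tensor computation -----------------------------------------------------

# all requested SPI values for both directions of one unordered pair
.pair_spis <- function(x, y, tr_seconds, spis) {
  und <- list(); fwd <- list(); bwd <- list()
  if ("pearson" %in% spis) und$pearson <- pearson_spi(x, y)
  if (any(c("DTW", "barycenter_DTW") %in% spis)) {
    d <- dtw_features(x, y)
    und$DTW <- d[["DTW"]]; und$barycenter_DTW <- d[["barycenter_DTW"]]
  }
  spectral_wanted <- c("coherence_magnitude", "PLI", "power_envelope_corr",
                       "PSI_frequency", "PSI_time_frequency")
  if (any(spectral_wanted %in% spis)) {
    s <- spectral_spis(x, y, tr_seconds)
    und$coherence_magnitude <- s[["coherence_magnitude"]]
    und$PLI <- s[["PLI"]]
    und$power_envelope_corr <- s[["power_envelope_corr"]]
    fwd$PSI_frequency <- s[["PSI_frequency"]]
    bwd$PSI_frequency <- -s[["PSI_frequency"]]
    fwd$PSI_time_frequency <- s[["PSI_time_frequency"]]
    bwd$PSI_time_frequency <- -s[["PSI_time_frequency"]]
  }
  if (any(c("DI", "transfer_entropy", "phi_star") %in% spis)) {
    i_f <- information_spis(x, y)
    i_b <- information_spis(y, x)
    und$phi_star <- i_f[["phi_star"]]
    fwd$DI <- i_f[["DI"]]; bwd$DI <- i_b[["DI"]]
    fwd$transfer_entropy <- i_f[["transfer_entropy"]]
    bwd$transfer_entropy <- i_b[["transfer_entropy"]]
  }
  if ("ANM" %in% spis) {
    fwd$ANM <- anm_statistic(x, y); bwd$ANM <- anm_statistic(y, x)
  }
  if ("spectral_GC" %in% spis) {
    fwd$spectral_GC <- spectral_granger(x, y)$gc_mean
    bwd$spectral_GC <- spectral_granger(y, x)$gc_mean
  }
  if ("cointegration" %in% spis) {
    fwd$cointegration <-
      as.numeric(adf_statistic(stats::lm.fit(cbind(1, x), y)$residuals))
    bwd$cointegration <-
      as.numeric(adf_statistic(stats::lm.fit(cbind(1, y), x)$residuals))
  }
  list(und = und, fwd = fwd, bwd = bwd)
}

#' Compute the pairwise-interaction tensor
#'
#' Evaluates each requested SPI on the z-scored series of every region
#' pair of every participant. Per-pair failures are recorded as missing
#' values (with a warning), never dataset-fatal.
#'
#' @param dataset a quality-controlled \code{ts_dataset}.
#' @param spis character vector of SPI names (subset of
#'   \code{spi_catalog()$spi}); default all 14.
#' @return object of class \code{spi_tensor}: a named list with one entry
#'   per SPI, each holding \code{values} (numeric N x P matrix) and
#'   \code{pairs} (its \code{\link{pair_index}}); plus attributes
#'   \code{participant_ids} and \code{region_labels}.
#' @export
compute_spi_tensor <- function(dataset, spis = spi_catalog()$spi) {
  cat_tab <- spi_catalog()
  unknown <- setdiff(spis, cat_tab$spi)
  if (length(unknown)) stop("unknown SPI(s): ", paste(unknown, collapse = ", "))
  d <- dim(dataset$data)
  N <- d[1]; R <- d[2]
  upairs <- pair_index(R, directed = FALSE)
  out <- list()
  for (s in spis) {
    dird <- cat_tab$directed[cat_tab$spi == s]
    pr <- pair_index(R, dird)
    out[[s]] <- list(values = matrix(NA_real_, N, nrow(pr)),
                     pairs = pr, directed = dird)
  }
  dir_key <- function(pr) paste(pr$i, pr$j)
  n_fail <- 0
  for (n in seq_len(N)) {
    Z <- apply(participant_matrix(dataset, n), 2, zscore_series)
    for (p in seq_len(nrow(upairs))) {
      i <- upairs$i[p]; j <- upairs$j[p]
      res <- tryCatch(.pair_spis(Z[, i], Z[, j], dataset$tr_seconds, spis),
                      error = function(e) NULL)
      if (is.null(res)) { n_fail <- n_fail + 1; next }
      for (s in spis) {
        if (!out[[s]]$directed) {
          if (!is.null(res$und[[s]]))
            out[[s]]$values[n, p] <- res$und[[s]]
        } else {
          key <- dir_key(out[[s]]$pairs)
          kf <- match(paste(i, j), key); kb <- match(paste(j, i), key)
          if (!is.null(res$fwd[[s]])) out[[s]]$values[n, kf] <- res$fwd[[s]]
          if (!is.null(res$bwd[[s]])) out[[s]]$values[n, kb] <- res$bwd[[s]]
        }
      }
    }
  }
  if (n_fail > 0)
    warning(n_fail, " pair computation(s) failed; recorded as missing")
  for (s in spis) {
    rn <- dataset$participant_ids
    cn <- paste(dataset$region_labels[out[[s]]$pairs$i],
                dataset$region_labels[out[[s]]$pairs$j], sep = "->")
    dimnames(out[[s]]$values) <- list(rn, cn)
  }
  structure(out, class = "spi_tensor",
            participant_ids = dataset$participant_ids,
            region_labels = dataset$region_labels)
}

#' @export
print.spi_tensor <- function(x, ...) {
  cat(sprintf("<spi_tensor> %d SPI(s), %d participants\n", length(x),
              length(attr(x, "participant_ids"))))
  for (s in names(x))
    cat(sprintf("  %-20s %s P = %d\n", s,
                if (x[[s]]$directed) "directed  " else "undirected",
                ncol(x[[s]]$values)))
  invisible(x)
}
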