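#' The 25 univariate time-series feature names
#'
#' Fixed order (alphabetical, as tabulated); every feature tensor uses it.
#' @return character vector of length 25.
#' @export
feature_names <- function() {
  c("ACF_first_min", "ACF_timescale", "AMI_timescale", "AMI2",
    "centroid_freq", "DFA", "embedding_dist", "entropy_pairs", "fALFF",
    "forecast_error", "high_fluctuation", "low_freq_power", "mean",
    "mode_10", "mode_5", "outlier_timing_neg", "outlier_timing_pos",
    "periodicity", "rs_range", "SD", "stretch_decreasing", "stretch_high",
    "transition_variance", "trev", "whiten_timescale")
}

#' z-score a time series
#'
#' Centering by the mean and scaling by the sample SD (denominator n-1).
#' All features except the raw mean and SD are computed on the z-scored
#' series, making them invariant to positive affine transforms of the
#' input.
#'
#' @param x numeric vector, length >= 2.
#' @return z-scored vector (mean 0, sample SD 1); all-\code{NA} for a
#'   constant or non-finite input (the undefined-feature sentinel).
#' @export
zscore_series <- function(x) {
  if (length(x) < 2 || any(!is.finite(x))) return(rep(NA_real_, length(x)))
  s <- stats::sd(x)
  if (!is.finite(s) || s < 1e-14 * max(1, abs(mean(x))))
    return(rep(NA_real_, length(x)))
  (x - mean(x)) / s
}

# --- autocorrelation-based features ----------------------------------------

# smallest lag k >= 1 with ACF(k) < 1/e
first_1e_crossing <- function(ac) {
  k <- which(ac[-1] < exp(-1))
  if (length(k) == 0) return(NA_real_)
  k[1]
}

autocorrelation_features <- function(z) {
  T <- length(z)
  if (T < 10 || anyNA(z)) {
    return(c(ACF_timescale = NA_real_, ACF_first_min = NA_real_,
             periodicity = NA_real_, whiten_timescale = NA_real_))
  }
  ac <- acf_biased(z)
  tau <- first_1e_crossing(ac)
  # first lag at a local ACF minimum
  first_min <- NA_real_
  if (length(ac) >= 3) {
    for (k in 2:(length(ac) - 1)) {
      if (ac[k] < ac[k - 1] && ac[k] < ac[k + 1]) { first_min <- k - 1; break }
    }
  }
  # first local ACF maximum at lag >= 2 with positive value; 0 if none
  per <- 0
  if (length(ac) >= 4) {
    for (k in 3:(length(ac) - 1)) {  # ac index k = lag k-1
      if (ac[k] > ac[k - 1] && ac[k] > ac[k + 1] && ac[k] > 0) {
        per <- k - 1; break
      }
    }
  }
  dz <- diff(z)
  tau_d <- first_1e_crossing(acf_biased(dz))
  c(ACF_timescale = as.numeric(tau), ACF_first_min = first_min,
    periodicity = as.numeric(per),
    whiten_timescale = as.numeric(tau_d) - as.numeric(tau))
}

# --- spectral features ------------------------------------------------------

spectral_features <- function(z, tr_seconds) {
  if (length(z) < 16 || anyNA(z) || tr_seconds <= 0) {
    return(c(centroid_freq = NA_real_, low_freq_power = NA_real_,
             fALFF = NA_real_))
  }
  ps <- welch_psd(z, tr_seconds)
  S <- ps$spec; f <- ps$freq
  tot <- sum(S)
  if (tot <= 0) {
    return(c(centroid_freq = NA_real_, low_freq_power = NA_real_,
             fALFF = NA_real_))
  }
  centroid <- sum(f * S) / tot
  low <- sum(S[f <= 0.2 * max(f)]) / tot
  falff <- sum(S[f >= 0.01 & f <= 0.08]) / tot
  c(centroid_freq = centroid, low_freq_power = low, fALFF = falff)
}

# --- fluctuation analysis ---------------------------------------------------

# log-spaced integer scales in [5, T/4]; slope fit over the lower half
fluctuation_scales <- function(T, n = 20) {
  smax <- floor(T / 4)
  if (smax < 5) return(integer(0))
  unique(round(exp(seq(log(5), log(smax), length.out = n))))
}

dfa_fluctuation <- function(z, s) {
  y <- cumsum(z - mean(z))
  nwin <- floor(length(y) / s)
  if (nwin < 1) return(NA_real_)
  tt <- seq_len(s)
  sx2 <- sum((tt - mean(tt))^2)
  f2 <- vapply(seq_len(nwin), function(w) {
    seg <- y[((w - 1) * s + 1):(w * s)]
    b <- sum((tt - mean(tt)) * (seg - mean(seg))) / sx2
    res <- seg - (mean(seg) + b * (tt - mean(tt)))
    mean(res^2)
  }, numeric(1))
  sqrt(mean(f2))
}

# Anis-Lloyd expected R/S of iid noise at window length n (with the
# small-n exact-gamma form); used to de-bias the rescaled-range exponent.
rs_expected_iid <- function(n) {
  i <- seq_len(n - 1)
  s <- sum(sqrt((n - i) / i))
  if (n <= 340) {
    pref <- exp(lgamma((n - 1) / 2) - lgamma(n / 2)) / sqrt(pi)
  } else {
    pref <- 1 / sqrt(n * pi / 2)
  }
  (n - 0.5) / n * pref * s
}

rs_fluctuation <- function(z, s) {
  nwin <- floor(length(z) / s)
  if (nwin < 1) return(NA_real_)
  rs <- vapply(seq_len(nwin), function(w) {
    seg <- z[((w - 1) * s + 1):(w * s)]
    y <- cumsum(seg - mean(seg))
    rng <- max(y) - min(y)
    sdv <- stats::sd(seg)
    if (sdv <= 0) return(NA_real_)
    rng / sdv
  }, numeric(1))
  mean(rs, na.rm = TRUE)
}

fluctuation_features <- function(z) {
  T <- length(z)
  if (T < 50 || anyNA(z)) return(c(DFA = NA_real_, rs_range = NA_real_))
  scales <- fluctuation_scales(T)
  if (length(scales) < 6) return(c(DFA = NA_real_, rs_range = NA_real_))
  lower <- scales[seq_len(ceiling(length(scales) / 2))]
  fit_slope <- function(vals) {
    ok <- is.finite(vals) & vals > 0
    if (sum(ok) < 3) return(NA_real_)
    stats::coef(stats::lm(log(vals[ok]) ~ log(lower[ok])))[[2]]
  }
  dfa <- fit_slope(vapply(lower, function(s) dfa_fluctuation(z, s),
                          numeric(1)))
  # rescaled-range exponent, de-biased against the Anis-Lloyd iid
  # expectation: H = 0.5 + slope of log(R/S observed / R/S iid-expected)
  rs_obs <- vapply(lower, function(s) rs_fluctuation(z, s), numeric(1))
  rs_iid <- vapply(lower, rs_expected_iid, numeric(1))
  ratio <- rs_obs / rs_iid
  ok <- is.finite(ratio) & ratio > 0
  rs <- if (sum(ok) < 3) NA_real_ else
    0.5 + stats::coef(stats::lm(log(ratio[ok]) ~ log(lower[ok])))[[2]]
  c(DFA = dfa, rs_range = rs)
}

# --- symbolic / information-theoretic features ------------------------------

# Gaussian automutual information AMI(k) = -0.5*log(1 - rho(k)^2)
symbolic_info_features <- function(z) {
  T <- length(z)
  out <- c(AMI_timescale = NA_real_, AMI2 = NA_real_,
           entropy_pairs = NA_real_, transition_variance = NA_real_)
  if (T < 20 || anyNA(z)) return(out)

  ac <- acf_biased(z)
  rho2 <- pmin(ac[-1]^2, 1 - 1e-12)
  ami <- -0.5 * log(1 - rho2)
  for (k in 2:(length(ami) - 1)) {
    if (ami[k] < ami[k - 1] && ami[k] < ami[k + 1]) {
      out["AMI_timescale"] <- k; break
    }
  }
  if (is.na(out["AMI_timescale"])) out["AMI_timescale"] <- length(ami)

  # plug-in MI (nats) of the 5x5 joint histogram of (z_t, z_{t+2})
  a <- z[1:(T - 2)]; b <- z[3:T]
  brk_a <- seq(min(a), max(a), length.out = 6); brk_a[c(1, 6)] <- c(-Inf, Inf)
  brk_b <- seq(min(b), max(b), length.out = 6); brk_b[c(1, 6)] <- c(-Inf, Inf)
  joint <- table(cut(a, brk_a), cut(b, brk_b)) / (T - 2)
  pa <- rowSums(joint); pb <- colSums(joint)
  nz <- joint > 0
  out["AMI2"] <- sum(joint[nz] * log(joint[nz] /
                                       outer(pa, pb)[nz]))

  # equiprobable tercile symbolization
  q <- stats::quantile(z, c(1, 2) / 3, type = 7)
  sym <- findInterval(z, q, rightmost.closed = FALSE) + 1L  # 1..3
  if (length(unique(sym)) < 2) return(out)
  pairs <- paste(sym[-T], sym[-1])
  p_pair <- table(pairs) / (T - 1)
  out["entropy_pairs"] <- -sum(p_pair * log(p_pair))

  trans <- matrix(0, 3, 3)
  for (t in 1:(T - 1)) trans[sym[t], sym[t + 1]] <- trans[sym[t], sym[t + 1]] + 1
  rs <- rowSums(trans)
  trans <- trans / ifelse(rs == 0, 1, rs)
  pop_var <- function(v) mean((v - mean(v))^2)
  out["transition_variance"] <- sum(apply(trans, 2, pop_var))
  out
}

# --- distribution / location features ---------------------------------------

hist_mode <- function(z, k) {
  brk <- seq(min(z), max(z), length.out = k + 1)
  cnt <- tabulate(findInterval(z, brk, rightmost.closed = TRUE,
                               all.inside = TRUE), nbins = k)
  i <- which.max(cnt)
  (brk[i] + brk[i + 1]) / 2
}

distribution_features <- function(x_raw, z) {
  T <- length(z)
  out <- c(mean = NA_real_, SD = NA_real_, mode_5 = NA_real_,
           mode_10 = NA_real_, outlier_timing_pos = NA_real_,
           outlier_timing_neg = NA_real_, high_fluctuation = NA_real_)
  if (T >= 2 && all(is.finite(x_raw))) {
    out["mean"] <- mean(x_raw)
    out["SD"] <- stats::sd(x_raw)
  }
  if (T < 10 || anyNA(z)) return(out)
  out["mode_5"] <- hist_mode(z, 5)
  out["mode_10"] <- hist_mode(z, 10)
  n_out <- max(1L, ceiling(0.05 * T))
  ord <- order(z)
  out["outlier_timing_neg"] <- mean(ord[seq_len(n_out)]) / T
  out["outlier_timing_pos"] <- mean(ord[(T - n_out + 1):T]) / T
  out["high_fluctuation"] <- mean(abs(diff(z)) > 0.04)
  out
}

# --- residual / shape features ----------------------------------------------

longest_run <- function(flags) {
  if (!any(flags)) return(0L)
  r <- rle(flags)
  max(r$lengths[r$values])
}

residual_and_shape_features <- function(z) {
  T <- length(z)
  out <- c(forecast_error = NA_real_, stretch_decreasing = NA_real_,
           stretch_high = NA_real_, trev = NA_real_,
           embedding_dist = NA_real_)
  if (T < 10 || anyNA(z)) return(out)

  pred <- vapply(4:T, function(t) mean(z[(t - 3):(t - 1)]), numeric(1))
  out["forecast_error"] <- stats::sd(z[4:T] - pred)

  out["stretch_decreasing"] <- longest_run(diff(z) < 0)
  out["stretch_high"] <- longest_run(z > mean(z))

  d <- diff(z)
  m2 <- mean(d^2)
  if (m2 > 0) out["trev"] <- mean(d^3) / m2^1.5

  # distances between successive points in the 2-d lag-1 embedding,
  # compared against a fitted exponential density
  ex <- z[1:(T - 1)]; ey <- z[2:T]
  dd <- sqrt(diff(ex)^2 + diff(ey)^2)
  mu <- mean(dd)
  if (mu > 0) {
    nb <- 20L
    brk <- seq(0, max(dd), length.out = nb + 1)
    h <- tabulate(findInterval(dd, brk, rightmost.closed = TRUE,
                               all.inside = TRUE), nbins = nb)
    dens <- h / (length(dd) * diff(brk))
    ctr <- (brk[-1] + brk[-(nb + 1)]) / 2
    out["embedding_dist"] <- mean(abs(dens - stats::dexp(ctr, rate = 1 / mu)))
  }
  out
}

#' Compute all 25 univariate features for one time series
#'
#' Mean and SD are computed on the raw series; everything else on the
#' z-scored series. Undefined values (constant series, failed fits) are
#' returned as \code{NA}, never silently zero.
#'
#' @param x numeric vector (raw series).
#' @param tr_seconds sampling interval in seconds (needed for the absolute
#'   frequency band of fALFF).
#' @return named numeric vector of length 25 in \code{\link{feature_names}}
#'   order.
#' @export
compute_features <- function(x, tr_seconds) {
  z <- zscore_series(x)
  vals <- c(autocorrelation_features(z),
            spectral_features(z, tr_seconds),
            fluctuation_features(z),
            symbolic_info_features(z),
            distribution_features(x, z),
            residual_and_shape_features(z))
  vals[feature_names()]
}

#' Compute the N x R x F univariate feature tensor
#'
#' @param dataset a quality-controlled \code{ts_dataset}.
#' @return object of class \code{feature_tensor}: list with \code{values}
#'   (numeric array N x R x 25, dimnames participant/region/feature) and
#'   \code{feature_names}.
#' @export
compute_feature_tensor <- function(dataset) {
  d <- dim(dataset$data)
  fn <- feature_names()
  vals <- array(NA_real_, c(d[1], d[2], length(fn)),
                dimnames = list(dataset$participant_ids,
                                dataset$region_labels, fn))
  for (i in seq_len(d[1])) for (r in seq_len(d[2])) {
    vals[i, r, ] <- compute_features(dataset$data[i, r, ],
                                     dataset$tr_seconds)
  }
  structure(list(values = vals, feature_names = fn),
            class = "feature_tensor")
}

#' @export
print.feature_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<feature_tensor> %d participants x %d regions x %d features\n",
              d[1], d[2], d[3]))
  invisible(x)
}

#' Feature tensor as tidy long data
#' @param tensor a \code{feature_tensor}.
#' @return data.frame with columns participant_id, region, feature, value.
#' @export
feature_tensor_long <- function(tensor) {
  d <- dimnames(tensor$values)
  data.frame(expand.grid(participant_id = d[[1]], region = d[[2]],
                         feature = d[[3]], stringsAsFactors = FALSE,
                         KEEP.OUT.ATTRS = FALSE),
             value = as.vector(tensor$values))
}
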