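# Shared spectral machinery: Welch auto-/cross-spectra and the analytic
# signal. Settings are shared between the univariate spectral features and
# the spectral pairwise statistics so both see the same estimator.

hann_window <- function(L) {
  if (L == 1) return(1)
  0.5 * (1 - cos(2 * pi * (0:(L - 1)) / (L - 1)))
}

welch_segments <- function(T, seg_len) {
  step <- max(1, floor(seg_len / 2))  # 50% overlap
  starts <- seq(1, T - seg_len + 1, by = step)
  lapply(starts, function(s) s:(s + seg_len - 1))
}

#' Welch cross-spectral density of two series
#'
#' Hann window, segment length \code{min(T, 64)}, 50\% overlap, one-sided.
#' With \code{y = x} this is the Welch power spectral density. Frequencies
#' are in Hz given the sampling interval \code{tr_seconds}.
#'
#' @param x,y numeric vectors of equal length (\code{y} defaults to
#'   \code{x}).
#' @param tr_seconds sampling interval in seconds.
#' @param seg_len segment length; default \code{min(length(x), 64)}.
#' @return list with \code{freq} (Hz, DC to Nyquist) and \code{spec}
#'   (complex cross-spectral density; real for \code{y = x}).
#' @export
welch_cross_spectrum <- function(x, y = x, tr_seconds = 1,
                                 seg_len = min(length(x), 64L)) {
  T <- length(x)
  stopifnot(length(y) == T, T >= 2, seg_len >= 2)
  w <- hann_window(seg_len)
  segs <- welch_segments(T, seg_len)
  nfreq <- floor(seg_len / 2) + 1
  acc <- complex(nfreq)
  for (idx in segs) {
    fx <- stats::fft((x[idx] - mean(x[idx])) * w)[1:nfreq]
    fy <- stats::fft((y[idx] - mean(y[idx])) * w)[1:nfreq]
    acc <- acc + fx * Conj(fy)
  }
  spec <- acc / (length(segs) * sum(w^2))
  fs <- 1 / tr_seconds
  freq <- (0:(nfreq - 1)) * fs / seg_len
  list(freq = freq, spec = spec)
}

welch_psd <- function(x, tr_seconds = 1, seg_len = min(length(x), 64L)) {
  cs <- welch_cross_spectrum(x, x, tr_seconds, seg_len)
  list(freq = cs$freq, spec = Re(cs$spec))
}

#' Analytic signal via the frequency-domain Hilbert transform
#'
#' @param x numeric vector.
#' @return complex vector of the same length; \code{Mod()} gives the
#'   amplitude envelope, \code{Arg()} the instantaneous phase.
#' @export
analytic_signal <- function(x) {
  T <- length(x)
  h <- numeric(T)
  if (T %% 2 == 0) {
    h[c(1, T / 2 + 1)] <- 1
    h[2:(T / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((T + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x - mean(x)) * h, inverse = TRUE) / T
}

# Biased-normalization ACF (1/T) via FFT, lags 0..max_lag.
acf_biased <- function(x, max_lag = floor(length(x) / 2)) {
  T <- length(x)
  xc <- x - mean(x)
  n <- stats::nextn(2 * T, 2)
  f <- stats::fft(c(xc, numeric(n - T)))
  ac <- Re(stats::fft(f * Conj(f), inverse = TRUE))[1:(max_lag + 1)] / n
  if (ac[1] <= 0) return(rep(NA_real_, max_lag + 1))
  ac / ac[1]
}
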