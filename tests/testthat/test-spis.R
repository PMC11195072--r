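# Pairwise statistics: hand evaluations, closed forms, dual-route
# identities and symmetry contracts.

# independent brute-force DTW oracle: plain recursion, usable for short
# series only
dtw_brute <- function(x, y) {
  rec <- function(i, j) {
    if (i == 1 && j == 1) return(abs(x[1] - y[1]))
    best <- Inf
    if (i > 1) best <- min(best, rec(i - 1, j))
    if (j > 1) best <- min(best, rec(i, j - 1))
    if (i > 1 && j > 1) best <- min(best, rec(i - 1, j - 1))
    best + abs(x[i] - y[j])
  }
  rec(length(x), length(y))
}

test_that("pearson matches hand evaluations", {
  expect_equal(pearson_spi(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearson_spi(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(pearson_spi(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
})

test_that("DTW equals hand-built alignments and the brute-force oracle", {
  expect_equal(unname(dtw_features(c(0, 0, 1, 0), c(0, 0, 1, 0))["DTW"]), 0)
  # warping absorbs a one-sample shift
  expect_equal(unname(dtw_features(c(0, 0, 1, 0), c(0, 1, 0, 0))["DTW"]), 0)
  # full DP table by hand
  expect_equal(unname(dtw_features(c(0, 1), c(1, 0))["DTW"]), 2)

  set.seed(21)
  for (i in 1:200) {
    n <- sample(2:6, 1); m <- sample(2:6, 1)
    x <- round(rnorm(n), 2); y <- round(rnorm(m), 2)
    expect_equal(mtsrep:::dtw_distance_cpp(x, y), dtw_brute(x, y),
                 tolerance = 1e-12)
  }
})

test_that("the DTW barycenter interpolates the pair", {
  set.seed(22)
  x <- rnorm(60); y <- rnorm(60)
  b <- dtw_features(x, y)
  # identical inputs: barycenter is the series itself
  expect_equal(unname(dtw_features(x, x)["barycenter_DTW"]), max(x))
  # max of the barycenter is bounded by the pooled max
  expect_lte(b[["barycenter_DTW"]], max(c(x, y)) + 1e-12)
})

test_that("Gaussian transfer entropy matches its closed form and the Granger identity", {
  set.seed(23)
  T <- 2e5
  x <- rnorm(T)
  y <- c(0, 0.5 * x[-T]) + rnorm(T)
  # y_t = 0.5 x_{t-1} + eps: TE -> (1/2) ln(1.25)
  expect_equal(transfer_entropy_gaussian(x, y), 0.5 * log(1.25),
               tolerance = 0.01)
  # disconnected system
  expect_lt(abs(transfer_entropy_gaussian(rnorm(5000), rnorm(5000))), 0.002)

  # dual-route identity: TE = (1/2) * Granger ln-variance-ratio, where the
  # Granger side is computed independently via lm()
  for (i in 1:10) {
    n <- 200
    a <- as.numeric(arima.sim(list(ar = 0.5), n))
    b <- as.numeric(arima.sim(list(ar = -0.3), n)) + 0.3 * c(0, a[-n])
    r_res <- lm(b[-1] ~ b[-n])$residuals
    f_res <- lm(b[-1] ~ b[-n] + a[-n])$residuals
    granger <- log(mean(r_res^2) / mean(f_res^2))
    expect_equal(transfer_entropy_gaussian(a, b), granger / 2,
                 tolerance = 1e-10)
  }
})

test_that("phi-star is symmetric, non-negative, and vanishes for disconnected pairs", {
  set.seed(24)
  expect_lt(phi_star_gaussian(rnorm(2000), rnorm(2000)), 0.005)
  for (i in 1:5) {
    a <- as.numeric(arima.sim(list(ar = 0.5), 300))
    b <- 0.6 * a + rnorm(300)
    expect_gte(phi_star_gaussian(a, b), 0)
    expect_equal(phi_star_gaussian(a, b), phi_star_gaussian(b, a),
                 tolerance = 1e-12)
  }
})

test_that("spectral statistics behave at the coupling extremes", {
  set.seed(25)
  tt <- 0:511
  osc <- sin(2 * pi * tt / 20) + 0.1 * rnorm(512)
  # self-coupling: perfect coherence, but PLI is blind to zero lag
  s_self <- spectral_spis(osc, osc, 1)
  expect_equal(unname(s_self["coherence_magnitude"]), 1, tolerance = 1e-10)
  expect_equal(unname(s_self["PLI"]), 0)
  # quarter-cycle delay: constant +/- pi/2 phase difference
  osc2 <- sin(2 * pi * (tt - 5) / 20) + 0.1 * rnorm(512)
  expect_gt(unname(spectral_spis(osc, osc2, 1)["PLI"]), 0.9)
  # exact PSI antisymmetry
  x <- rnorm(256); y <- rnorm(256)
  sxy <- spectral_spis(x, y, 1); syx <- spectral_spis(y, x, 1)
  expect_equal(unname(sxy["PSI_frequency"]), -unname(syx["PSI_frequency"]),
               tolerance = 1e-12)
  expect_equal(unname(sxy["PSI_time_frequency"]),
               -unname(syx["PSI_time_frequency"]), tolerance = 1e-12)
  # undirected statistics are exchange-symmetric
  for (nm in c("coherence_magnitude", "PLI", "power_envelope_corr"))
    expect_equal(unname(sxy[nm]), unname(syx[nm]), tolerance = 1e-12)
})

test_that("coherence of independent noise shows the known positive bias", {
  # Monte-Carlo oracle, frozen: mean |coherency| of independent white
  # noise with these Welch settings (T = 512, Hann-64, 50% overlap)
  # computed from 200 independent replicates before freezing: 0.240
  # (SE 0.002), single draws within [0.18, 0.31].
  set.seed(26)
  vals <- replicate(10, {
    unname(spectral_spis(rnorm(512), rnorm(512), 1)["coherence_magnitude"])
  })
  expect_equal(mean(vals), 0.240, tolerance = 0.03)
  expect_true(all(vals > 0.15 & vals < 0.35))
})

test_that("spectral Granger causality satisfies the Geweke integral identity", {
  set.seed(27)
  T <- 3000
  x <- numeric(T); y <- numeric(T)
  for (t in 2:T) {
    x[t] <- 0.5 * x[t - 1] + rnorm(1)
    y[t] <- 0.4 * y[t - 1] + 0.4 * x[t - 1] + rnorm(1)
  }
  g <- spectral_granger(x, y, order = 1)
  # time-domain ln-variance-ratio at the same order, via lm()
  r_res <- lm(y[-1] ~ y[-T])$residuals
  f_res <- lm(y[-1] ~ y[-T] + x[-T])$residuals
  td <- log(mean(r_res^2) / mean(f_res^2))
  expect_equal(g$gc_mean, td, tolerance = 0.02)
  # no causation in the quiet direction or between independent series
  expect_lt(spectral_granger(y, x, order = 1)$gc_mean, 0.01)
  expect_lt(spectral_granger(rnorm(500), rnorm(500))$gc_mean, 0.02)
})

test_that("the cointegration statistic separates shared from independent trends", {
  set.seed(28)
  coupled <- numeric(20); indep <- numeric(20)
  for (i in 1:20) {
    w <- cumsum(rnorm(400))
    coupled[i] <- unname(causal_spis(zscore_series(w),
                                     zscore_series(w + rnorm(400)))["cointegration"])
    indep[i] <- unname(causal_spis(zscore_series(w),
                                   zscore_series(cumsum(rnorm(400))))["cointegration"])
  }
  # shared stochastic trend: strongly negative ADF statistic
  expect_lt(mean(coupled), -8)
  # independent random walks stay near the non-rejecting region
  expect_gt(mean(indep), -3)
})

test_that("pair indexing matches the counting conventions", {
  expect_equal(nrow(pair_index(3, directed = TRUE)), 6)
  expect_equal(nrow(pair_index(82, directed = TRUE)), 6642)
  expect_equal(nrow(pair_index(48, directed = TRUE)), 2256)
  expect_equal(nrow(pair_index(48, directed = FALSE)), 1128)
  expect_equal(nrow(pair_index(10, directed = TRUE)), 90)
  # row-major determinism
  p <- pair_index(3, directed = TRUE)
  expect_equal(p$i, c(1, 1, 2, 2, 3, 3))
  expect_equal(p$j, c(2, 3, 1, 3, 1, 2))
})

test_that("the SPI tensor holds consistent per-pair values", {
  ds <- tiny_dataset(N = 3, R = 3, T = 80)
  st <- compute_spi_tensor(ds, c("pearson", "transfer_entropy",
                                 "PSI_frequency"))
  expect_s3_class(st, "spi_tensor")
  expect_equal(ncol(st$pearson$values), 3)         # undirected: 3 pairs
  expect_equal(ncol(st$transfer_entropy$values), 6) # directed: 6 pairs
  # PSI antisymmetry survives tensor assembly
  pr <- st$PSI_frequency$pairs
  for (p in which(pr$i < pr$j)) {
    q <- which(pr$i == pr$j[p] & pr$j == pr$i[p])
    expect_equal(st$PSI_frequency$values[, p],
                 -st$PSI_frequency$values[, q], tolerance = 1e-12)
  }
  # pearson equals direct correlation of z-scored series
  z1 <- zscore_series(ds$data[1, 1, ]); z2 <- zscore_series(ds$data[1, 2, ])
  expect_equal(unname(st$pearson$values[1, 1]), cor(z1, z2))
})
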