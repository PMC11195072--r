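# Univariate feature bank: closed-form limits, hand computations and
# invariance properties.

test_that("z-scoring gives mean 0 / sample SD 1 and flags constants", {
  z <- zscore_series(c(1, 2, 3))
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)
  expect_equal(zscore_series(z), z, tolerance = 1e-12)
  expect_true(all(is.na(zscore_series(c(5, 5, 5)))))
})

test_that("autocorrelation timescales match known processes", {
  set.seed(11)
  # iid noise: ACF(1) ~ 0 < 1/e
  wn <- rnorm(5000)
  expect_equal(unname(compute_features(wn, 2)["ACF_timescale"]), 1)
  # AR(1) phi = 0.6: 0.6 > 1/e > 0.36
  ar <- as.numeric(arima.sim(list(ar = 0.6), 2e5))
  expect_equal(unname(compute_features(ar, 2)["ACF_timescale"]), 2)
  # sinusoid with period 20 samples peaks in ACF at its period
  s <- sin(2 * pi * (0:999) / 20) + rnorm(1000) * 1e-4
  expect_equal(unname(compute_features(s, 2)["periodicity"]), 20)
})

test_that("spectral features match band constructions", {
  tt <- 0:499
  # 0.05 Hz at TR = 2 s sits inside [0.01, 0.08] Hz
  s_in <- sin(2 * pi * 0.05 * tt * 2)
  expect_gt(unname(compute_features(s_in, 2)["fALFF"]), 0.95)
  # 0.2 Hz sits outside the band
  s_out <- sin(2 * pi * 0.2 * tt * 2)
  expect_lt(unname(compute_features(s_out, 2)["fALFF"]), 0.05)
  # flat spectrum: lowest 20% of frequencies hold ~20% of power
  set.seed(12)
  wn <- rnorm(10000)
  expect_lt(abs(unname(compute_features(wn, 2)["low_freq_power"]) - 0.2),
            0.03)
  # centroid of a pure tone is its frequency
  f <- compute_features(sin(2 * pi * 0.05 * tt * 2), 2)
  expect_equal(unname(f["centroid_freq"]), 0.05, tolerance = 0.005)
})

test_that("fluctuation exponents recover known scaling laws", {
  set.seed(13)
  wn <- rnorm(10000)
  f <- compute_features(wn, 2)
  expect_equal(unname(f["DFA"]), 0.5, tolerance = 0.05)
  expect_equal(unname(f["rs_range"]), 0.5, tolerance = 0.07)
  rw <- cumsum(rnorm(10000))
  expect_equal(unname(compute_features(rw, 2)["DFA"]), 1.5, tolerance = 0.1)
})

test_that("symbolic and information features match analytic values", {
  set.seed(14)
  # iid symbols: successive tercile pairs are uniform over 9 states
  wn <- rnorm(2e5)
  f <- compute_features(wn, 2)
  expect_equal(unname(f["entropy_pairs"]), log(9), tolerance = 0.01)
  # independence at lag 2 (plug-in bias is O(bins^2 / T))
  expect_lt(unname(f["AMI2"]), 0.005)
  # cyclic terciles: permutation transition matrix, column variance 3*(2/9)
  cyc <- rep(c(-1, 0, 1), 400) + rnorm(1200) * 1e-9
  expect_equal(unname(compute_features(cyc, 2)["transition_variance"]),
               2 / 3, tolerance = 1e-6)
})

test_that("distribution features follow their definitions", {
  raw <- rep(c(2, 4, 6), 4)
  f <- compute_features(raw, 2)
  expect_equal(unname(f["mean"]), mean(raw))
  expect_equal(unname(f["SD"]), sd(raw))

  # maxima confined to the last 10% of samples
  set.seed(15)
  z <- c(rnorm(180), rnorm(20) + 50)
  expect_gt(unname(compute_features(z, 2)["outlier_timing_pos"]), 0.9)
  # the same series reversed puts them at the start
  expect_lt(unname(compute_features(rev(z), 2)["outlier_timing_pos"]), 0.1)

  # z-scored ramp of length 100: |increments| = sqrt(12)/100 < 0.04
  ramp <- as.numeric(1:100)
  expect_equal(unname(compute_features(ramp, 2)["high_fluctuation"]), 0)
})

test_that("shape features count runs and asymmetries correctly", {
  # strictly decreasing ramp of length 12: 11 decreasing steps
  dec <- c(12:1, 5, 6, 7)
  expect_equal(unname(compute_features(dec, 2)["stretch_decreasing"]), 11)
  # alternating series never spends 2 samples above its mean
  alt <- rep(c(1, -1), 20)
  expect_equal(unname(compute_features(alt, 2)["stretch_high"]), 1)
  # a long sinusoid is time-reversible
  s <- sin(2 * pi * (0:9999) / 50)
  expect_lt(abs(unname(compute_features(s, 2)["trev"])), 0.01)
  # trev flips sign under time reversal
  set.seed(16)
  x <- as.numeric(arima.sim(list(ar = 0.5), 500))^3
  f_fwd <- unname(compute_features(x, 2)["trev"])
  f_rev <- unname(compute_features(rev(x), 2)["trev"])
  expect_equal(f_fwd, -f_rev, tolerance = 1e-10)
})

test_that("all features except mean/SD are affine-invariant; ACF features are reversal-invariant", {
  set.seed(17)
  affine_variant <- c("mean", "SD")
  for (rep_i in 1:5) {
    x <- as.numeric(arima.sim(list(ar = 0.4), 200))
    fx <- compute_features(x, 2)
    fy <- compute_features(3.2 * x + 7, 2)
    keep <- setdiff(feature_names(), affine_variant)
    expect_equal(fx[keep], fy[keep], tolerance = 1e-8)
    # ACF-derived features are invariant under time reversal
    fr <- compute_features(rev(x), 2)
    acf_feats <- c("ACF_timescale", "ACF_first_min", "periodicity",
                   "AMI_timescale")
    expect_equal(fx[acf_feats], fr[acf_feats])
  }
})

test_that("bounded features stay in range on random inputs", {
  set.seed(18)
  for (rep_i in 1:10) {
    x <- as.numeric(arima.sim(list(ar = runif(1, -0.5, 0.8)), 150))
    f <- compute_features(x, 2)
    expect_true(f["fALFF"] >= 0 && f["fALFF"] <= 1)
    expect_true(f["low_freq_power"] >= 0 && f["low_freq_power"] <= 1)
    expect_true(f["high_fluctuation"] >= 0 && f["high_fluctuation"] <= 1)
    expect_true(f["stretch_decreasing"] >= 1 && f["stretch_decreasing"] <= 149)
    expect_true(f["stretch_high"] >= 1 && f["stretch_high"] <= 149)
  }
})

test_that("the feature tensor has stable shape, order and missing handling", {
  ds <- tiny_dataset(N = 2, R = 3, T = 60)
  ft <- compute_feature_tensor(ds)
  expect_equal(dim(ft$values), c(2, 3, 25))
  expect_identical(dimnames(ft$values)[[3]], feature_names())
  # determinism
  ft2 <- compute_feature_tensor(ds)
  expect_identical(ft$values, ft2$values)
  # constant series yields missing sentinels, not zeros
  ds$data[1, 2, ] <- 4
  ft3 <- compute_feature_tensor(ds)
  expect_true(is.na(ft3$values[1, 2, "ACF_timescale"]))
  expect_equal(unname(ft3$values[1, 2, "mean"]), 4)
  expect_equal(unname(ft3$values[1, 2, "SD"]), 0)
  # tidy long export matches the tensor
  long <- feature_tensor_long(ft)
  expect_equal(nrow(long), 2 * 3 * 25)
  expect_equal(long$value[long$participant_id == "p01" &
                            long$region == "r2" &
                            long$feature == "mean"],
               unname(ft$values["p01", "r2", "mean"]))
})
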