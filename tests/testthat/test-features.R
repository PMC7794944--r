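test_that("the registry holds 102 uniquely named features in nine groups", {
  reg <- feature_registry()
  expect_length(reg, 102L)
  expect_length(unique(reg), 102L)
  expect_equal(as.vector(table(attr(reg, "group"))[c(
    "time", "spectral", "cepstral", "chroma", "semg", "moment", "hjorth",
    "fractal", "ltp")]),
    c(19L, 17L, 8L, 12L, 13L, 6L, 2L, 5L, 20L))
})

test_that("time-domain factors match closed forms on a unit sine", {
  x <- tone(1, fs = 1000, dur = 1) # one exact period
  v <- suppressWarnings(time_domain_features(x, 1000)) # too few peaks for jitter
  expect_equal(v[["Root Mean Square"]], 1 / sqrt(2), tolerance = 1e-9)
  expect_equal(v[["Crest Factor"]], sqrt(2), tolerance = 1e-9)
  expect_equal(v[["Peak to Peak Value"]], 2, tolerance = 1e-9)
  expect_equal(v[["Energy"]], 500, tolerance = 1e-9)
})

test_that("constant signals give unit factors and sentinel skewness", {
  expect_warning(v <- time_domain_features(rep(2, 100), 100), "sentinel")
  expect_equal(v[["Crest Factor"]], 1)
  expect_equal(v[["Shape Factor"]], 1)
  expect_equal(v[["Impulse Factor"]], 1)
  expect_equal(v[["Skewness"]], 0) # sentinel
})

test_that("average frequency counts zero crossings per interval", {
  suppressWarnings({
    v <- time_domain_features(c(1, -1, 1, -1), 10)
  })
  expect_equal(v[["Average Frequency"]], 1.0)
})

test_that("jitter is near zero for a metronomic pulse train", {
  x <- clean_pulse(fs = 250, dur = 10)
  v <- time_domain_features(x, 250)
  expect_lt(v[["Jitter"]], 5) # ms
})

test_that("spectral descriptors localise a pure tone", {
  x <- tone(50, fs = 1000, dur = 2)
  v <- spectral_features(x, 1000)
  expect_lt(abs(v[["Spectral Centroid"]] - 50), 0.5)
  expect_lt(abs(v[["Median Frequency"]] - 50), 0.5)
  expect_lte(v[["Total Harmonic Distortions"]], -60)
})

test_that("THD recovers a half-amplitude second harmonic", {
  x <- tone(50, fs = 1000, dur = 2) + tone(100, fs = 1000, dur = 2, amp = 0.5)
  v <- spectral_features(x, 1000)
  expect_lt(abs(v[["Total Harmonic Distortions"]] - (-6.02)), 0.5)
})

test_that("an all-zero signal has no spectrum", {
  expect_error(spectral_features(numeric(256), 1000), "undefined")
})

test_that("scaling shifts MFCC1 and leaves MFCC2-4 unchanged", {
  set.seed(5)
  x <- clean_pulse(dur = 3) + 0.05 * rnorm(3000)
  a <- cepstral_features(x, 1000)
  b <- cepstral_features(3 * x, 1000)
  expect_gt(abs(b[[1]] - a[[1]]), 1e-3) # log-energy offset moved c0
  expect_equal(a[2:4], b[2:4], tolerance = 1e-6)
})

test_that("cepstral extraction is deterministic", {
  set.seed(8)
  x <- rnorm(4096)
  expect_identical(cepstral_features(x, 1000), cepstral_features(x, 1000))
})

test_that("chroma puts a 440 Hz tone in class A and rotates on transposition", {
  a4 <- chroma_features(tone(440, fs = 4000, dur = 2), 4000)
  expect_identical(unname(which.max(a4)), 1L)
  up <- chroma_features(tone(440 * 2^(1 / 12), fs = 4000, dur = 2), 4000)
  expect_identical(unname(which.max(up)), 2L)
  expect_true(all(chroma_features(numeric(2048), 1000) == 0))
})

test_that("sEMG counting features match hand computations", {
  v <- semg_features(c(0, 1, 0, 1, 0))
  expect_equal(v[["Wavelength"]], 4)
  expect_equal(v[["Average Amplitude Change"]], 1)
  expect_equal(semg_features(seq(0, 1, length.out = 20))[["Slope Sign Change"]], 0)
  expect_equal(semg_features(c(0, 0.1, 0.3), thresh = 0.15)[["Willison Amplitude"]], 1)
})

test_that("moment descriptors match brute-force difference sums", {
  x <- c(0, 1, 0, -1, 0, 1)
  m0 <- sqrt(sum(x^2))
  m2 <- sqrt(sum(diff(x)^2))
  m4 <- sqrt(sum(diff(x, differences = 2)^2))
  v <- moment_features(x)
  expect_equal(v[["Root Squared Zero Order Moment"]], log(m0))
  expect_equal(v[["Root Squared 2nd Order Moment"]], log(m2))
  expect_equal(v[["Root Squared 4th Order Moment"]], log(m4))
  expect_equal(v[["Sparseness"]], log(m0 / sqrt((m0 - m2) * (m0 - m4))))
  expect_equal(v[["Irregularity Factor"]], log(m2 / sqrt(m0 * m4)))
  expect_equal(v[["Waveform Length Ratio"]], log(sum(abs(diff(x))) /
                                                  sum(abs(diff(x, differences = 2)))))
})

test_that("log-scaled moments are shift-equivariant under doubling", {
  set.seed(2)
  x <- rnorm(50)
  a <- suppressWarnings(moment_features(x))
  b <- suppressWarnings(moment_features(2 * x))
  expect_equal(b[["Root Squared Zero Order Moment"]] -
                 a[["Root Squared Zero Order Moment"]], log(2),
               tolerance = 1e-10)
})

test_that("a pure ramp trips the waveform-length-ratio guard", {
  expect_warning(v <- moment_features(seq_len(10)), "sentinel")
  expect_equal(v[["Waveform Length Ratio"]], 0)
})

test_that("Hjorth mobility approaches omega*dt for a fine-sampled sine", {
  x <- tone(2, fs = 1000, dur = 5)
  v <- hjorth_features(x)
  expect_lt(abs(v[["Mobility"]] - 2 * pi * 2 / 1000) / (2 * pi * 2 / 1000),
            0.02)
  set.seed(4)
  noise <- hjorth_features(rnorm(5000))
  expect_gt(noise[["Complexity"]], v[["Complexity"]])
  expect_error(hjorth_features(rep(1, 100)), "undefined")
})

test_that("fractal dimensions behave at the known extremes", {
  expect_lt(abs(higuchi_fd(seq(0, 1, length.out = 1000)) - 1), 0.05)
  set.seed(6)
  expect_gte(higuchi_fd(rnorm(1e4)), 1.8)
  expect_lte(approx_entropy(rep(c(0, 1, 0, -1), 75)), 0.05)
})

test_that("scale-invariant features ignore amplitude; equivariant ones track it", {
  cfg <- pupg_config(n_per_class = 1, seed = 17)
  x <- pupg_signal(cfg, "normal", 1)$samples
  a <- time_domain_features(x, 1000)
  b <- time_domain_features(2.5 * x, 1000)
  for (f in c("Crest Factor", "Shape Factor", "Impulse Factor"))
    expect_equal(a[[f]], b[[f]], tolerance = 1e-10)
  expect_equal(b[["Root Mean Square"]], 2.5 * a[["Root Mean Square"]],
               tolerance = 1e-10)
  expect_equal(higuchi_fd(2.5 * x), higuchi_fd(x), tolerance = 1e-9)
})

test_that("LTP histograms count every window once", {
  set.seed(9)
  for (x in list(rnorm(200), clean_pulse(fs = 100, dur = 3))) {
    v <- ltp_features(x, t = 0.01)
    expect_equal(sum(v[1:10]), length(x) - 8)
    expect_equal(sum(v[11:20]), length(x) - 8)
  }
  const <- ltp_features(rep(1, 60))
  expect_equal(unname(const[1]), 52)
  expect_true(all(const[c(2:10, 12:20)] == 0))
})

test_that("LTP matches an exhaustive per-sample pattern enumeration", {
  set.seed(10)
  x <- round(rnorm(12), 2)
  t <- 0.05
  hist_u <- integer(10); hist_l <- integer(10)
  for (i in 5:8) {
    nb <- x[i + c(-4:-1, 1:4)]
    for (side in c("u", "l")) {
      bits <- if (side == "u") nb > x[i] + t else nb < x[i] - t
      trans <- sum(bits != bits[c(2:8, 1)])
      bin <- if (trans <= 2) sum(bits) + 1L else 10L
      if (side == "u") hist_u[bin] <- hist_u[bin] + 1L
      else hist_l[bin] <- hist_l[bin] + 1L
    }
  }
  expect_equal(unname(ltp_features(x, t)), c(hist_u, hist_l))
})

test_that("extract_features returns 102 finite values in registry order", {
  cfg <- pupg_config(n_per_class = 1, seed = 25)
  s <- pupg_signal(cfg, "hypertension", 1)
  v <- extract_features(s)
  expect_length(v, 102L)
  expect_identical(names(v), as.character(feature_registry()))
  expect_true(all(is.finite(v)))
  expect_identical(v, extract_features(s))
})

test_that("degenerate-but-valid inputs still yield finite vectors", {
  set.seed(11)
  degenerates <- list(
    c(rep(0, 2000), 1, rep(0, 2000)),           # single spike
    rep(c(0, 1), 1500),                          # square alternation
    seq(0, 1, length.out = 2048) + 1e-6 * rnorm(2048), # near-ramp
    rep(1, 3000) + 1e-9 * rnorm(3000)            # near-constant
  )
  for (x in degenerates) {
    v <- suppressWarnings(extract_features(x, fs = 1000))
    expect_true(all(is.finite(v)))
  }
})
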