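test_that("zero-mean normalization standardizes with population sigma", {
  rec <- eeg_recording(matrix(c(1, 2, 3), 1), fs = 10)
  z <- zero_mean_normalize(rec)
  # mu = 2, population sigma = sqrt(2/3)
  expect_equal(z$data[1, ], c(-1.5, 0, 1.5) / sqrt(1.5), tolerance = 1e-12)
  expect_equal(z$data[1, 1], -1.2247, tolerance = 1e-4)

  set.seed(1)
  rec2 <- eeg_recording(matrix(rnorm(3 * 500, mean = 5, sd = 3), 3), fs = 10)
  z2 <- zero_mean_normalize(rec2)
  expect_lt(max(abs(rowMeans(z2$data))), 1e-10)
  expect_lt(max(abs(sqrt(rowMeans(z2$data^2)) - 1)), 1e-10)
  # idempotence
  expect_equal(zero_mean_normalize(z2)$data, z2$data, tolerance = 1e-10)

  const <- eeg_recording(matrix(c(5, 5, 5, 1, 2, 3), 2, byrow = TRUE), fs = 1)
  expect_error(zero_mean_normalize(const), "channel\\(s\\) 1")
})

test_that("band-pass keeps 10 Hz, rejects 60 Hz and DC at fs=160", {
  n <- 1600; t <- seq_len(n) / 160
  trim <- 201:1400   # drop filter edge transients before measuring
  rms <- function(x) sqrt(mean(x^2))

  in_band <- eeg_recording(matrix(sin(2 * pi * 10 * t), 1), fs = 160)
  out <- bandpass(in_band)
  expect_equal(rms(out$data[1, trim]), rms(in_band$data[1, trim]),
               tolerance = 0.05)

  stop_band <- eeg_recording(matrix(sin(2 * pi * 60 * t), 1), fs = 160)
  expect_lt(rms(bandpass(stop_band)$data[1, trim]),
            0.1 * rms(stop_band$data[1, trim]))   # >= 20 dB down

  dc <- eeg_recording(matrix(rep(1, n), 1), fs = 160)
  expect_lt(rms(bandpass(dc)$data[1, trim]), 0.05)

  expect_error(bandpass(dc, high = 80), "Nyquist")
})

test_that("Yule-Walker recovers AR coefficients and matches a direct solve", {
  set.seed(10)
  x <- as.numeric(stats::arima.sim(list(ar = c(0.5, -0.3)), 10000))
  fit <- ar_coefficients(x, p = 2)
  expect_equal(fit$coef, c(0.5, -0.3), tolerance = 0.05)
  expect_equal(fit$order, 2L)

  # independent oracle: solve the Yule-Walker normal equations directly
  # from the biased sample autocovariances
  xc <- x - mean(x)
  acov <- vapply(0:2, function(k)
    sum(xc[1:(10000 - k)] * xc[(1 + k):10000]) / 10000, 0)
  a_direct <- solve(stats::toeplitz(acov[1:2]), acov[2:3])
  expect_equal(fit$coef, a_direct, tolerance = 1e-8)

  wn <- rnorm(5000)
  expect_lt(max(abs(ar_coefficients(wn, p = 2)$coef)), 0.05)

  p0 <- ar_coefficients(wn + 3, p = 0)
  expect_length(p0$coef, 0L)
  expect_equal(p0$intercept, mean(wn + 3))

  expect_error(ar_coefficients(c(1, NA, 3), p = 1), "non-finite|short")
  expect_error(ar_coefficients(rnorm(50), p = 6), "short")
})

test_that("AR estimation error shrinks with series length", {
  errs <- vapply(c(500, 5000, 50000), function(n) {
    set.seed(n)
    med <- stats::median(abs(vapply(1:5, function(i) {
      x <- as.numeric(stats::arima.sim(list(ar = c(0.5, -0.3)), n))
      max(abs(ar_coefficients(x, 2)$coef - c(0.5, -0.3)))
    }, 0)))
    med
  }, 0)
  expect_true(errs[1] > errs[2] && errs[2] > errs[3])
})

test_that("Welch PSD integrates to the variance and localizes tones", {
  set.seed(2)
  x <- rnorm(16384)
  psd <- welch_psd(x, fs = 160, nperseg = 256)
  expect_equal(sum(psd$power) * psd$resolution, 1.0, tolerance = 0.1)
  expect_true(all(psd$power >= 0))
  expect_equal(psd$freq[1], 0)
  expect_equal(psd$freq[length(psd$freq)], 80)

  tone <- sin(2 * pi * 10 * seq_len(4800) / 160)
  pt <- welch_psd(tone, fs = 160, nperseg = 256)
  expect_lte(abs(pt$freq[which.max(pt$power)] - 10), pt$resolution)

  z <- welch_psd(rep(0, 1000), fs = 160, nperseg = 256)
  expect_true(all(z$power == 0))
  expect_error(welch_psd(rnorm(100), fs = 160, nperseg = 256), "window error")
})

test_that("Welch PSD agrees with an independent implementation", {
  # plain averaged-periodogram oracle written against the definition,
  # restricted to non-overlapping segments to stay independent
  set.seed(3)
  x <- rnorm(2048)
  fs <- 100; nper <- 256
  ours <- welch_psd(x, fs, nperseg = nper, overlap = 0)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nper - 1)) / nper)
  segs <- split(x, rep(1:8, each = nper))
  pxx <- rowMeans(vapply(segs, function(s) {
    s <- s - mean(s)
    sp <- abs(fft(s * w))^2 / (fs * sum(w^2))
    sp <- sp[1:(nper / 2 + 1)]
    sp[2:(nper / 2)] <- 2 * sp[2:(nper / 2)]
    sp
  }, numeric(nper / 2 + 1)))
  expect_equal(ours$power, unname(pxx), tolerance = 1e-10)
})

test_that("feature extraction lays out K x (p + bands) deterministic blocks", {
  set.seed(4)
  segs <- lapply(1:3, function(i) matrix(rnorm(4 * 400), 4))
  segs[[3]] <- segs[[1]]
  batch <- eeglink:::new_segment_batch(
    segs, data.frame(subject = c(1L, 2L, 1L), task = 1L, class = 1L),
    data.frame(recording = 1L, offset = 0L))
  fe <- extract_features(batch, fs = 160, p = 6, nperseg = 128)
  expect_equal(ncol(fe$x), 4 * (6 + 5))
  expect_identical(fe$x[3, ], fe$x[1, ])

  # doubling the alpha content of channel 1 raises its alpha-band feature
  tone <- 2 * sin(2 * pi * 10 * seq_len(400) / 160)
  seg_hi <- segs[[1]]; seg_hi[1, ] <- seg_hi[1, ] + tone
  b2 <- eeglink:::new_segment_batch(
    list(segs[[1]], seg_hi),
    data.frame(subject = c(1L, 1L), task = 1:2, class = 1L),
    data.frame(recording = 1L, offset = 0L))
  f2 <- extract_features(b2, fs = 160, p = 6, nperseg = 128)
  alpha_col <- 6 + 3   # channel 1 block: 6 AR coefs then delta, theta, alpha
  expect_gt(f2$x[2, alpha_col], f2$x[1, alpha_col])
})

test_that("PSD features are invariant to constant offsets after the pipeline", {
  set.seed(5)
  x <- rnorm(800)
  rec <- eeg_recording(matrix(x, 1), fs = 160)
  rec_off <- eeg_recording(matrix(x + 7, 1), fs = 160)
  pipe <- function(r) bandpass(zero_mean_normalize(r))
  p1 <- welch_psd(pipe(rec)$data[1, ], 160)
  p2 <- welch_psd(pipe(rec_off)$data[1, ], 160)
  expect_equal(p1$power, p2$power, tolerance = 1e-8)
})
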