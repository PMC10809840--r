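test_that("out-of-range correction interpolates only offending samples", {
  x <- seq(-50, 50, length.out = 101)        # linear ramp, in range
  rec <- tone_recording(x, 256, "C4")
  expect_equal(correct_out_of_range(rec, 200)$samples, rec$samples)

  # a spike on a line: monotone cubic interpolation restores the line
  xs <- x; xs[40] <- 500
  fixed <- correct_out_of_range(tone_recording(xs, 256, "C4"), 200)
  expect_equal(unname(fixed$samples[1, 40]), x[40], tolerance = 1e-9)
  expect_equal(unname(fixed$samples[1, -40]), x[-40])

  # leading run out of range: nearest-valid fill
  xl <- x; xl[1:3] <- -400
  fixed2 <- correct_out_of_range(tone_recording(xl, 256, "C4"), 200)
  expect_equal(unname(fixed2$samples[1, 1:3]), rep(x[4], 3))

  # > 50% bad: flagged unusable with a warning
  xb <- rep(300, 101); xb[1:10] <- 0
  expect_warning(out <- correct_out_of_range(tone_recording(xb, 256, "C4"),
                                             200), "unusable")
  expect_identical(attr(out, "unusable_channels"), "C4")
  expect_true(all(is.finite(out$samples)))
})

test_that("notch filter removes the mains tone and passes 10 Hz", {
  fs <- 256
  x50 <- make_tone(50, fs, 10)
  y50 <- notch_filter(tone_recording(x50, fs), 50, 25)$samples[1, ]
  expect_lt(rms_trimmed(y50, fs), 0.05 * rms_trimmed(x50, fs))

  x10 <- make_tone(10, fs, 10)
  y10 <- notch_filter(tone_recording(x10, fs), 50, 25)$samples[1, ]
  expect_equal(rms_trimmed(y10, fs), rms_trimmed(x10, fs), tolerance = 0.05)

  z <- notch_filter(tone_recording(rep(0, fs * 2), fs), 50, 25)
  expect_equal(max(abs(z$samples)), 0)

  # single-pass design contract: deep null at 50 Hz, >= 0.95 at 10 Hz
  co <- neowave:::notch_coefficients(50, fs, 25)
  expect_lt(freq_response(co$b, co$a, 50, fs), 0.01)
  expect_gt(freq_response(co$b, co$a, 10, fs), 0.95)
})

test_that("high-pass filter is 6th-order Butterworth with DC rejection", {
  fs <- 256
  # DC: constant offset driven to ~0 mean
  xdc <- make_tone(10, fs, 10) + 10
  ydc <- highpass_filter(tone_recording(xdc, fs), 1, 6)$samples[1, ]
  expect_lt(abs(mean(ydc[(fs + 1):(length(ydc) - fs)])), 0.01)

  # deep stopband: 0.1 Hz attenuated below 1% RMS (6th-order rolloff)
  xslow <- make_tone(0.1, fs, 40)
  yslow <- highpass_filter(tone_recording(xslow, fs), 1, 6)$samples[1, ]
  expect_lt(rms_trimmed(yslow, fs, 10), 0.01 * rms_trimmed(xslow, fs, 10))

  # passband: 10 Hz within 2%
  x10 <- make_tone(10, fs, 10)
  y10 <- highpass_filter(tone_recording(x10, fs), 1, 6)$samples[1, ]
  expect_equal(rms_trimmed(y10, fs), rms_trimmed(x10, fs), tolerance = 0.02)

  # single-pass magnitude at the cutoff is 1/sqrt(2) by construction
  bf <- signal::butter(6, 1 / (fs / 2), type = "high")
  expect_equal(freq_response(bf$b, bf$a, 1, fs), 1 / sqrt(2),
               tolerance = 0.01)
})

test_that("zero-phase filtering leaves no lag and is linear", {
  fs <- 256
  x <- make_tone(5, fs, 4)
  y <- highpass_filter(tone_recording(x, fs), 1, 6)$samples[1, ]
  cc <- ccf(x, y, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  a <- rnorm(fs * 2); b <- rnorm(fs * 2)
  f <- function(v) notch_filter(tone_recording(v, fs), 50, 25)$samples[1, ]
  expect_equal(f(2 * a + 3 * b), 2 * f(a) + 3 * f(b), tolerance = 1e-8)
})

test_that("z-scoring uses the population convention and flags constants", {
  rec <- tone_recording(c(1, 2, 3), 256, "C4")
  z <- zscore_channels(rec)
  expect_equal(unname(z$samples[1, ]),
               c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-9)
  # idempotence
  expect_equal(zscore_channels(z)$samples, z$samples, tolerance = 1e-9)
  # constant channel
  zc <- zscore_channels(tone_recording(rep(5, 10), 256, "C4"))
  expect_true(all(zc$samples == 0))
  expect_identical(attr(zc, "constant_channels"), "C4")
})

test_that("PCA denoising retains the requested variance fraction", {
  set.seed(13)
  rec <- recording(matrix(rnorm(18 * 512), 18), 256,
                   paste0("ch", 1:18))
  rec <- zscore_channels(rec)
  full <- pca_denoise(rec, 1.0)
  expect_equal(full$samples, rec$samples, tolerance = 1e-9)

  part <- pca_denoise(rec, 0.95)
  info <- attr(part, "pca")
  expect_gte(info$retained_variance, 0.95)
  expect_lt(info$retained_components, 18)
  # reconstruction captures at least the retained eigenvalue fraction
  num <- sum(apply(part$samples, 1, var))
  den <- sum(apply(rec$samples, 1, var))
  expect_gte(num / den, 0.95 - 1e-9)

  # rank-1 case: two identical channels, one component reproduces both
  x <- rnorm(256)
  r2 <- zscore_channels(recording(rbind(x, x), 256, c("a", "b")))
  expect_warning(d2 <- pca_denoise(r2, 0.95), "rank-deficient")
  expect_equal(d2$samples, r2$samples, tolerance = 1e-9)
  expect_equal(attr(d2, "pca")$retained_components, 1)
})

test_that("preprocess applies the fixed chain and records provenance", {
  out <- generate_recording(synth_config(n_channels = 3, duration = 20,
    seizure_intervals = list(c(5, 15)),
    channel_labels = c("C4-P4", "Cz-Pz", "C3-P3"), seed = 9))
  pp <- preprocess(out$recording)
  expect_equal(dim(pp$samples), dim(out$recording$samples))
  prov <- attr(pp, "provenance")
  expect_true(is.list(prov$pca))
  expect_gte(prov$pca$retained_variance, 0.95)
  # z-scored before PCA: channel means ~ 0
  expect_lt(max(abs(rowMeans(pp$samples))), 0.05)
})
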