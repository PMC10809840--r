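test_that("complex envelope recovers amplitude and tracks AM modulators", {
  fs <- 256
  expect_equal(complex_envelope(make_tone(3, fs, 1, amplitude = 2)), 2,
               tolerance = 0.02)
  expect_identical(complex_envelope(rep(0, fs)), 0)

  # AM signal: per-epoch envelope medians track the modulator's medians
  t <- (0:(4 * fs - 1)) / fs
  modl <- 1 + 0.5 * cos(2 * pi * 0.5 * t)
  x <- modl * cos(2 * pi * 10 * t)
  for (e in 1:4) {
    idx <- ((e - 1) * fs + 1):(e * fs)
    expect_equal(complex_envelope(x[idx]), median(modl[idx]),
                 tolerance = 0.05)
  }
})

test_that("extrema detection is adaptive and scale-free", {
  fs <- 256
  x <- make_tone(3, fs, 1)
  pk <- detect_extrema(x)
  maxima <- pk[x[pk] > 0]
  # analytic maxima of cos(2*pi*3*t) at t = 0, 1/3, 2/3 -> samples 1, 86.3,
  # 171.7; the first lies inside the discarded edge half-window
  expect_true(all(abs(maxima - c(86.3, 171.7)) <= 2))

  # scale invariance
  expect_identical(detect_extrema(10 * x), pk)

  # monotone ramp: no interior extrema
  expect_length(detect_extrema(seq(0, 1, length.out = 300)), 0)

  expect_error(detect_extrema(rnorm(10)), "longer than")
})

test_that("sharpness implements the 7-ms flank median in z-units", {
  # constructed peak: height 10, flanks 6 and 4 exactly 7 ms away
  fs <- 1000
  x <- tent_signal(1000, 500, 7, 10, 6, 4)
  x[c(493, 500, 507)] <- c(6, 10, 4)   # pin the flank samples exactly
  p <- sharpness_params(window_len = 250)
  expect_identical(sharpness(x, fs, p), 5)

  # offset invariance (exact) and linear amplitude scaling
  expect_identical(sharpness(x + 100, fs, p), 5)
  expect_identical(sharpness(3 * x, fs, p), 15)

  # a phase-warped (peaked) wave is strictly sharper than the sinusoid
  fs2 <- 256
  s0 <- sharpness(make_tone(4, fs2, 4), fs2)
  s1 <- sharpness(neowave:::phase_warp_shape(make_tone(4, fs2, 4), 0.6), fs2)
  expect_gt(s1, s0)

  # no usable extrema -> flagged missing value
  out <- sharpness(seq(0, 1, length.out = 300), fs2)
  expect_true(is.na(out))
  expect_identical(attr(out, "flag"), "no_extrema")
})

test_that("degree of nonlinearity recovers intrawave modulation depth", {
  fs <- 256
  # pure sinusoid: DoN ~ 0
  expect_lt(degree_of_nonlinearity(make_tone(5, fs, 4), fs), 0.02)

  # eps recovery within 15% of eps/sqrt(2)
  t <- (0:(4 * fs - 1)) / fs
  for (eps in c(0.1, 0.2, 0.3, 0.4)) {
    x <- cos(2 * pi * 3 * t + eps * sin(2 * pi * 3 * t))
    expect_equal(degree_of_nonlinearity(x, fs), eps / sqrt(2),
                 tolerance = 0.15)
  }

  # approximately linear in eps
  d2 <- degree_of_nonlinearity(cos(2 * pi * 3 * t +
                                     0.2 * sin(2 * pi * 3 * t)), fs)
  d4 <- degree_of_nonlinearity(cos(2 * pi * 3 * t +
                                     0.4 * sin(2 * pi * 3 * t)), fs)
  expect_equal(d4 / d2, 2, tolerance = 0.1)

  # amplitude invariance
  x <- cos(2 * pi * 3 * t + 0.3 * sin(2 * pi * 3 * t))
  expect_equal(degree_of_nonlinearity(5 * x, fs),
               degree_of_nonlinearity(x, fs), tolerance = 1e-9)
  expect_equal(degree_of_nonlinearity(-2 * x, fs),
               degree_of_nonlinearity(x, fs), tolerance = 1e-9)

  # no zero crossings -> flagged missing
  out <- degree_of_nonlinearity(rep(1, fs), fs)
  expect_true(is.na(out))
  expect_identical(attr(out, "flag"), "no_crossings")
})

test_that("band powers concentrate in the generating band", {
  fs <- 256
  bp2 <- band_powers(make_tone(2, fs, 1), fs)
  expect_gt(bp2[["delta"]] / sum(bp2), 0.9)
  bp20 <- band_powers(make_tone(20, fs, 1), fs)
  expect_gt(bp20[["beta"]] / sum(bp20), 0.9)
  expect_true(all(band_powers(rep(0, fs), fs) == 0))
})

test_that("energy ratio and RMS follow their closed forms", {
  bp <- c(delta = 5, theta = 1, alpha = 1, beta = 3, gamma = 1)
  expect_equal(energy_ratio(bp), 2)
  er_flag <- energy_ratio(c(delta = 1, theta = 0, alpha = 0, beta = 1,
                            gamma = 0))
  expect_true(is.na(er_flag))

  fs <- 256
  expect_gt(energy_ratio(band_powers(make_tone(20, fs, 1), fs)), 10)
  expect_lt(energy_ratio(band_powers(make_tone(5, fs, 1), fs)), 0.1)

  expect_equal(rms_amplitude(make_tone(4, fs, 1)), 1 / sqrt(2),
               tolerance = 1e-6)
  expect_equal(rms_amplitude(rep(-3, 10)), 3)
  a <- rnorm(100); b <- rnorm(100)
  expect_equal(rms_amplitude(c(a, b))^2,
               mean(c(rms_amplitude(a)^2, rms_amplitude(b)^2)))
})

test_that("feature invariances hold: offsets, scaling, amplitude", {
  fs <- 256
  x <- make_tone(4, fs, 2) + 0.1 * rnorm(2 * fs)
  # envelope and RMS scale linearly with amplitude
  expect_equal(complex_envelope(3 * x[1:fs]), 3 * complex_envelope(x[1:fs]),
               tolerance = 1e-9)
  expect_equal(rms_amplitude(3 * x), 3 * rms_amplitude(x), tolerance = 1e-9)
  # sharpness offset-invariant on a realistic waveform
  expect_equal(sharpness(x + 50, fs), sharpness(x, fs), tolerance = 1e-9)
})

test_that("the feature table is labelled per fusion level", {
  out <- generate_recording(synth_config(n_channels = 2, duration = 30,
    seizure_intervals = list(c(10, 22)),
    rater_noise = list(jitter_sd = 0, miss_prob = 0),
    channel_labels = c("C4-P4", "Cz-Pz"), seed = 17))
  tab <- feature_table(preprocess(out$recording), out$annotations, "s1")
  expect_setequal(unique(tab$feature), c("envelope", "sharpness", "don"))
  expect_setequal(unique(tab$fusion), 1:3)
  # one row per (channel, epoch, feature, fusion)
  expect_equal(nrow(tab), 2 * 30 * 3 * 3)
  # with noiseless raters, labels agree across fusion levels
  t1 <- tab[tab$fusion == 1, ]; t3 <- tab[tab$fusion == 3, ]
  expect_identical(t1$label, t3$label)
  # seizure seconds 10..21 -> epochs 11..22 labelled seizure
  lab <- t3$label[t3$channel == "C4-P4" & t3$feature == "envelope"]
  expect_true(all(lab[11:22] != "nonseizure"))
  expect_true(all(lab[-(11:22)] == "nonseizure"))
})
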