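#' Configuration for the synthetic neonatal-EEG generator
#'
#' Builds the parameter set for [generate_recording()]. The generator
#' emulates the structure the analysis pipeline assumes: multichannel
#' recordings at 256 Hz with per-second ternary-rater seizure annotations,
#' seizure bursts carrying an elevated delta-band envelope, sharpened
#' extrema, and intrawave frequency modulation that deepens toward seizure
#' termination.
#'
#' The background is a slowly drifting near-sinusoidal delta rhythm
#' (independently per channel) with a small admixture of band-limited
#' 1/f^alpha Gaussian noise. A rhythm-dominated background is required for
#' the degree-of-nonlinearity contrast: the instantaneous frequency of pure
#' Gaussian noise is heavy-tailed, which would place the background's
#' nonlinearity above any seizure value regardless of spectral shaping (see
#' the methods vignette).
#'
#' Inside a seizure interval the background is attenuated to
#' `bg_suppression` of its amplitude and a delta oscillation at
#' `seizure_freq` is added. Across the three equal thirds of each event the
#' oscillation amplitude follows `envelope_gain_profile` (a gain of g
#' makes the seizure envelope about g times the background envelope) and
#' the intrawave modulation depth follows
#' `nonlinearity_eps`, i.e. the instantaneous phase is
#' `2*pi*f*t + eps*sin(2*pi*f*t)`. Waveform peakedness is controlled by
#' `sharpness_shape` s in \[0, 1\] via the half-wave power transform
#' `sign(u)*|u|^(1+2s)` (s = 0 leaves a sinusoid; larger s sharpens the
#' extrema while leaving zero crossings and extremum timing unchanged).
#'
#' @param n_channels number of channels (default 18, the longitudinal
#'   bipolar pairs returned by [default_montage()]).
#' @param fs sampling rate in Hz.
#' @param duration recording length in whole seconds.
#' @param seizure_intervals list of `c(start_s, end_s)` event intervals,
#'   disjoint, each at least 3 s, within `[0, duration]`.
#' @param envelope_gain_profile length-3 positive vector `(g1, g2, g3)`:
#'   per-stage seizure envelope relative to the background envelope.
#' @param sharpness_shape waveform peakedness in \[0, 1\].
#' @param nonlinearity_eps length-3 vector of per-stage modulation depths
#'   in \[0, 1).
#' @param rater_noise list with `jitter_sd` (s, boundary jitter of each
#'   rater's event limits) and `miss_prob` (per-event, per-rater miss
#'   probability).
#' @param background list: `alpha` (1/f exponent of the noise admixture),
#'   `f0` (mean rhythm frequency, Hz), `fdrift` (relative frequency-drift
#'   depth), `adrift` (relative amplitude-drift depth), `noise_mix`
#'   (RMS of the noise admixture relative to the rhythm).
#' @param seizure_freq fundamental of the seizure oscillation (Hz).
#' @param bg_suppression residual background amplitude inside seizures.
#' @param spatial_profile per-channel seizure amplitude weights (recycled);
#'   default uniform.
#' @param subject_gain_sd standard deviation of the log-normal
#'   per-recording seizure-amplitude factor (one draw per recording,
#'   common to all stages and channels). Models inter-individual
#'   variability in seizure amplitude; 0 disables it.
#' @param amplitude_uV overall scale: background RMS in microvolts.
#' @param channel_labels channel names; defaults to the first `n_channels`
#'   bipolar pair labels.
#' @param n_raters number of annotators (3, as in triple-reviewed datasets).
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return A validated list of class `nw_synth_config`.
#' @seealso [generate_recording()], [generate_pure_tone()]
#' @export
synth_config <- function(n_channels = 18,
                         fs = 256,
                         duration = 120,
                         seizure_intervals = list(c(30, 60), c(80, 104)),
                         envelope_gain_profile = c(2, 3, 1.6),
                         sharpness_shape = 0.3,
                         nonlinearity_eps = c(0.1, 0.25, 0.6),
                         rater_noise = list(jitter_sd = 1, miss_prob = 0.05),
                         background = list(alpha = 1, f0 = 3, fdrift = 0.15,
                                           adrift = 0.3, noise_mix = 0.02),
                         seizure_freq = 2.5,
                         bg_suppression = 0.2,
                         spatial_profile = 1,
                         subject_gain_sd = 0.2,
                         amplitude_uV = 30,
                         channel_labels = NULL,
                         n_raters = 3,
                         seed = 1) {
  if (is.null(channel_labels)) {
    pairs <- default_montage()
    if (n_channels > nrow(pairs))
      stop("n_channels exceeds the 18 default bipolar labels; ",
           "supply `channel_labels`")
    channel_labels <- paste0(pairs$anode, "-", pairs$cathode)[seq_len(n_channels)]
  }
  cfg <- structure(
    list(n_channels = n_channels, fs = fs, duration = duration,
         seizure_intervals = seizure_intervals,
         envelope_gain_profile = envelope_gain_profile,
         sharpness_shape = sharpness_shape,
         nonlinearity_eps = nonlinearity_eps,
         rater_noise = rater_noise, background = background,
         seizure_freq = seizure_freq, bg_suppression = bg_suppression,
         spatial_profile = spatial_profile,
         subject_gain_sd = subject_gain_sd, amplitude_uV = amplitude_uV,
         channel_labels = channel_labels, n_raters = n_raters, seed = seed),
    class = "nw_synth_config")
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  with(cfg, {
    if (duration <= 0 || duration != round(duration))
      stop("`duration` must be a positive whole number of seconds")
    if (length(channel_labels) != n_channels)
      stop("`channel_labels` length must equal `n_channels`")
    if (sharpness_shape < 0 || sharpness_shape > 1)
      stop("`sharpness_shape` must lie in [0, 1]")
    if (any(nonlinearity_eps < 0) || any(nonlinearity_eps >= 1))
      stop("`nonlinearity_eps` must lie in [0, 1)")
    if (any(envelope_gain_profile <= 0))
      stop("`envelope_gain_profile` must be positive")
    if (subject_gain_sd < 0)
      stop("`subject_gain_sd` must be nonnegative")
    if (length(seizure_intervals)) {
      iv <- do.call(rbind, seizure_intervals)
      if (any(iv[, 2] - iv[, 1] < 3))
        stop("each seizure interval must last at least 3 s")
      if (any(iv < 0) || any(iv > duration))
        stop("seizure intervals must lie within [0, duration]; ",
             "duration shorter than an interval")
      o <- order(iv[, 1])
      if (any(iv[o, 1][-1] < iv[o, 2][-nrow(iv)]))
        stop("seizure intervals must be disjoint")
    }
    # noise admixture extends to 60 Hz, so fs must resolve it
    if (fs <= 2 * 60)
      stop("`fs` must exceed twice the highest generated frequency (60 Hz)")
    invisible(NULL)
  })
}

# unit-variance Gaussian noise low-passed with a Gaussian spectral kernel
smooth_noise <- function(n, fs, fc) {
  f <- (0:(n - 1)) * fs / n
  f2 <- pmin(f, fs - f)
  z <- complex(real = stats::rnorm(n), imaginary = stats::rnorm(n))
  x <- Re(stats::fft(z * exp(-(f2 / fc)^2), inverse = TRUE))
  x / stats::sd(x)
}

# unit-variance 1/f^alpha Gaussian noise band-limited to 0.5-60 Hz
pink_noise <- function(n, fs, alpha = 1) {
  f <- (0:(n - 1)) * fs / n
  f2 <- pmin(f, fs - f)
  amp <- ifelse(f2 >= 0.5 & f2 <= 60, 1 / pmax(f2, 0.5)^(alpha / 2), 0)
  z <- complex(real = stats::rnorm(n), imaginary = stats::rnorm(n))
  x <- Re(stats::fft(z * amp, inverse = TRUE))
  x / stats::sd(x)
}

# half-wave power transform: sharpens extrema, keeps zero crossings
phase_warp_shape <- function(u, shape) sign(u) * abs(u)^(1 + 2 * shape)

# raised-cosine step from 0 to 1 over [0, ramp] seconds
.ramp_window <- function(t, on, off, ramp = 0.5) {
  w <- numeric(length(t))
  inside <- t >= on & t < off
  w[inside] <- 1
  if (ramp > 0) {
    ri <- t >= on & t < on + ramp
    w[ri] <- 0.5 * (1 - cos(pi * (t[ri] - on) / ramp))
    ro <- t >= off - ramp & t < off
    w[ro] <- pmin(w[ro], 0.5 * (1 - cos(pi * (off - t[ro]) / ramp)))
  }
  w
}

# piecewise per-stage value over an event, linearly blended over `blend` s
.stage_profile <- function(t, on, off, values, blend = 1) {
  st <- split_stages(c(on, off))
  edges <- c(st[[1]][1], st[[1]][2], st[[2]][2], st[[3]][2])
  v <- numeric(length(t))
  for (k in 1:3) {
    lo <- edges[k]; hi <- edges[k + 1]
    v[t >= lo & t < hi] <- values[k]
  }
  v[t >= edges[4]] <- values[3]
  v[t < edges[1]] <- values[1]
  if (blend > 0) {
    for (k in 2:3) {
      b <- edges[k]
      zone <- t >= b - blend / 2 & t < b + blend / 2
      frac <- (t[zone] - (b - blend / 2)) / blend
      v[zone] <- values[k - 1] + frac * (values[k] - values[k - 1])
    }
  }
  v
}

#' Generate a synthetic multichannel recording with rated seizure events
#'
#' Draws a recording under the configured background and seizure model and
#' corrupts the ground-truth per-second seizure mask independently per rater
#' (boundary jitter plus event misses) to produce a multi-rater annotation
#' set. Identical seeds give bit-identical output.
#'
#' @param cfg an [synth_config()] object.
#' @return A list with elements `recording` ([recording()]),
#'   `annotations` (see [fuse_annotations()]), `truth` (ground-truth
#'   per-second 0/1 mask), and `events` (the configured intervals).
#' @examples
#' out <- generate_recording(synth_config(n_channels = 2, duration = 60,
#'   seizure_intervals = list(c(20, 40)), seed = 7))
#' out$recording
#' colSums(out$annotations$rater_masks)
#' @export
generate_recording <- function(cfg) {
  stopifnot(inherits(cfg, "nw_synth_config"))
  validate_synth_config(cfg)
  set.seed(cfg$seed)
  n <- cfg$duration * cfg$fs
  t <- (0:(n - 1)) / cfg$fs
  bgp <- cfg$background
  # inter-individual seizure-amplitude factor, one draw per recording
  subj_gain <- exp(stats::rnorm(1, 0, cfg$subject_gain_sd))
  w_sz <- numeric(n)         # combined seizure window
  osc <- numeric(n)          # shared seizure oscillation (unit gain profile)
  # scale so that gain g gives a seizure envelope g times the background
  # envelope (sqrt(2) per unit background RMS): normalize the warped
  # waveform by its own median envelope
  ref <- phase_warp_shape(cos(2 * pi * cfg$seizure_freq *
                                (0:(4 * cfg$fs - 1)) / cfg$fs),
                          cfg$sharpness_shape)
  env_scale <- sqrt(2) / stats::median(Mod(analytic_signal(ref)))
  for (iv in cfg$seizure_intervals) {
    w <- .ramp_window(t, iv[1], iv[2])
    w_sz <- pmax(w_sz, w)
    gain <- .stage_profile(t, iv[1], iv[2], cfg$envelope_gain_profile)
    eps <- .stage_profile(t, iv[1], iv[2], cfg$nonlinearity_eps)
    ph <- 2 * pi * cfg$seizure_freq * (t - iv[1])
    osc <- osc + w * gain * subj_gain * env_scale *
      phase_warp_shape(cos(ph + eps * sin(ph)), cfg$sharpness_shape)
  }
  sw <- rep_len(cfg$spatial_profile, cfg$n_channels)
  samples <- matrix(0, cfg$n_channels, n)
  for (i in seq_len(cfg$n_channels)) {
    finst <- bgp$f0 * (1 + bgp$fdrift * smooth_noise(n, cfg$fs, 0.2))
    phase <- 2 * pi * cumsum(finst) / cfg$fs
    amp <- pmax(1 + bgp$adrift * smooth_noise(n, cfg$fs, 0.3), 0.2)
    bg <- amp * cos(phase) + bgp$noise_mix * pink_noise(n, cfg$fs, bgp$alpha)
    bg <- bg / stats::sd(bg)
    supp <- 1 - (1 - cfg$bg_suppression) * w_sz
    samples[i, ] <- cfg$amplitude_uV * (supp * bg + sw[i] * osc)
  }
  rec <- recording(samples, cfg$fs, cfg$channel_labels)
  truth <- integer(cfg$duration)
  for (iv in cfg$seizure_intervals)
    truth[seq(floor(iv[1]) + 1, ceiling(iv[2]))] <- 1L
  masks <- .rater_masks(cfg, truth)
  list(recording = rec, annotations = fuse_annotations(masks),
       truth = truth, events = cfg$seizure_intervals)
}

.rater_masks <- function(cfg, truth) {
  masks <- matrix(0L, cfg$n_raters, cfg$duration)
  jit <- cfg$rater_noise$jitter_sd
  miss <- cfg$rater_noise$miss_prob
  for (r in seq_len(cfg$n_raters)) {
    for (iv in cfg$seizure_intervals) {
      if (miss > 0 && stats::runif(1) < miss) next
      a <- iv[1]; b <- iv[2]
      if (jit > 0) {
        a <- a + round(stats::rnorm(1, 0, jit))
        b <- b + round(stats::rnorm(1, 0, jit))
      }
      a <- max(0, min(a, cfg$duration - 1))
      b <- max(a + 1, min(b, cfg$duration))
      masks[r, seq(floor(a) + 1, ceiling(b))] <- 1L
    }
  }
  rownames(masks) <- paste0("rater", seq_len(cfg$n_raters))
  masks
}

#' Generate an intrawave-modulated test tone
#'
#' Single-channel tone `amplitude * cos(2*pi*freq*t + eps*sin(2*pi*freq*t))`.
#' With `eps = 0` this is a pure sinusoid; for `0 < eps < 1` the
#' instantaneous frequency is `freq * (1 + eps*cos(2*pi*freq*t))`, whose
#' normalized standard deviation over whole periods is `eps/sqrt(2)` -- the
#' closed-form reference for [degree_of_nonlinearity()].
#'
#' @param freq fundamental frequency (Hz), below `fs/2`.
#' @param amplitude peak amplitude (uV).
#' @param fs sampling rate (Hz).
#' @param duration length in seconds.
#' @param eps intrawave modulation depth in \[0, 1).
#' @return An [recording()] with one channel labelled `"SYNTH"`.
#' @examples
#' tone <- generate_pure_tone(3, fs = 256, duration = 4, eps = 0.2)
#' degree_of_nonlinearity(tone$samples[1, ], 256)  # ~ 0.2/sqrt(2)
#' @export
generate_pure_tone <- function(freq, amplitude = 1, fs = 256, duration = 1,
                               eps = 0) {
  if (eps < 0 || eps >= 1) stop("`eps` must lie in [0, 1)")
  if (freq >= fs / 2) stop("`freq` must be below the Nyquist frequency")
  t <- (0:(round(duration * fs) - 1)) / fs
  ph <- 2 * pi * freq * t
  recording(amplitude * cos(ph + eps * sin(ph)), fs, "SYNTH")
}
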