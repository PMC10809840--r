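# shared fixtures and independent oracles, built in code

make_tone <- function(freq, fs = 256, duration = 1, amplitude = 1, phase = 0) {
  amplitude * cos(2 * pi * freq * (0:(round(duration * fs) - 1)) / fs + phase)
}

# single-channel recording wrapper
tone_recording <- function(x, fs = 256, label = "C4-P4") {
  recording(matrix(x, nrow = 1), fs, label)
}

# complex frequency response of a b/a filter at frequency f (Hz)
freq_response <- function(b, a, f, fs) {
  z <- exp(-1i * 2 * pi * f / fs)
  vapply(seq_along(f), function(i) {
    zi <- z[i]^(0:(max(length(b), length(a)) - 1))
    abs(sum(b * zi[seq_along(b)]) / sum(a * zi[seq_along(a)]))
  }, numeric(1))
}

# RMS after discarding `trim` seconds at each end
rms_trimmed <- function(x, fs, trim = 1) {
  n <- length(x)
  sqrt(mean(x[(trim * fs + 1):(n - trim * fs)]^2))
}

# a tent signal with one interior peak of height `peak` at `at`, whose
# values exactly `d` samples either side are `left` and `right`
tent_signal <- function(n, at, d, peak, left, right) {
  x <- numeric(n)
  i <- seq_len(n)
  x[i <= at] <- peak - (at - i[i <= at]) * (peak - left) / d
  x[i > at] <- peak - (i[i > at] - at) * (peak - right) / d
  x
}

# small labelled feature table built directly (no signal processing);
# per-subject shifts emulate the repeated-measures structure
toy_feature_table <- function(n_subj = 6, channels = c("C4-P4", "Cz-Pz"),
                              effect = 0, sd = 0.2, n_epochs = 10,
                              feature = "envelope", seed = 1) {
  set.seed(seed)
  rows <- list()
  for (s in seq_len(n_subj)) {
    subj_shift <- rnorm(1, 0, 0.3)
    for (ch in channels) {
      for (lab in c("nonseizure", "S1", "S2", "S3")) {
        base <- 1 + subj_shift + if (lab == "nonseizure") 0 else effect
        rows[[length(rows) + 1]] <- data.frame(
          subject = sprintf("s%02d", s), channel = ch,
          epoch = seq_len(n_epochs), fusion = 3, label = lab,
          period = if (lab == "nonseizure") "nonseizure" else "seizure",
          feature = feature, value = exp(rnorm(n_epochs, base, sd)))
      }
    }
  }
  do.call(rbind, rows)
}
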