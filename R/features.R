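#' Analytic signal via the Hilbert transform
#'
#' FFT implementation: the negative-frequency half of the spectrum is
#' zeroed and the positive half doubled. The magnitude of the result is
#' the instantaneous envelope, its argument the instantaneous phase.
#'
#' @param x real numeric vector.
#' @return Complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 2) return(as.complex(x))
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Complex-envelope amplitude of an epoch
#'
#' The median of the instantaneous amplitude (modulus of the analytic
#' signal) over the epoch. The median is robust to the transient spikes
#' the Hilbert envelope develops at epoch edges. Per-period summaries
#' average these per-epoch medians. Despite the conventional name
#' "envelope power", this is an amplitude (not squared) measure.
#'
#' @param x single-channel epoch samples.
#' @return Scalar envelope value (0 for an all-zero epoch).
#' @export
complex_envelope <- function(x) {
  if (all(x == 0)) return(0)
  stats::median(Mod(analytic_signal(x)))
}

#' Sharpness detection parameters
#'
#' @param window_len sliding window length in samples (default 64, i.e.
#'   0.25 s at 256 Hz, long enough to hold one delta cycle).
#' @param tukey_taper Tukey window taper fraction in \[0, 1\].
#' @param flank_offset flank distance for the sharpness measure (ms).
#' @param flank_mode `"interp"` evaluates the flanks at exactly +/-7 ms by
#'   linear interpolation (sampling-rate independent); `"nearest"` uses the
#'   nearest sample.
#' @param polarity `"both"` detects maxima and minima (on the negated
#'   signal); `"max"` detects maxima only.
#' @return A list of class `nw_sharpness_params`.
#' @export
sharpness_params <- function(window_len = 64, tukey_taper = 0.5,
                             flank_offset = 7,
                             flank_mode = c("interp", "nearest"),
                             polarity = c("both", "max")) {
  if (window_len < 8) stop("`window_len` must be at least 8 samples")
  if (tukey_taper < 0 || tukey_taper > 1)
    stop("`tukey_taper` must lie in [0, 1]")
  if (flank_offset <= 0) stop("`flank_offset` must be positive")
  structure(list(window_len = window_len, tukey_taper = tukey_taper,
                 flank_offset = flank_offset,
                 flank_mode = match.arg(flank_mode),
                 polarity = match.arg(polarity)),
            class = "nw_sharpness_params")
}

# Tukey (tapered cosine) window of length n with taper fraction r
tukey_window <- function(n, r) {
  if (r <= 0) return(rep(1, n))
  if (r >= 1) return(0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1))))
  w <- rep(1, n)
  k <- 0:(n - 1)
  edge <- floor(r * (n - 1) / 2)
  lo <- k <= edge
  w[lo] <- 0.5 * (1 + cos(pi * (2 * k[lo] / (r * (n - 1)) - 1)))
  hi <- k >= (n - 1) * (1 - r / 2)
  w[hi] <- 0.5 * (1 + cos(pi * (2 * k[hi] / (r * (n - 1)) - 2 / r + 1)))
  w
}

#' Detect extrema with a sliding-window order-statistic filter
#'
#' A Tukey window slides over the signal with a one-sample shift. At each
#' position the weighted track is the maximum of the window-weighted
#' samples; positions where the input meets its own track (the center
#' weight is 1, so equality means no tapered neighbour exceeds the
#' sample) are the detected local maxima. The taper makes the criterion
#' adaptive: remote samples must exceed a peak by a growing margin to
#' suppress it, so detection is invariant to positive rescaling of the
#' input. The signal is median-centered before detection, so the detected
#' indices are invariant to constant offsets as well. With
#' `polarity = "both"` the filter is also run on the negated signal to
#' collect minima. Detections closer than half a window to the record
#' edge are discarded.
#'
#' @param x numeric samples, longer than the window.
#' @param params an [sharpness_params()] object.
#' @return Ordered integer sample indices of the detected extrema (empty
#'   when none are found).
#' @export
detect_extrema <- function(x, params = sharpness_params()) {
  n <- length(x)
  if (n <= params$window_len)
    stop("signal must be longer than the detection window")
  x <- x - stats::median(x)   # detection is offset-invariant by centering
  pk <- .osf_maxima(x, params)
  if (params$polarity == "both")
    pk <- sort(union(pk, .osf_maxima(-x, params)))
  pk
}

.osf_maxima <- function(x, params) {
  L <- params$window_len
  w <- tukey_window(L, params$tukey_taper)
  h <- L %/% 2
  offs <- seq_len(L) - 1 - (h - 1)            # center the window
  n <- length(x)
  track <- rep(-Inf, n)
  for (j in seq_len(L)) {
    o <- offs[j]
    src <- seq_len(n) + o
    ok <- src >= 1 & src <= n
    track[ok] <- pmax(track[ok], w[j] * x[src[ok]])
  }
  hit <- which(x >= track)
  # require a strict local maximum to break plateau/taper ties
  hit <- hit[hit > 1 & hit < n]
  hit <- hit[x[hit] >= x[hit - 1] & x[hit] >= x[hit + 1]]
  hit[hit > h & hit <= n - h]
}

#' Epileptic sharpness of a segment
#'
#' For each detected extremum the absolute voltage differences to the
#' signal 7 ms before and after are averaged,
#' `s_i = (|x_peak - x_peak-7ms| + |x_peak - x_peak+7ms|) / 2`, and the
#' sharpness of the segment is the median of `s_i` over all extrema whose
#' flanks fall inside the segment. On z-scored input the value is in
#' z-units. Invariant to constant offsets; scales linearly with amplitude.
#'
#' @param x numeric segment samples.
#' @param fs sampling rate (Hz).
#' @param params an [sharpness_params()] object.
#' @return Scalar sharpness, or `NA` (with attribute `flag = "no_extrema"`)
#'   when no usable extremum exists.
#' @examples
#' x <- sin(2 * pi * 4 * (0:255) / 256)
#' sharpness(x, 256)
#' @export
sharpness <- function(x, fs, params = sharpness_params()) {
  pk <- detect_extrema(x, params)
  d <- params$flank_offset / 1000 * fs
  if (params$flank_mode == "nearest") d <- round(d)
  pk <- pk[pk - d >= 1 & pk + d <= length(x)]
  if (!length(pk))
    return(structure(NA_real_, flag = "no_extrema"))
  flank <- function(at) {
    lo <- floor(at); frac <- at - lo
    v <- x[lo] * (1 - frac)
    up <- pmin(lo + 1, length(x))
    v + x[up] * frac
  }
  s <- (abs(x[pk] - flank(pk - d)) + abs(x[pk] - flank(pk + d))) / 2
  stats::median(s)
}

#' Degree of nonlinearity of a segment
#'
#' Quantifies intrawave frequency modulation: the standard deviation of
#' the instantaneous frequency (derivative of the unwrapped Hilbert
#' phase, central differences over interior samples), normalized by the
#' zero-crossing frequency of the segment
#' (`IF_z = zero crossings / (2 * duration)`). A pure sinusoid gives
#' ~0; the tone `cos(wt + eps*sin(wt))` gives `eps/sqrt(2)`. The first
#' and last `edge_trim` seconds are excluded from the standard deviation
#' to suppress Hilbert edge effects. Negative instantaneous frequencies
#' (phase slips) are retained but tracked: when more than 20% of samples
#' have negative IF the result carries attribute `quality = "phase_slips"`
#' and a warning is raised.
#'
#' @param x numeric segment samples (needs at least 2 zero crossings).
#' @param fs sampling rate (Hz).
#' @param edge_trim seconds dropped at each end (default 0.1).
#' @return Scalar DoN; `NA` with attribute `flag = "no_crossings"` when
#'   the zero-crossing frequency is zero.
#' @examples
#' t <- (0:1023) / 256
#' degree_of_nonlinearity(cos(2 * pi * 3 * t + 0.2 * sin(2 * pi * 3 * t)), 256)
#' @export
degree_of_nonlinearity <- function(x, fs, edge_trim = 0.1) {
  n <- length(x)
  s <- sign(x); s <- s[s != 0]
  zc <- sum(diff(s) != 0)
  if (zc == 0) return(structure(NA_real_, flag = "no_crossings"))
  if_z <- zc / (2 * (n / fs))
  ph <- Arg(analytic_signal(x))
  ph <- ph + 2 * pi * c(0, cumsum(round(-diff(ph) / (2 * pi))))  # unwrap
  inst <- (ph[3:n] - ph[1:(n - 2)]) * fs / (2 * 2 * pi)
  k <- max(1L, round(edge_trim * fs))
  idx <- seq.int(k, length(inst) - k + 1)
  inst <- inst[idx]
  out <- stats::sd((inst - if_z) / if_z)
  neg <- mean(inst < 0)
  if (neg > 0.2) {
    attr(out, "quality") <- "phase_slips"
    attr(out, "negative_if_fraction") <- neg
    warning(sprintf("%.0f%% of instantaneous frequencies are negative",
                    100 * neg), call. = FALSE)
  }
  out
}

.band_edges <- list(delta = c(1, 4), theta = c(4, 9), alpha = c(9, 13),
                    beta = c(13, 30), gamma = c(30, Inf))

#' Band powers of a 1-s epoch
#'
#' Hamming-windowed periodogram, power summed over the delta (1-4 Hz),
#' theta (4-9 Hz), alpha (9-13 Hz), beta (13-30 Hz) and gamma (>30 Hz)
#' bins. Per-period summaries average the per-epoch band powers.
#'
#' @param x epoch samples (one epoch).
#' @param fs sampling rate (Hz).
#' @return Named numeric vector of the five band powers.
#' @export
band_powers <- function(x, fs) {
  n <- length(x)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  X <- stats::fft(x * w)
  nf <- floor(n / 2)
  psd <- (Mod(X[2:(nf + 1)])^2) * 2 / (fs * sum(w^2))
  if (n %% 2 == 0) psd[nf] <- psd[nf] / 2      # Nyquist bin not doubled
  f <- (1:nf) * fs / n
  df <- fs / n
  vapply(.band_edges, function(be)
    sum(psd[f >= be[1] & f < be[2]]) * df, numeric(1))
}

#' Energy ratio of a band-power vector
#'
#' The proportion of high-frequency power (beta + gamma) relative to the
#' low-frequency component (theta + alpha); delta is excluded from both.
#'
#' @param bp named band-power vector from [band_powers()].
#' @return Scalar ratio; `NA` with attribute `flag = "zero_denominator"`
#'   when theta + alpha is zero.
#' @export
energy_ratio <- function(bp) {
  den <- bp[["theta"]] + bp[["alpha"]]
  if (den == 0) return(structure(NA_real_, flag = "zero_denominator"))
  (bp[["beta"]] + bp[["gamma"]]) / den
}

#' Root-mean-square amplitude
#'
#' @param x numeric samples.
#' @return `sqrt(mean(x^2))`.
#' @export
rms_amplitude <- function(x) {
  if (!length(x)) stop("empty input")
  sqrt(mean(x^2))
}

.all_features <- c("envelope", "sharpness", "don", "rms", "energy_ratio",
                   "delta", "theta", "alpha", "beta", "gamma")

#' Compute per-epoch features for every channel
#'
#' Splits each channel into nonoverlapping epochs aligned to sample 0 (a
#' final partial epoch is discarded) and evaluates the requested features
#' per epoch: `envelope` ([complex_envelope()]), `sharpness`
#' ([sharpness()]), `don` ([degree_of_nonlinearity()]), `rms`
#' ([rms_amplitude()]), `energy_ratio` and the five band powers.
#'
#' @param rec an [recording()] (normally preprocessed).
#' @param features character vector of feature names.
#' @param epoch_len epoch length in seconds (default 1).
#' @param params an [sharpness_params()] object.
#' @return Long data frame with columns `channel`, `epoch` (1-based),
#'   `feature`, `value`.
#' @export
extract_features <- function(rec, features = c("envelope", "sharpness", "don"),
                             epoch_len = 1, params = sharpness_params()) {
  stopifnot(inherits(rec, "nw_recording"))
  features <- match.arg(features, .all_features, several.ok = TRUE)
  spe <- round(epoch_len * rec$fs)
  n_ep <- floor(ncol(rec$samples) / spe)
  if (n_ep < 1) stop("recording shorter than one epoch")
  bands <- intersect(features, names(.band_edges))
  need_bp <- length(bands) > 0 || "energy_ratio" %in% features
  out <- vector("list", nrow(rec$samples))
  for (i in seq_len(nrow(rec$samples))) {
    ch <- rec$channel_labels[i]
    vals <- matrix(NA_real_, n_ep, length(features),
                   dimnames = list(NULL, features))
    for (e in seq_len(n_ep)) {
      x <- rec$samples[i, ((e - 1) * spe + 1):(e * spe)]
      if (need_bp) bp <- band_powers(x, rec$fs)
      for (f in features) {
        vals[e, f] <- switch(f,
          envelope = complex_envelope(x),
          sharpness = as.numeric(sharpness(x, rec$fs, params)),
          don = suppressWarnings(
            as.numeric(degree_of_nonlinearity(x, rec$fs))),
          rms = rms_amplitude(x),
          energy_ratio = as.numeric(energy_ratio(bp)),
          bp[[f]])
      }
    }
    out[[i]] <- data.frame(channel = ch, epoch = rep(seq_len(n_ep),
                                                     length(features)),
                           feature = rep(features, each = n_ep),
                           value = as.vector(vals))
  }
  do.call(rbind, out)
}

#' Build the labelled long-format feature table
#'
#' Combines [extract_features()] with per-epoch segment labels at every
#' annotation fusion level: each epoch is labelled `nonseizure`, `S1`,
#' `S2` or `S3` (seizure thirds) per level k.
#'
#' @param rec preprocessed [recording()].
#' @param ann `nw_annotations` from [fuse_annotations()] /
#'   [read_annotations()].
#' @param subject_id subject identifier stored in the table.
#' @param features,epoch_len,params passed to [extract_features()].
#' @param fusion_levels agreement levels to label (default all).
#' @return Data frame with columns `subject`, `channel`, `epoch`,
#'   `fusion`, `label` (`nonseizure`/`S1`/`S2`/`S3`), `period`
#'   (`seizure`/`nonseizure`), `feature`, `value`.
#' @export
feature_table <- function(rec, ann, subject_id = "s1",
                          features = c("envelope", "sharpness", "don"),
                          epoch_len = 1, params = sharpness_params(),
                          fusion_levels = seq_len(ann$n_raters)) {
  feats <- extract_features(rec, features, epoch_len, params)
  n_ep <- max(feats$epoch)
  out <- lapply(fusion_levels, function(k) {
    lab <- label_epochs(n_ep, epoch_len, ann$fused[[k]])
    df <- feats
    df$fusion <- k
    df$label <- lab[df$epoch]
    df
  })
  out <- do.call(rbind, out)
  out$period <- ifelse(out$label == "nonseizure", "nonseizure", "seizure")
  out$subject <- subject_id
  out[, c("subject", "channel", "epoch", "fusion", "label", "period",
          "feature", "value")]
}
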