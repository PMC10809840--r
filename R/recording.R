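#' Multichannel EEG recording
#'
#' Container for a uniformly sampled multichannel signal. Samples are stored
#' as a channels x time numeric matrix in microvolts; channel labels follow
#' the 10-20 convention (referential, e.g. `"C4"`) or the longitudinal
#' bipolar convention (`"C4-P4"`).
#'
#' @param samples numeric matrix, channels in rows, samples in columns (uV).
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector, one unique label per row.
#' @param start_time optional `POSIXct` acquisition start.
#' @return An object of class `nw_recording`.
#' @examples
#' rec <- recording(matrix(rnorm(512), 2), fs = 256, c("C4", "P4"))
#' rec
#' @export
recording <- function(samples, fs, channel_labels, start_time = NULL) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1)
  stopifnot(is.matrix(samples), is.numeric(samples))
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive number")
  if (length(channel_labels) != nrow(samples))
    stop("need one channel label per row of `samples`")
  channel_labels <- as.character(channel_labels)
  if (anyDuplicated(channel_labels))
    stop("channel labels must be unique")
  rownames(samples) <- channel_labels
  structure(
    list(samples = samples, fs = fs, channel_labels = channel_labels,
         start_time = start_time),
    class = "nw_recording")
}

#' @export
print.nw_recording <- function(x, ...) {
  cat(sprintf("<nw_recording> %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs, n_seconds(x)))
  lab <- x$channel_labels
  if (length(lab) > 8) lab <- c(lab[1:8], "...")
  cat("  channels:", paste(lab, collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.nw_recording <- function(x, channels = seq_len(min(6, nrow(x$samples))),
                              ...) {
  tt <- seq_len(ncol(x$samples)) / x$fs
  sub <- x$samples[channels, , drop = FALSE]
  sp <- 4 * stats::median(apply(sub, 1, stats::sd))
  graphics::plot(range(tt), c(0.5, length(channels) + 0.5), type = "n",
                 xlab = "time (s)", ylab = "", yaxt = "n", ...)
  graphics::axis(2, at = seq_along(channels),
                 labels = x$channel_labels[channels], las = 1)
  for (i in seq_along(channels))
    graphics::lines(tt, i + sub[i, ] / max(sp, .Machine$double.eps))
  invisible(x)
}

# duration in (possibly fractional) seconds
n_seconds <- function(rec) ncol(rec$samples) / rec$fs

# apply a function channel-wise, keeping the recording structure
map_channels <- function(rec, f, ...) {
  out <- t(apply(rec$samples, 1, f, ...))
  if (ncol(out) != ncol(rec$samples)) out <- t(out)
  rec$samples <- out
  rownames(rec$samples) <- rec$channel_labels
  rec
}
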