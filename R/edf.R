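# Minimal EDF (European Data Format) reader/writer for uniformly sampled
# EEG. Covers plain EDF with one data-record duration of 1 s and identical
# sampling rate across signals -- the layout clinical neonatal recordings
# use. Annotations channels (EDF+) are not interpreted.

edf_pad <- function(x, width) {
  x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width) edf_pad(formatC(x, format = "g", digits = 6), width)

#' Write a recording to an EDF file
#'
#' Samples are scaled per channel to the full signed 16-bit digital range,
#' so the round trip is exact up to that quantization. The recording must
#' span a whole number of seconds (EDF stores fixed 1-s data records).
#'
#' @param rec an [recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_edf()]
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "nw_recording"))
  ns <- nrow(rec$samples)
  nsamp <- ncol(rec$samples)
  if (nsamp %% rec$fs != 0)
    stop("recording must span a whole number of seconds for EDF export")
  nrec <- nsamp / rec$fs
  pmaxs <- apply(abs(rec$samples), 1, max)
  pmaxs <- ifelse(pmaxs > 0, pmaxs, 1)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X X X X", 80), edf_pad("Startdate X", 80),
    "01.01.00", "00.00.00",
    edf_pad(as.character(256 + ns * 256), 8), edf_pad("", 44),
    edf_pad(as.character(nrec), 8), edf_pad("1", 8),
    edf_pad(as.character(ns), 4))
  writeChar(hdr, con, eos = NULL)
  fields <- c(
    vapply(rec$channel_labels, edf_pad, "", width = 16),
    rep(edf_pad("", 80), ns),                    # transducer
    rep(edf_pad("uV", 8), ns),                   # physical dimension
    vapply(-pmaxs, edf_num, "", width = 8),      # physical minimum
    vapply(pmaxs, edf_num, "", width = 8),       # physical maximum
    rep(edf_pad("-32767", 8), ns),               # digital minimum
    rep(edf_pad("32767", 8), ns),                # digital maximum
    rep(edf_pad("", 80), ns),                    # prefiltering
    rep(edf_pad(as.character(rec$fs), 8), ns),   # samples per record
    rep(edf_pad("", 32), ns))
  writeChar(paste(fields, collapse = ""), con, eos = NULL)
  dig <- round(sweep(rec$samples, 1, pmaxs, "/") * 32767)
  for (r in seq_len(nrec)) {
    idx <- ((r - 1) * rec$fs + 1):(r * rec$fs)
    writeBin(as.integer(t(dig[, idx, drop = FALSE])), con, size = 2,
             endian = "little")
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' Returns samples in physical units (uV). Channel labels are normalized:
#' a leading `"EEG "` prefix and a trailing reference suffix (`"-REF"`,
#' `"-LE"`, `"-AVG"`) are stripped and whitespace trimmed.
#'
#' @param path path to an EDF/EDF+ file.
#' @return An [recording()].
#' @export
read_edf <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 256) stop("not a readable EDF file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  hdr_bytes <- as.integer(rd(8)); rd(44)
  nrec <- as.integer(rd(8))
  recdur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1 || is.na(nrec) || nrec < 0)
    stop("malformed EDF header: ", path)
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  replicate(ns, rd(80))                       # transducer
  replicate(ns, rd(8))                        # dimension
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  replicate(ns, rd(80))                       # prefiltering
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  replicate(ns, rd(32))
  if (length(unique(spr)) != 1L)
    stop("EDF files with differing per-signal sampling rates are not supported")
  expected <- hdr_bytes + nrec * sum(spr) * 2
  if (sz < expected)
    stop("truncated EDF file: expected ", expected, " bytes, found ", sz)
  fs <- spr[1] / recdur
  samples <- matrix(0, ns, nrec * spr[1])
  for (r in seq_len(nrec)) {
    d <- readBin(con, "integer", n = sum(spr), size = 2, endian = "little")
    dm <- matrix(d, nrow = spr[1])
    idx <- ((r - 1) * spr[1] + 1):(r * spr[1])
    samples[, idx] <- t(dm)
  }
  scale <- (pmax - pmin) / (dmax - dmin)
  samples <- sweep(sweep(samples, 1, dmin, "-"), 1, scale, "*")
  samples <- sweep(samples, 1, pmin, "+")
  recording(samples, fs, normalize_labels(labels))
}

# strip common EDF label decorations ("EEG Fp1-REF" -> "Fp1")
normalize_labels <- function(labels) {
  out <- trimws(labels)
  out <- sub("^EEG[ _]+", "", out, ignore.case = TRUE)
  out <- sub("[-_ ](REF|LE|AVG)$", "", out, ignore.case = TRUE)
  trimws(out)
}
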