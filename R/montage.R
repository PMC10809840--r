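#' Standard longitudinal bipolar montage
#'
#' The 18 anode-cathode pairs of the longitudinal ("double banana") bipolar
#' layout over the 10-20 electrode positions.
#'
#' @return A data frame with character columns `anode` and `cathode`.
#' @export
default_montage <- function() {
  pairs <- matrix(c(
    "Fp1", "F3", "F3", "C3", "C3", "P3", "P3", "O1",
    "Fp2", "F4", "F4", "C4", "C4", "P4", "P4", "O2",
    "Fp1", "F7", "F7", "T3", "T3", "T5", "T5", "O1",
    "Fp2", "F8", "F8", "T4", "T4", "T6", "T6", "O2",
    "Fz", "Cz", "Cz", "Pz"), ncol = 2, byrow = TRUE)
  data.frame(anode = pairs[, 1], cathode = pairs[, 2])
}

#' Derive a bipolar montage from a referential recording
#'
#' Each output channel is the sample-wise difference anode minus cathode,
#' labelled `"A-B"`. Label matching is case-insensitive after EDF label
#' normalization, so `"EEG FP1-REF"` matches `"Fp1"`. Because each channel
#' is a difference of two electrodes, any signal common to all referential
#' channels (the reference) cancels.
#'
#' @param rec referential [recording()].
#' @param montage data frame with columns `anode` and `cathode`;
#'   default [default_montage()].
#' @return An [recording()] with one channel per montage pair.
#' @examples
#' rec <- recording(rbind(Fz = c(1, 2), Cz = c(0, 1), Pz = c(2, 2)),
#'                  fs = 1, c("Fz", "Cz", "Pz"))
#' to_bipolar(rec, data.frame(anode = "Fz", cathode = "Cz"))$samples
#' @export
to_bipolar <- function(rec, montage = default_montage()) {
  stopifnot(inherits(rec, "nw_recording"))
  have <- toupper(normalize_labels(rec$channel_labels))
  need <- unique(c(montage$anode, montage$cathode))
  missing <- need[!toupper(need) %in% have]
  if (length(missing)) {
    bad <- montage[toupper(montage$anode) %in% toupper(missing) |
                   toupper(montage$cathode) %in% toupper(missing), ]
    stop("electrode(s) absent from recording: ",
         paste(missing, collapse = ", "), " (needed for pair(s) ",
         paste(paste0(bad$anode, "-", bad$cathode), collapse = ", "), ")")
  }
  idx <- function(lab) match(toupper(lab), have)
  out <- rec$samples[idx(montage$anode), , drop = FALSE] -
    rec$samples[idx(montage$cathode), , drop = FALSE]
  recording(out, rec$fs, paste0(montage$anode, "-", montage$cathode),
            rec$start_time)
}
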