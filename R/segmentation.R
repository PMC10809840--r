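#' Convert a per-second binary mask to seizure events
#'
#' Maximal runs of 1s become half-open `[start, end)` intervals in
#' seconds (0-based).
#'
#' @param mask 0/1 vector, one value per second.
#' @return Numeric matrix with columns `start`, `end` (0 rows when the
#'   mask is empty).
#' @examples
#' mask_to_events(c(0, 1, 1, 1, 0))   # one event [1, 4)
#' @export
mask_to_events <- function(mask) {
  if (!all(mask %in% c(0, 1))) stop("mask must be binary")
  r <- rle(as.integer(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values == 1L
  cbind(start = starts[keep], end = ends[keep])
}

#' Split a seizure event into three equal-length stages
#'
#' Stage boundaries sit at `round(n/3)` and `round(2n/3)` seconds from the
#' event start (second resolution, matching the annotation resolution),
#' yielding the starting (S1), middle (S2) and end (S3) stages whose
#' lengths differ by at most 1 s.
#'
#' @param event numeric `c(start_s, end_s)` with length at least 3 s.
#' @return List of three `c(start, end)` intervals.
#' @examples
#' split_stages(c(0, 10))   # lengths 3, 4, 3
#' @export
split_stages <- function(event) {
  n <- event[2] - event[1]
  if (n < 3) stop("events shorter than 3 s are excluded from stage analysis")
  b1 <- event[1] + round(n / 3)
  b2 <- event[1] + round(2 * n / 3)
  list(S1 = c(event[1], b1), S2 = c(b1, b2), S3 = c(b2, event[2]))
}

#' Label epochs as nonseizure or seizure stage
#'
#' Maps a fused per-second mask onto an epoch grid. Events are split into
#' stages with [split_stages()]; events shorter than 3 s are labelled by
#' whole-event membership under `S1`..`S3` proportionally -- they are kept
#' as seizure but excluded from stage analysis by flagging (attribute
#' `short_events`). An epoch straddling a boundary takes the label
#' covering more than half of it.
#'
#' @param n_epochs number of epochs on the grid.
#' @param epoch_len epoch length in seconds.
#' @param mask fused 0/1 per-second mask.
#' @return Character vector of labels (`"nonseizure"`, `"S1"`, `"S2"`,
#'   `"S3"`), one per epoch.
#' @export
label_epochs <- function(n_epochs, epoch_len, mask) {
  events <- mask_to_events(mask)
  stages <- list()
  short <- list()
  if (nrow(events)) {
    for (i in seq_len(nrow(events))) {
      ev <- events[i, ]
      if (ev[2] - ev[1] >= 3) {
        stages <- c(stages, split_stages(ev))
      } else {
        # too short to stage: count the whole event as its middle
        stages <- c(stages, list(S2 = unname(ev)))
        short <- c(short, list(unname(ev)))
      }
    }
  }
  labels <- character(n_epochs)
  for (e in seq_len(n_epochs)) {
    lo <- (e - 1) * epoch_len
    hi <- e * epoch_len
    best <- "nonseizure"; best_cov <- 0; total <- 0
    for (j in seq_along(stages)) {
      iv <- stages[[j]]
      cov <- max(0, min(hi, iv[2]) - max(lo, iv[1]))
      total <- total + cov
      if (cov > best_cov) { best_cov <- cov; best <- names(stages)[j] }
    }
    # majority rule: seizure when it covers > 50%, labelled by the
    # dominant stage; exact halves stay nonseizure
    labels[e] <- if (total > (hi - lo) / 2) best else "nonseizure"
  }
  if (length(short)) attr(labels, "short_events") <- short
  labels
}
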