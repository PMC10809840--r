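#' Fuse per-rater seizure masks into consensus annotation levels
#'
#' Given one binary mask per rater at 1-s resolution, builds the fused
#' masks at every agreement level: `fused[[k]][t] = 1` when at least `k`
#' raters marked second `t` as seizure. Raising `k` can only remove
#' seizure seconds, so `fused[[3]]` is contained in `fused[[2]]`, which is
#' contained in `fused[[1]]`.
#'
#' @param masks integer/numeric matrix of 0/1, raters in rows, seconds in
#'   columns.
#' @return An object of class `nw_annotations`: list with `rater_masks`,
#'   `n_raters`, and `fused` (list indexed by agreement level k).
#' @examples
#' m <- rbind(c(1, 1, 0), c(1, 0, 0), c(1, 1, 0))
#' fuse_annotations(m)$fused[[2]]
#' @export
fuse_annotations <- function(masks) {
  if (is.vector(masks)) masks <- matrix(masks, nrow = 1)
  if (!all(masks %in% c(0, 1)))
    stop("rater masks must be binary (0/1)")
  masks <- matrix(as.integer(masks), nrow = nrow(masks),
                  dimnames = dimnames(masks))
  votes <- colSums(masks)
  fused <- lapply(seq_len(nrow(masks)), function(k) as.integer(votes >= k))
  structure(list(rater_masks = masks, n_raters = nrow(masks), fused = fused),
            class = "nw_annotations")
}

#' @export
print.nw_annotations <- function(x, ...) {
  cat(sprintf("<nw_annotations> %d rater(s) x %d s\n", x$n_raters,
              ncol(x$rater_masks)))
  for (k in seq_along(x$fused))
    cat(sprintf("  fused k=%d: %d seizure second(s)\n", k, sum(x$fused[[k]])))
  invisible(x)
}

#' Write rater masks as a per-second CSV
#'
#' One row per second, one 0/1 column per rater, with a header row of
#' rater names.
#'
#' @param ann an `nw_annotations` object or a raters x seconds 0/1 matrix.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  masks <- if (inherits(ann, "nw_annotations")) ann$rater_masks else ann
  df <- as.data.frame(t(masks))
  names(df) <- paste0("rater", seq_len(nrow(masks)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read per-rater annotation masks from CSV
#'
#' Expects one row per second and one column per rater. A header row is
#' tolerated but not required (a first line that does not parse as numbers
#' is treated as a header).
#'
#' @param path CSV path.
#' @return An `nw_annotations` object (see [fuse_annotations()]).
#' @export
read_annotations <- function(path) {
  first <- utils::read.csv(path, header = FALSE, nrows = 1,
                           colClasses = "character")
  has_header <- any(is.na(suppressWarnings(as.numeric(unlist(first)))))
  df <- utils::read.csv(path, header = has_header)
  m <- t(as.matrix(df))
  if (!all(m %in% c(0, 1)))
    stop("annotation CSV must contain only 0/1 values")
  rownames(m) <- if (has_header) names(df) else
    paste0("rater", seq_len(nrow(m)))
  fuse_annotations(m)
}
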