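#' Binarise one marker channel
#'
#' Global Otsu threshold by default (the acquisition-time thresholding of the
#' original microscope workflow is not recoverable from exported images), or
#' a fixed threshold. Components smaller than `min_signal_area` pixels are
#' discarded as noise specks. A constant channel yields an empty mask with a
#' warning.
#'
#' @param channel 2-D intensity matrix.
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold Numeric threshold when `method = "fixed"`.
#' @param min_signal_area Minimum component area retained, px.
#' @param min_contrast Minimum separation between foreground and background
#'   means in units of the background standard deviation for an Otsu split
#'   to be accepted; guards against bisecting pure noise on a signal-free
#'   channel (a channel failing the guard yields an empty mask).
#' @return A list of class `marker_mask`: `mask` (logical), `labels`
#'   (8-connected component labels, dense), `n_components`.
#' @export
segment_marker <- function(channel, method = c("otsu", "fixed"),
                           threshold = NULL, min_signal_area = 5,
                           min_contrast = 5) {
  method <- match.arg(method)
  stopifnot(is.matrix(channel))
  empty <- function(msg) {
    warning("segment_marker: ", msg, "; returning empty mask")
    structure(list(mask = matrix(FALSE, nrow(channel), ncol(channel)),
                   labels = matrix(0L, nrow(channel), ncol(channel)),
                   n_components = 0L),
              class = "marker_mask")
  }
  if (max(channel) == min(channel))
    return(empty("constant channel"))
  thr <- if (method == "otsu")
    EBImage::otsu(EBImage::Image(channel), range = range(channel))
  else as.numeric(threshold)
  fg <- channel > thr
  if (method == "otsu") {
    bg_sd <- stats::sd(channel[!fg])
    snr <- (mean(channel[fg]) - mean(channel[!fg])) /
      max(bg_sd, .Machine$double.eps)
    if (!is.finite(snr) || snr < min_contrast)
      return(empty("no foreground distinguishable from background noise"))
  }
  lab <- EBImage::bwlabel(fg)
  if (max(lab) > 0 && min_signal_area > 1) {
    sizes <- tabulate(lab[lab > 0], nbins = max(lab))
    drop <- which(sizes < min_signal_area)
    if (length(drop)) {
      fg[lab %in% drop] <- FALSE
      lab <- EBImage::bwlabel(fg)
    }
  }
  structure(list(mask = fg, labels = matrix(as.integer(lab), nrow(lab)),
                 n_components = as.integer(max(lab))),
            class = "marker_mask")
}

#' Overlap positivity rule (OLIG2)
#'
#' A nucleus is positive when the marker foreground covers at least
#' `min_overlap_fraction` of the nucleus mask — the nuclear-overlap rule used
#' for transcription-factor signal.
#'
#' @param nuclei A `nucleus_set`.
#' @param mask A `marker_mask` sharing the image shape.
#' @param min_overlap_fraction Minimum covered fraction of the nucleus mask.
#' @return Sorted integer vector of positive nucleus labels.
#' @export
call_overlap_marker <- function(nuclei, mask, min_overlap_fraction = 0.1) {
  stopifnot(inherits(nuclei, "nucleus_set"), inherits(mask, "marker_mask"),
            all(dim(nuclei$labels) == dim(mask$mask)))
  if (nrow(nuclei$table) == 0L || !any(mask$mask)) return(integer(0))
  inter <- nuclei$labels[mask$mask]
  inter <- inter[inter > 0]
  if (!length(inter)) return(integer(0))
  ov <- tabulate(inter, nbins = max(nuclei$table$label))
  areas <- nuclei$table$area[order(nuclei$table$label)]
  sort(which(ov / areas >= min_overlap_fraction))
}

#' Adjacency positivity rule (DCX / NES)
#'
#' A marker component is adjacent to a nucleus when it intersects the
#' morphological dilation of that nucleus's mask by `adjacency_px` (disc
#' structuring element). Every nucleus a component is adjacent to is called
#' positive — a signal adjacent to more than one nucleus counts all of them —
#' but each nucleus is counted at most once per marker. Components adjacent
#' to no nucleus contribute nothing.
#'
#' @param nuclei A `nucleus_set`.
#' @param mask A `marker_mask`.
#' @param adjacency_px Dilation radius in pixels.
#' @param voronoi Optional `voronoi_partition`; accepted for pipeline
#'   symmetry (territories are reported for audit) but not needed by the
#'   dilation-intersection semantics.
#' @return Sorted integer vector of positive nucleus labels.
#' @export
call_adjacent_marker <- function(nuclei, mask, adjacency_px = 3,
                                 voronoi = NULL) {
  stopifnot(inherits(nuclei, "nucleus_set"), inherits(mask, "marker_mask"),
            all(dim(nuclei$labels) == dim(mask$mask)))
  n <- nrow(nuclei$table)
  if (n == 0L || mask$n_components == 0L) return(integer(0))
  h <- nrow(mask$mask); w <- ncol(mask$mask)
  brush <- EBImage::makeBrush(2L * as.integer(ceiling(adjacency_px)) + 1L,
                              shape = "disc")
  pad <- as.integer(ceiling(adjacency_px)) + 1L
  pos <- logical(n)
  for (k in nuclei$table$label) {
    px <- which(nuclei$labels == k, arr.ind = TRUE)
    r0 <- max(1L, min(px[, 1]) - pad); r1 <- min(h, max(px[, 1]) + pad)
    c0 <- max(1L, min(px[, 2]) - pad); c1 <- min(w, max(px[, 2]) + pad)
    crop <- nuclei$labels[r0:r1, c0:c1] == k
    dil <- EBImage::dilate(crop, brush) > 0
    if (any(dil & mask$mask[r0:r1, c0:c1])) pos[k] <- TRUE
  }
  which(pos)
}
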