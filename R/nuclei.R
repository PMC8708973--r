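#' Nucleus detection parameters
#'
#' Operationalises the "oval and coherent" nucleus rule: a connected Hoechst
#' foreground component is kept as a nucleus when its pixel area, convex
#' solidity and ellipse eccentricity all fall inside the stated bounds.
#'
#' @param area_min,area_max Retained component area bounds, px^2.
#' @param solidity_min Minimum area / convex-hull-area ("coherent").
#' @param ecc_max Maximum moment eccentricity ("oval").
#' @param threshold `"otsu"` (default) or a fixed numeric threshold on the
#'   `[0, 1]` intensity scale.
#' @return A list of class `nucleus_params`.
#' @export
nucleus_params <- function(area_min = 80, area_max = 8000,
                           solidity_min = 0.8, ecc_max = 0.95,
                           threshold = "otsu") {
  structure(list(area_min = area_min, area_max = area_max,
                 solidity_min = solidity_min, ecc_max = ecc_max,
                 threshold = threshold),
            class = "nucleus_params")
}

# area / convex-hull polygon area from a component's pixel coordinates;
# the shoelace hull area on pixel centres can undercut the discrete area
# slightly, so solidity is clamped to 1.
pixel_solidity <- function(rows, cols) {
  n <- length(rows)
  if (n <= 3) return(1)
  hull <- grDevices::chull(cols, rows)
  hx <- cols[hull]; hy <- rows[hull]
  m <- length(hull)
  if (m < 3) return(1)
  shoelace <- abs(sum(hx * hy[c(2:m, 1)] - hx[c(2:m, 1)] * hy)) / 2
  min(1, n / max(shoelace, n))
}

#' Detect nuclei in the Hoechst channel
#'
#' Thresholds the nuclei channel (Otsu by default), labels 8-connected
#' foreground components, and retains those passing the shape filter in
#' `params`. Zero retained nuclei is a valid (empty) result, reported with a
#' message rather than an error.
#'
#' @param nuclei_channel Single-channel 2-D intensity matrix on `[0, 1]`.
#' @param params A [nucleus_params()].
#' @return A list of class `nucleus_set`:
#'   \describe{
#'     \item{labels}{integer label image with dense labels `1..n` (0 =
#'       background) for the retained nuclei.}
#'     \item{table}{data.frame per nucleus: `label`, centroid `row`/`col`,
#'       `area`, `eccentricity`, `solidity`.}
#'     \item{dim}{image dimensions.}
#'   }
#' @export
detect_nuclei <- function(nuclei_channel, params = nucleus_params()) {
  stopifnot(is.matrix(nuclei_channel))
  x <- nuclei_channel
  thr <- if (identical(params$threshold, "otsu")) {
    if (max(x) == min(x)) Inf else EBImage::otsu(EBImage::Image(x), range = range(x))
  } else as.numeric(params$threshold)
  fg <- x > thr
  if (!any(fg)) {
    message("detect_nuclei: no foreground; returning empty nucleus set")
    return(empty_nucleus_set(dim(x)))
  }
  lab <- EBImage::bwlabel(fg)
  ids <- seq_len(max(lab))
  px <- which(lab > 0, arr.ind = TRUE)
  comp <- lab[px]
  ord <- order(comp)
  px <- px[ord, , drop = FALSE]; comp <- comp[ord]
  idx <- split(seq_len(nrow(px)), comp)

  keep <- integer(0)
  rows_out <- list()
  for (k in ids) {
    i <- idx[[as.character(k)]]
    if (is.null(i)) next
    rows <- px[i, 1]; cols <- px[i, 2]
    area <- length(i)
    if (area < params$area_min || area > params$area_max) next
    sol <- pixel_solidity(rows, cols)
    if (sol < params$solidity_min) next
    ecc <- moment_eccentricity(rows, cols)
    if (ecc > params$ecc_max) next
    keep <- c(keep, k)
    rows_out[[length(rows_out) + 1L]] <-
      data.frame(label = NA_integer_, row = mean(rows), col = mean(cols),
                 area = area, eccentricity = ecc, solidity = sol)
  }
  if (length(keep) == 0L) {
    message("detect_nuclei: no component passed the shape filter")
    return(empty_nucleus_set(dim(x)))
  }
  # relabel densely 1..n in original label order
  newlab <- integer(max(lab)); newlab[keep] <- seq_along(keep)
  labels <- matrix(0L, nrow(x), ncol(x))
  sel <- comp %in% keep
  labels[px[sel, , drop = FALSE]] <- newlab[comp[sel]]
  tab <- do.call(rbind, rows_out)
  tab$label <- seq_along(keep)
  structure(list(labels = labels, table = tab[, c("label", "row", "col",
                                                  "area", "eccentricity",
                                                  "solidity")],
                 dim = dim(x)),
            class = "nucleus_set")
}

empty_nucleus_set <- function(dm) {
  structure(list(labels = matrix(0L, dm[1], dm[2]),
                 table = data.frame(label = integer(0), row = numeric(0),
                                    col = numeric(0), area = numeric(0),
                                    eccentricity = numeric(0),
                                    solidity = numeric(0)),
                 dim = dm),
            class = "nucleus_set")
}

# Eccentricity from second central moments (same definition as image-moment
# ellipse fitting): sqrt(1 - lambda_min/lambda_max).
moment_eccentricity <- function(rows, cols) {
  mrr <- stats::var(rows) * (length(rows) - 1) / length(rows)
  mcc <- stats::var(cols) * (length(cols) - 1) / length(cols)
  mrc <- stats::cov(rows, cols) * (length(rows) - 1) / length(rows)
  tr <- mrr + mcc
  det <- mrr * mcc - mrc^2
  disc <- sqrt(max(tr^2 / 4 - det, 0))
  l1 <- tr / 2 + disc; l2 <- tr / 2 - disc
  if (l1 <= 0) return(0)
  sqrt(max(1 - l2 / l1, 0))
}

#' Construct a nucleus set from a known label image
#'
#' Convenience constructor used with the synthetic generator's ground-truth
#' label image, bypassing detection.
#'
#' @param labels Integer label matrix, labels dense `1..n`.
#' @return A `nucleus_set`.
#' @export
nucleus_set_from_labels <- function(labels) {
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) && !identical(as.integer(ids), seq_along(ids)))
    stop("labels must be dense 1..n")
  tab <- do.call(rbind, lapply(ids, function(k) {
    px <- which(labels == k, arr.ind = TRUE)
    data.frame(label = k, row = mean(px[, 1]), col = mean(px[, 2]),
               area = nrow(px),
               eccentricity = moment_eccentricity(px[, 1], px[, 2]),
               solidity = pixel_solidity(px[, 1], px[, 2]))
  }))
  if (is.null(tab))
    return(empty_nucleus_set(dim(labels)))
  structure(list(labels = labels, table = tab, dim = dim(labels)),
            class = "nucleus_set")
}
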