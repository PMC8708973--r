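#' Specification for a synthetic multiplex immunofluorescence field
#'
#' Describes one simulated four-channel field (nuclei/Hoechst, OLIG2, NES,
#' DCX). The generator places elliptical nuclei with a minimum centroid
#' spacing, draws per-cell marker positivity from the given fractions
#' (optionally reweighted towards co-positivity), and renders marker signal
#' with channel-specific morphology: OLIG2 as a nuclear blob contained in the
#' nucleus mask, DCX and NES as thin branched perinuclear filaments that stay
#' outside every nucleus interior but hug their own nucleus boundary.
#'
#' @param width,height Field size in pixels.
#' @param n_cells Number of cells to place (>= 1).
#' @param nucleus_radius_range Length-2 numeric, min and max semi-major axis
#'   of the nuclear ellipse in pixels.
#' @param nucleus_eccentricity_max Maximum ellipse eccentricity in `[0, 1)`.
#' @param marker_fractions Named fractions in `[0, 1]` for `OLIG2`, `NES`,
#'   `DCX`: the marginal probability that a cell is truly positive.
#' @param pair_enrichment Named odds multipliers (>= 0) for co-positivity of
#'   the pairs `OLIG2.NES`, `OLIG2.DCX`, `NES.DCX`; 1 means independence.
#' @param signal_intensity Named per-channel mean foreground intensity on the
#'   `[0, 1]` scale (channels `nuclei`, `OLIG2`, `NES`, `DCX`).
#' @param noise_sd Per-channel Gaussian background noise sd (scalar recycled).
#' @param background Mean background intensity.
#' @param min_centroid_spacing Minimum Euclidean distance between nucleus
#'   centroids, pixels.
#' @param bit_depth Intensity quantisation on file output, 8 or 16 (default
#'   16, matching typical confocal TIFFs).
#' @param seed Integer seed; identical spec + seed gives bit-identical output.
#' @return An object of class `image_sim_spec`.
#' @export
image_sim_spec <- function(width = 600L, height = 600L, n_cells = 250L,
                           nucleus_radius_range = c(7, 10),
                           nucleus_eccentricity_max = 0.7,
                           marker_fractions = c(OLIG2 = 0.10, NES = 0.20, DCX = 0.05),
                           pair_enrichment = c(OLIG2.NES = 1, OLIG2.DCX = 1, NES.DCX = 1),
                           signal_intensity = c(nuclei = 0.85, OLIG2 = 0.75,
                                                NES = 0.70, DCX = 0.70),
                           noise_sd = 0.010,
                           background = 0.03,
                           min_centroid_spacing = 24,
                           bit_depth = 16L,
                           seed = 1L) {
  spec <- list(width = as.integer(width), height = as.integer(height),
               n_cells = as.integer(n_cells),
               nucleus_radius_range = as.numeric(nucleus_radius_range),
               nucleus_eccentricity_max = as.numeric(nucleus_eccentricity_max),
               marker_fractions = marker_fractions,
               pair_enrichment = pair_enrichment,
               signal_intensity = signal_intensity,
               noise_sd = noise_sd, background = background,
               min_centroid_spacing = as.numeric(min_centroid_spacing),
               bit_depth = as.integer(bit_depth), seed = as.integer(seed))
  class(spec) <- "image_sim_spec"
  validate_image_sim_spec(spec)
  spec
}

validate_image_sim_spec <- function(spec) {
  stopifnot(inherits(spec, "image_sim_spec"))
  if (spec$n_cells < 1L)
    stop("n_cells must be >= 1")
  rr <- spec$nucleus_radius_range
  if (length(rr) != 2L || any(rr <= 0) || rr[1] > rr[2])
    stop("nucleus_radius_range must be (min, max) with 0 < min <= max")
  if (spec$width < 2 * rr[2] || spec$height < 2 * rr[2])
    stop("field must be at least twice the maximum nucleus radius on each side")
  e <- spec$nucleus_eccentricity_max
  if (e < 0 || e >= 1)
    stop("nucleus_eccentricity_max must lie in [0, 1)")
  mf <- spec$marker_fractions
  if (!all(c("OLIG2", "NES", "DCX") %in% names(mf)))
    stop("marker_fractions must name OLIG2, NES and DCX")
  if (any(mf < 0 | mf > 1))
    stop("marker_fractions must lie in [0, 1]")
  if (any(spec$pair_enrichment < 0))
    stop("pair_enrichment odds multipliers must be >= 0")
  invisible(spec)
}

# Joint marker draw: independent Bernoulli marginals reweighted by pairwise
# odds multipliers over the 8 combinations (multiplier 1 == independence).
draw_marker_truth <- function(n, fractions, enrichment) {
  combos <- expand.grid(OLIG2 = c(FALSE, TRUE), NES = c(FALSE, TRUE),
                        DCX = c(FALSE, TRUE))
  p <- rep(1, nrow(combos))
  for (m in c("OLIG2", "NES", "DCX")) {
    pm <- fractions[[m]]
    p <- p * ifelse(combos[[m]], pm, 1 - pm)
  }
  pairs <- list(OLIG2.NES = c("OLIG2", "NES"),
                OLIG2.DCX = c("OLIG2", "DCX"),
                NES.DCX  = c("NES", "DCX"))
  for (pr in names(pairs)) {
    w <- enrichment[[pr]]
    if (!is.null(w) && w != 1) {
      both <- combos[[pairs[[pr]][1]]] & combos[[pairs[[pr]][2]]]
      p[both] <- p[both] * w
    }
  }
  if (sum(p) == 0) stop("degenerate marker probability table")
  idx <- sample.int(nrow(combos), n, replace = TRUE, prob = p / sum(p))
  combos[idx, , drop = FALSE]
}

# Dart-throwing placement with a minimum pairwise spacing; errors if the
# requested count cannot be packed, reporting the achieved count.
place_centroids <- function(n, width, height, spacing, margin, max_tries = 200L) {
  rows <- numeric(0); cols <- numeric(0)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      r <- stats::runif(1, 1 + margin, height - margin)
      c <- stats::runif(1, 1 + margin, width - margin)
      if (length(rows) == 0 || min((rows - r)^2 + (cols - c)^2) >= spacing^2) {
        rows <- c(rows, r); cols <- c(cols, c); placed <- TRUE
        break
      }
    }
    if (!placed)
      stop(sprintf(
        "packing failure: placed only %d of %d cells at spacing %.1f px",
        length(rows), n, spacing))
  }
  cbind(row = rows, col = cols)
}

# Pixels of a filled rotated ellipse, clipped to the field. Returns a
# two-column integer matrix (row, col).
ellipse_pixels <- function(cr, cc, a, b, theta, height, width) {
  rad <- ceiling(a) + 1L
  rs <- max(1L, floor(cr - rad)):min(height, ceiling(cr + rad))
  cs <- max(1L, floor(cc - rad)):min(width, ceiling(cc + rad))
  g <- expand.grid(row = rs, col = cs)
  dr <- g$row - cr; dc <- g$col - cc
  u <- dr * cos(theta) + dc * sin(theta)
  v <- -dr * sin(theta) + dc * cos(theta)
  keep <- (u / a)^2 + (v / b)^2 <= 1
  as.matrix(g[keep, , drop = FALSE])
}

# Perinuclear branched filament: 2-5 arcs riding just outside the ellipse
# boundary (radial offset 1..3 px), each with small angular jitter and an
# occasional short outward twig. Returns (row, col) pixels outside the
# nucleus interior.
branch_pixels <- function(cr, cc, a, b, theta, height, width, n_branches,
                          offset_range = c(1, 3)) {
  pts <- NULL
  for (k in seq_len(n_branches)) {
    phi0 <- stats::runif(1, 0, 2 * pi)
    len <- stats::runif(1, 0.5, 1.4)                    # arc length, radians
    phis <- seq(phi0, phi0 + len, by = 0.035)
    off <- stats::runif(1, offset_range[1], offset_range[2]) +
      cumsum(stats::rnorm(length(phis), 0, 0.08))
    off <- pmin(pmax(off, 0.8), offset_range[2] + 0.5)
    # ellipse boundary radius at body-frame angle phi
    rb <- (a * b) / sqrt((b * cos(phis))^2 + (a * sin(phis))^2)
    rad <- rb + off
    u <- rad * cos(phis); v <- rad * sin(phis)
    rr <- cr + u * cos(theta) - v * sin(theta)
    cols <- cc + u * sin(theta) + v * cos(theta)
    pts <- rbind(pts, cbind(rr, cols))
    if (stats::runif(1) < 0.5) {                        # outward twig
      j <- sample(seq_along(phis), 1L)
      tl <- stats::runif(1, 2, 4)
      ts <- seq(0, tl, by = 0.5)
      rr2 <- rr[j] + ts * cos(phis[j] + theta)
      cc2 <- cols[j] + ts * sin(phis[j] + theta)
      pts <- rbind(pts, cbind(rr2, cc2))
    }
  }
  px <- unique(cbind(round(pts[, 1]), round(pts[, 2])))
  keep <- px[, 1] >= 1 & px[, 1] <= height & px[, 2] >= 1 & px[, 2] <= width
  px <- px[keep, , drop = FALSE]
  # stay out of the own-nucleus interior (other nuclei are beyond spacing)
  dr <- px[, 1] - cr; dc <- px[, 2] - cc
  u <- dr * cos(theta) + dc * sin(theta)
  v <- -dr * sin(theta) + dc * cos(theta)
  px[(u / a)^2 + (v / b)^2 > 1, , drop = FALSE]
}

#' Generate a ground-truthed synthetic four-channel immunofluorescence field
#'
#' Renders one field according to an [image_sim_spec()]: elliptical nuclei in
#' the Hoechst channel, OLIG2 as intranuclear blobs, DCX/NES as perinuclear
#' branched filaments, plus Gaussian background noise in every channel.
#'
#' @param spec An [image_sim_spec()].
#' @return A list with elements
#'   \describe{
#'     \item{image}{named list of `height x width` intensity matrices on
#'       `[0, 1]` for channels `nuclei`, `OLIG2`, `NES`, `DCX`, of class
#'       `mif_image` (attributes `channels`, `bit_depth`).}
#'     \item{labels}{integer nucleus label image (0 = background), labels
#'       dense `1..n_cells`.}
#'     \item{truth}{data.frame with one row per cell: `cell_id`, centroid
#'       `row`/`col`, `nucleus_label`, and logical `olig2`, `nes`, `dcx`.}
#'   }
#' @export
generate_if_image <- function(spec) {
  validate_image_sim_spec(spec)
  set.seed(spec$seed)
  h <- spec$height; w <- spec$width
  rr <- spec$nucleus_radius_range
  cents <- place_centroids(spec$n_cells, w, h, spec$min_centroid_spacing,
                           margin = rr[2] + 1)
  n <- spec$n_cells
  a <- stats::runif(n, rr[1], rr[2])
  ecc <- stats::runif(n, 0, spec$nucleus_eccentricity_max)
  b <- a * sqrt(1 - ecc^2)
  theta <- stats::runif(n, 0, pi)
  truth_mk <- draw_marker_truth(n, spec$marker_fractions, spec$pair_enrichment)

  labels <- matrix(0L, h, w)
  chan <- function() matrix(0, h, w)
  sig <- list(nuclei = chan(), OLIG2 = chan(), NES = chan(), DCX = chan())
  si <- spec$signal_intensity

  for (i in seq_len(n)) {
    np <- ellipse_pixels(cents[i, 1], cents[i, 2], a[i], b[i], theta[i], h, w)
    labels[np] <- i
    sig$nuclei[np] <- si[["nuclei"]] * stats::runif(nrow(np), 0.85, 1.1)
    if (truth_mk$OLIG2[i]) {
      blob <- ellipse_pixels(cents[i, 1], cents[i, 2],
                             0.65 * a[i], 0.65 * b[i], theta[i], h, w)
      sig$OLIG2[blob] <- si[["OLIG2"]] * stats::runif(nrow(blob), 0.85, 1.1)
    }
    for (m in c("NES", "DCX")) {
      if (truth_mk[[m]][i]) {
        nb <- sample(2:5, 1L)
        bp <- branch_pixels(cents[i, 1], cents[i, 2], a[i], b[i], theta[i],
                            h, w, nb)
        if (nrow(bp) > 0)
          sig[[m]][bp] <- si[[m]] * stats::runif(nrow(bp), 0.85, 1.1)
      }
    }
  }

  nsd <- rep_len(spec$noise_sd, 4L)
  names(nsd) <- c("nuclei", "OLIG2", "NES", "DCX")
  img <- lapply(names(sig), function(ch) {
    x <- sig[[ch]] + spec$background + matrix(stats::rnorm(h * w, 0, nsd[[ch]]), h, w)
    x <- pmin(pmax(x, 0), 1)
    # quantise to the nominal bit depth so in-memory and on-file data agree
    q <- 2^spec$bit_depth - 1
    round(x * q) / q
  })
  names(img) <- names(sig)
  attr(img, "channels") <- names(sig)
  attr(img, "bit_depth") <- spec$bit_depth
  class(img) <- "mif_image"

  truth <- data.frame(cell_id = seq_len(n),
                      row = cents[, 1], col = cents[, 2],
                      nucleus_label = seq_len(n),
                      olig2 = truth_mk$OLIG2, nes = truth_mk$NES,
                      dcx = truth_mk$DCX, row.names = NULL)
  list(image = img, labels = labels, truth = truth)
}

#' Write / read a multi-channel field as multi-page TIFF
#'
#' One page per channel, in the order recorded in the `channels` attribute;
#' channel names are stored in a plain-text sidecar `<path>.channels`.
#'
#' @param image A `mif_image` (named list of `[0,1]` intensity matrices).
#' @param path Output path.
#' @return `write_mif_tiff` returns `path` invisibly; `read_mif_tiff` returns
#'   a `mif_image`.
#' @export
write_mif_tiff <- function(image, path) {
  bits <- attr(image, "bit_depth")
  if (is.null(bits)) bits <- 16L
  pages <- lapply(unclass(image)[attr(image, "channels")], identity)
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  writeLines(attr(image, "channels"), paste0(path, ".channels"))
  invisible(path)
}

#' @rdname write_mif_tiff
#' @param channels Channel names when the sidecar file is absent.
#' @export
read_mif_tiff <- function(path, channels = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.null(channels)) {
    sidecar <- paste0(path, ".channels")
    channels <- if (file.exists(sidecar)) readLines(sidecar) else
      paste0("channel", seq_along(pages))
  }
  stopifnot(length(channels) == length(pages))
  img <- lapply(pages, function(p) {
    m <- as.matrix(p)
    attributes(m) <- list(dim = dim(m))
    m
  })
  names(img) <- channels
  attr(img, "channels") <- channels
  attr(img, "bit_depth") <- 16L
  class(img) <- "mif_image"
  img
}
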