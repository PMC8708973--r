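#' Sample random square counting spots from a field
#'
#' Draws up to `n_spots` axis-aligned square windows of side `side` fully
#' inside the image, reproducibly for a given seed. Windows are
#' non-overlapping by default. When `min_cells > 0`, windows whose nuclei
#' count falls below the floor are redrawn up to `max_retries` times and then
#' dropped, so fewer than `n_spots` windows may be returned (spot dropout).
#'
#' @param image A `mif_image` or a `c(height, width)` dimension vector.
#' @param n_spots Number of windows requested.
#' @param side Window side, pixels (600 in the original design).
#' @param seed Integer seed.
#' @param min_cells Minimum detected nuclei per retained window.
#' @param allow_overlap Permit overlapping windows.
#' @param max_retries Redraw budget per window.
#' @param nucleus_params Passed to [detect_nuclei()] when `min_cells > 0`.
#' @return data.frame: `spot_id`, `row0`, `col0` (top-left, 1-based), `side`.
#' @export
sample_spots <- function(image, n_spots = 3L, side = 600L, seed = 1L,
                         min_cells = 0L, allow_overlap = FALSE,
                         max_retries = 50L,
                         nucleus_params = glioquant::nucleus_params()) {
  dm <- if (inherits(image, "mif_image")) dim(image[[1]]) else as.integer(image)
  h <- dm[1]; w <- dm[2]
  if (side > h || side > w)
    stop(sprintf("spot side %d exceeds image dimension %dx%d", side, h, w))
  if (n_spots < 1L) stop("n_spots must be >= 1")
  set.seed(seed)
  taken <- list()
  out <- list()
  overlaps <- function(r0, c0) {
    for (t in taken)
      if (r0 < t[1] + side && t[1] < r0 + side &&
          c0 < t[2] + side && t[2] < c0 + side) return(TRUE)
    FALSE
  }
  for (s in seq_len(n_spots)) {
    found <- FALSE
    for (try in seq_len(max_retries)) {
      r0 <- sample.int(h - side + 1L, 1L)
      c0 <- sample.int(w - side + 1L, 1L)
      if (!allow_overlap && overlaps(r0, c0)) next
      if (min_cells > 0L && inherits(image, "mif_image")) {
        win <- crop_mif(image, r0, c0, side)
        ns <- suppressMessages(detect_nuclei(win$nuclei, nucleus_params))
        if (nrow(ns$table) < min_cells) next
      }
      taken[[length(taken) + 1L]] <- c(r0, c0)
      out[[length(out) + 1L]] <- data.frame(spot_id = length(out) + 1L,
                                            row0 = r0, col0 = c0,
                                            side = as.integer(side))
      found <- TRUE
      break
    }
    if (!found) next  # dropout: "if possible, three ... spots"
  }
  if (!length(out))
    return(data.frame(spot_id = integer(0), row0 = integer(0),
                      col0 = integer(0), side = integer(0)))
  do.call(rbind, out)
}

#' Crop a multi-channel field to a square window
#'
#' @param image A `mif_image`.
#' @param row0,col0 Top-left corner (1-based).
#' @param side Window side, pixels.
#' @return A `mif_image` of the window.
#' @export
crop_mif <- function(image, row0, col0, side) {
  win <- lapply(unclass(image)[attr(image, "channels")],
                function(ch) ch[row0:(row0 + side - 1L),
                                col0:(col0 + side - 1L), drop = FALSE])
  attr(win, "channels") <- attr(image, "channels")
  attr(win, "bit_depth") <- attr(image, "bit_depth")
  class(win) <- "mif_image"
  win
}

marker_combo_columns <- function() {
  c("dcx", "nes", "olig2", "olig2_dcx", "olig2_nes", "nes_dcx",
    "dcx_olig2_nes")
}

# counts of the 7 marker combinations from per-nucleus positivity logicals;
# singles are marginals, pairs/triple are intersections
combo_counts <- function(olig2, nes, dcx) {
  c(dcx = sum(dcx), nes = sum(nes), olig2 = sum(olig2),
    olig2_dcx = sum(olig2 & dcx), olig2_nes = sum(olig2 & nes),
    nes_dcx = sum(nes & dcx), dcx_olig2_nes = sum(olig2 & nes & dcx))
}

#' Quantification parameters for one spot
#'
#' @param nucleus [nucleus_params()] for the Hoechst channel.
#' @param marker_method,marker_thresholds Binarisation method shared by the
#'   three marker channels, and optional named fixed thresholds.
#' @param min_signal_area Minimum marker component area, px.
#' @param min_overlap_fraction OLIG2 overlap rule threshold.
#' @param adjacency_px DCX/NES adjacency dilation radius, px.
#' @return A list of class `quant_params`.
#' @export
quant_params <- function(nucleus = nucleus_params(),
                         marker_method = "otsu",
                         marker_thresholds = NULL,
                         min_signal_area = 5,
                         min_overlap_fraction = 0.1,
                         adjacency_px = 3) {
  structure(list(nucleus = nucleus, marker_method = marker_method,
                 marker_thresholds = marker_thresholds,
                 min_signal_area = min_signal_area,
                 min_overlap_fraction = min_overlap_fraction,
                 adjacency_px = adjacency_px),
            class = "quant_params")
}

#' Quantify marker-positive cells in one spot
#'
#' Composes the full per-spot heuristic: nuclei detection, nuclei-seeded
#' Voronoi tessellation, per-channel marker segmentation, the OLIG2 overlap
#' rule and the DCX/NES adjacency rule; returns counts and frequencies of
#' all seven marker combinations. A spot with zero detected nuclei yields a
#' record with `total_cells = 0` and `NA` frequencies.
#'
#' @param window A `mif_image` (typically a [crop_mif()] window).
#' @param params A [quant_params()].
#' @param spot_id,row0,col0 Identifiers copied into the record.
#' @return A list of class `spot_quantification`: `record` (one-row
#'   data.frame with `total_cells`, `n_*` counts and `freq_*` frequencies),
#'   `positives` (per-marker positive label vectors), `nuclei`, `voronoi`.
#' @export
quantify_spot <- function(window, params = quant_params(), spot_id = 1L,
                          row0 = 1L, col0 = 1L) {
  chans <- attr(window, "channels")
  stopifnot(all(c("nuclei", "OLIG2", "NES", "DCX") %in% chans))
  nuc <- suppressMessages(detect_nuclei(window$nuclei, params$nucleus))
  n <- nrow(nuc$table)
  cols <- marker_combo_columns()
  if (n == 0L) {
    rec <- data.frame(spot_id = spot_id, row0 = row0, col0 = col0,
                      side = nrow(window$nuclei), total_cells = 0L)
    for (cc in cols) rec[[paste0("n_", cc)]] <- 0L
    for (cc in cols) rec[[paste0("freq_", cc)]] <- NA_real_
    return(structure(list(record = rec, positives = NULL, nuclei = nuc,
                          voronoi = NULL),
                     class = "spot_quantification"))
  }
  vor <- build_voronoi(nuc)
  seg <- function(ch) {
    thr <- params$marker_thresholds[[ch]]
    if (identical(params$marker_method, "fixed") || !is.null(thr))
      segment_marker(window[[ch]], "fixed", threshold = thr,
                     min_signal_area = params$min_signal_area)
    else
      suppressWarnings(segment_marker(window[[ch]], "otsu",
                                      min_signal_area = params$min_signal_area))
  }
  pos_olig2 <- call_overlap_marker(nuc, seg("OLIG2"),
                                   params$min_overlap_fraction)
  pos_nes <- call_adjacent_marker(nuc, seg("NES"), params$adjacency_px,
                                  voronoi = vor)
  pos_dcx <- call_adjacent_marker(nuc, seg("DCX"), params$adjacency_px,
                                  voronoi = vor)
  labels <- nuc$table$label
  cnt <- combo_counts(labels %in% pos_olig2, labels %in% pos_nes,
                      labels %in% pos_dcx)
  rec <- data.frame(spot_id = spot_id, row0 = row0, col0 = col0,
                    side = nrow(window$nuclei), total_cells = n)
  for (cc in cols) rec[[paste0("n_", cc)]] <- as.integer(cnt[[cc]])
  for (cc in cols) rec[[paste0("freq_", cc)]] <- cnt[[cc]] / n
  structure(list(record = rec,
                 positives = list(OLIG2 = pos_olig2, NES = pos_nes,
                                  DCX = pos_dcx),
                 nuclei = nuc, voronoi = vor),
            class = "spot_quantification")
}

#' Quantify an image over sampled spots
#'
#' Samples counting windows with [sample_spots()] and quantifies each with
#' [quantify_spot()].
#'
#' @param image A `mif_image`.
#' @param n_spots,side,seed,min_cells Passed to [sample_spots()].
#' @param params A [quant_params()].
#' @param image_id Identifier copied into every record.
#' @return data.frame of per-spot records (one row per spot).
#' @export
quantify_image <- function(image, n_spots = 3L, side = 600L, seed = 1L,
                           params = quant_params(), min_cells = 0L,
                           image_id = "image1") {
  spots <- sample_spots(image, n_spots = n_spots, side = side, seed = seed,
                        min_cells = min_cells,
                        nucleus_params = params$nucleus)
  recs <- lapply(seq_len(nrow(spots)), function(i) {
    win <- crop_mif(image, spots$row0[i], spots$col0[i], spots$side[i])
    quantify_spot(win, params, spot_id = spots$spot_id[i],
                  row0 = spots$row0[i], col0 = spots$col0[i])$record
  })
  out <- if (length(recs)) do.call(rbind, recs) else
    quantify_spot(crop_mif(image, 1L, 1L, min(dim(image[[1]]))),
                  params)$record[0, ]
  cbind(data.frame(image_id = image_id), out)
}
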