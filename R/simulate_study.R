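#' Tissue categories used for ROI classification
#'
#' The closed set of tissue-origin categories: tumour margin, tumour adjacent
#' to the margin, tumour without margin context ("other"), and lower-grade
#' (non-GBM) tumour.
#' @export
tissue_categories <- function() {
  c("margin", "tumour_adjacent_to_margin", "tumour_other", "tumour_non_gbm")
}

#' Specification for a synthetic multi-case imaging study
#'
#' Emulates the shape of a clinical IF study: cases with up to three
#' sequential resections, ROIs classified by tissue category, and up to
#' three counting spots per ROI. Per-spot true marker frequencies are drawn
#' from per-category Beta distributions so that downstream site comparisons
#' have a known effect structure.
#'
#' @param n_cases Number of cases (default 17).
#' @param resections_per_case Integer vector recycled over cases: how many
#'   sequential resections each case contributes (1-3).
#' @param rois_per_tissue_category Named counts of ROIs per category drawn
#'   per resection (a total of about 60 ROIs in the default study).
#' @param true_frequency_effects data.frame with columns `category`,
#'   `marker`, `mean`, `dispersion`: per-category Beta mean and precision of
#'   the true per-spot frequency of each marker. The defaults place DCX low
#'   everywhere, OLIG2 enriched in the margin and NES enriched in tumour —
#'   the qualitative pattern the site comparisons are designed to detect.
#' @param total_cells_mean Named per-category mean of the per-spot cell
#'   count (margin fields are sparser than tumour fields).
#' @param spots_per_roi Spots per ROI (<= 3).
#' @param dropout_prob Probability that a spot is unusable and dropped.
#' @param seed Integer seed.
#' @return An object of class `study_sim_spec`.
#' @export
study_sim_spec <- function(n_cases = 17L,
                           resections_per_case = c(3L, 2L, 2L, 1L),
                           rois_per_tissue_category = c(
                             margin = 1L, tumour_adjacent_to_margin = 1L,
                             tumour_other = 1L, tumour_non_gbm = 0L),
                           true_frequency_effects = default_frequency_effects(),
                           total_cells_mean = c(
                             margin = 150, tumour_adjacent_to_margin = 280,
                             tumour_other = 300, tumour_non_gbm = 250),
                           spots_per_roi = 3L,
                           dropout_prob = 0.15,
                           seed = 1L) {
  spec <- list(n_cases = as.integer(n_cases),
               resections_per_case = as.integer(resections_per_case),
               rois_per_tissue_category = rois_per_tissue_category,
               true_frequency_effects = true_frequency_effects,
               total_cells_mean = total_cells_mean,
               spots_per_roi = as.integer(spots_per_roi),
               dropout_prob = dropout_prob,
               seed = as.integer(seed))
  class(spec) <- "study_sim_spec"
  validate_study_sim_spec(spec)
  spec
}

#' @rdname study_sim_spec
#' @export
default_frequency_effects <- function() {
  cats <- tissue_categories()
  # means follow the reported qualitative pattern: DCX rare everywhere,
  # OLIG2 highest in margin, NES abundant and highest inside tumour
  means <- rbind(dcx   = c(0.031, 0.011, 0.020, 0.015),
                 olig2 = c(0.198, 0.051, 0.082, 0.070),
                 nes   = c(0.177, 0.206, 0.254, 0.150))
  colnames(means) <- cats
  out <- expand.grid(category = cats, marker = rownames(means),
                     stringsAsFactors = FALSE)
  out$mean <- mapply(function(ct, mk) means[mk, ct], out$category, out$marker)
  out$dispersion <- 30
  out
}

validate_study_sim_spec <- function(spec) {
  stopifnot(inherits(spec, "study_sim_spec"))
  if (spec$n_cases < 1L) stop("n_cases must be >= 1")
  if (any(spec$resections_per_case < 1L | spec$resections_per_case > 3L))
    stop("resections_per_case must lie in 1..3")
  bad <- setdiff(names(spec$rois_per_tissue_category), tissue_categories())
  if (length(bad))
    stop("unknown tissue categories: ", paste(bad, collapse = ", "))
  if (spec$spots_per_roi < 1L || spec$spots_per_roi > 3L)
    stop("spots_per_roi must lie in 1..3")
  e <- spec$true_frequency_effects
  stopifnot(all(c("category", "marker", "mean", "dispersion") %in% names(e)))
  if (any(e$mean <= 0 | e$mean >= 1)) stop("effect means must lie in (0, 1)")
  invisible(spec)
}

#' Generate a synthetic study table of ROIs and spots
#'
#' Every ROI carries a case id, resection number and tissue category; every
#' retained spot carries its true marker frequencies (drawn from the
#' category's Beta effect distribution, shared across a ROI's spots up to
#' spot-level Beta noise) and realised marker-positive counts out of the
#' spot's cell count. Spots are lost independently with `dropout_prob`
#' (mirroring unusable fields), so the realised spot count is at most
#' ROIs x `spots_per_roi`.
#'
#' @param spec A [study_sim_spec()].
#' @return A list with `rois` (one row per ROI: `roi_id`, `case_id`,
#'   `resection`, `category`, `image_id`) and `spots` (one row per retained
#'   spot with `image_id`, `total_cells`, per-marker `freq_*` — realised
#'   frequencies — and `true_*` — the ROI-level true frequencies).
#' @export
generate_study <- function(spec) {
  validate_study_sim_spec(spec)
  set.seed(spec$seed)
  eff <- spec$true_frequency_effects
  res_per_case <- rep_len(spec$resections_per_case, spec$n_cases)
  cat_counts <- spec$rois_per_tissue_category
  cats <- rep(names(cat_counts), unlist(cat_counts))
  k_in_cat <- unlist(lapply(unlist(cat_counts), seq_len), use.names = FALSE)
  if (!length(cats)) stop("no ROIs requested")

  # one row per ROI: every (case, resection) carries the requested category mix
  per_case <- lapply(seq_len(spec$n_cases), function(ci)
    data.frame(case_id = sprintf("case%02d", ci),
               resection = rep(seq_len(res_per_case[ci]), each = length(cats)),
               category = rep(cats, res_per_case[ci]),
               k = rep(k_in_cat, res_per_case[ci])))
  rois <- do.call(rbind, per_case)
  rois <- cbind(roi_id = seq_len(nrow(rois)), rois)
  rois$image_id <- sprintf("%s_r%d_%s_%d", rois$case_id, rois$resection,
                           rois$category, rois$k)
  rois$k <- NULL

  # ROI-level true frequencies from each category's Beta effect distribution
  tr <- sapply(c("dcx", "olig2", "nes"), function(mk) {
    e <- eff[eff$marker == mk, ]
    mu <- e$mean[match(rois$category, e$category)]
    phi <- e$dispersion[match(rois$category, e$category)]
    stats::rbeta(nrow(rois), mu * phi, (1 - mu) * phi)
  })
  if (is.null(dim(tr)))
    tr <- matrix(tr, nrow = 1, dimnames = list(NULL, names(tr)))

  # spots: replicate ROIs, apply dropout, draw cell counts and positives
  sp_roi <- rep(seq_len(nrow(rois)), each = spec$spots_per_roi)
  spot_id <- rep(seq_len(spec$spots_per_roi), nrow(rois))
  keep <- stats::runif(length(sp_roi)) >= spec$dropout_prob
  n_cells <- stats::rpois(length(sp_roi),
                          spec$total_cells_mean[rois$category[sp_roi]])
  keep <- keep & n_cells > 0
  sp_roi <- sp_roi[keep]; spot_id <- spot_id[keep]; n_cells <- n_cells[keep]
  spots <- NULL
  if (length(sp_roi)) {
    pos <- sapply(c("dcx", "olig2", "nes"), function(mk)
      stats::rbinom(length(sp_roi), n_cells, tr[sp_roi, mk]))
    if (is.null(dim(pos)))
      pos <- matrix(pos, nrow = 1, dimnames = list(NULL, names(pos)))
    spots <- data.frame(image_id = rois$image_id[sp_roi], spot_id = spot_id,
                        total_cells = n_cells,
                        freq_dcx = pos[, "dcx"] / n_cells,
                        freq_olig2 = pos[, "olig2"] / n_cells,
                        freq_nes = pos[, "nes"] / n_cells,
                        true_dcx = tr[sp_roi, "dcx"],
                        true_olig2 = tr[sp_roi, "olig2"],
                        true_nes = tr[sp_roi, "nes"])
  }
  list(rois = rois, spots = spots)
}
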