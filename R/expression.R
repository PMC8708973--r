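#' Per-cell QC metrics
#'
#' Adds (or recomputes) `total_umis`, `genes_detected` and `mito_fraction`
#' in `colData`, derived from the `counts` assay and the `is_mito` gene flag.
#'
#' @param sce A `SingleCellExperiment` with a `counts` assay and an
#'   `is_mito` column in `rowData`.
#' @return The `SingleCellExperiment` with QC columns set.
#' @export
compute_qc <- function(sce) {
  counts <- SummarizedExperiment::assay(sce, "counts")
  rd <- SummarizedExperiment::rowData(sce)
  if (is.null(rd$is_mito))
    stop("rowData(sce)$is_mito is required to compute the mitochondrial fraction")
  tot <- Matrix::colSums(counts)
  det <- Matrix::colSums(counts > 0)
  mito <- Matrix::colSums(counts[rd$is_mito, , drop = FALSE])
  sce$total_umis <- as.numeric(tot)
  sce$genes_detected <- as.integer(det)
  sce$mito_fraction <- as.numeric(ifelse(tot > 0, mito / tot, 0))
  sce
}

#' Quality-control filter for single cells
#'
#' Retains exactly the cells with total UMIs > 1000, genes detected strictly
#' between 500 and 5000, and mitochondrial fraction < 10% (all bounds
#' strict). Genes are untouched. Idempotent.
#'
#' @param sce A `SingleCellExperiment`; QC columns are recomputed from
#'   counts before filtering.
#' @param min_umis,min_genes,max_genes,max_mito The strict bounds.
#' @return The filtered `SingleCellExperiment`.
#' @export
qc_filter <- function(sce, min_umis = 1000, min_genes = 500,
                      max_genes = 5000, max_mito = 0.10) {
  sce <- compute_qc(sce)
  keep <- sce$total_umis > min_umis &
    sce$genes_detected > min_genes & sce$genes_detected < max_genes &
    sce$mito_fraction < max_mito
  sce[, keep]
}

#' Uniformly downsample cells without replacement
#'
#' @param sce A `SingleCellExperiment`.
#' @param n Number of cells to keep (default 15000); if `n` is not smaller
#'   than the available cells, all are returned with a warning.
#' @param seed Integer seed.
#' @return The downsampled `SingleCellExperiment` (original column order).
#' @export
downsample_cells <- function(sce, n = 15000L, seed = 1L) {
  if (n >= ncol(sce)) {
    if (n > ncol(sce))
      warning(sprintf("requested %d cells but only %d available; returning all",
                      n, ncol(sce)))
    return(sce)
  }
  set.seed(seed)
  sce[, sort(sample.int(ncol(sce), n))]
}

#' Library-size log-normalisation
#'
#' `value = ln(1 + scale * count / cell_total)` per cell, stored as assay
#' `lognorm`. Per cell, `sum(exp(value) - 1) == scale` exactly.
#'
#' @param sce A `SingleCellExperiment` with non-negative counts.
#' @param scale Scale factor (default 10000).
#' @return The `SingleCellExperiment` with a `lognorm` assay added.
#' @export
log_normalize <- function(sce, scale = 1e4) {
  counts <- SummarizedExperiment::assay(sce, "counts")
  tot <- Matrix::colSums(counts)
  if (any(tot == 0))
    stop("log_normalize: cell(s) with zero total counts (run qc_filter first)")
  norm <- counts %*% Matrix::Diagonal(x = scale / tot)
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(counts)
  SummarizedExperiment::assay(sce, "lognorm") <- norm
  sce
}

# Pull the lognorm assay as a genes x cells sparse matrix from an SCE or
# pass a plain matrix through.
as_norm_matrix <- function(x) {
  if (methods::is(x, "SingleCellExperiment")) {
    if (!"lognorm" %in% SummarizedExperiment::assayNames(x))
      stop("run log_normalize() first: no 'lognorm' assay")
    SummarizedExperiment::assay(x, "lognorm")
  } else x
}
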