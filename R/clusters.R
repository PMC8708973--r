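#' Cluster cells on top principal components
#'
#' A standard, deterministic clustering stage: select the most variable
#' genes, scale, project onto the leading principal components and run
#' k-means. The contract is determinism given the seed and dense labels
#' `0..K-1`; the choice of k-means over graph methods is incidental.
#'
#' @param x A `SingleCellExperiment` with a `lognorm` assay, or a genes x
#'   cells normalized matrix.
#' @param k Number of clusters.
#' @param n_hvg Number of highest-variance genes used.
#' @param n_pcs Number of principal components.
#' @param seed Integer seed.
#' @return Integer vector of cluster labels `0..k-1`, one per cell.
#' @export
cluster_cells <- function(x, k = 8L, n_hvg = 1000L, n_pcs = 15L, seed = 1L) {
  mat <- as_norm_matrix(x)
  if (ncol(mat) < 2L) stop("need at least 2 cells to cluster")
  k <- min(k, ncol(mat))
  v <- rowVars_sparse(mat)
  hv <- order(v, decreasing = TRUE)[seq_len(min(n_hvg, nrow(mat)))]
  m <- t(as.matrix(mat[hv, , drop = FALSE]))
  m <- scale(m)
  m[, !is.finite(colSums(m))] <- 0
  n_pcs <- min(n_pcs, ncol(m), nrow(m) - 1L)
  set.seed(seed)
  pcs <- stats::prcomp(m, rank. = n_pcs)$x
  km <- stats::kmeans(pcs, centers = k, nstart = 10L, iter.max = 100L)
  # relabel to dense 0..K-1 in order of first appearance for determinism
  first <- order(match(seq_len(k), km$cluster))
  relab <- integer(k); relab[first] <- seq_len(k) - 1L
  unname(relab[km$cluster])
}

rowVars_sparse <- function(m) {
  mu <- Matrix::rowMeans(m)
  Matrix::rowMeans(m^2) - mu^2
}

#' Per-cluster marker summaries stratified by malignancy status
#'
#' For every cluster x status stratum: the arithmetic mean of normalized
#' expression of each requested marker gene, the stratum size, and its
#' fraction of the cluster (composition fractions sum to 1 per cluster).
#'
#' @param x A `SingleCellExperiment` with a `lognorm` assay, or a genes x
#'   cells normalized matrix.
#' @param labels Cluster labels, one per cell.
#' @param status Per-cell status (e.g. `cancer` / `normal`), one per cell.
#' @param markers Marker gene identifiers (must exist in rownames).
#' @return data.frame: `cluster`, `status`, `n_cells`,
#'   `fraction_of_cluster`, then one `mean_<gene>` column per marker.
#' @export
summarize_clusters <- function(x, labels, status, markers) {
  mat <- as_norm_matrix(x)
  stopifnot(length(labels) == ncol(mat), length(status) == ncol(mat))
  missing <- setdiff(markers, rownames(mat))
  if (length(missing))
    stop("unknown marker gene id(s): ", paste(missing, collapse = ", "))
  mm <- as.matrix(mat[markers, , drop = FALSE])
  key <- interaction(labels, status, drop = TRUE)
  out <- do.call(rbind, lapply(levels(key), function(lv) {
    idx <- which(key == lv)
    d <- data.frame(cluster = labels[idx[1]], status = status[idx[1]],
                    n_cells = length(idx))
    for (g in markers)
      d[[paste0("mean_", g)]] <- mean(mm[g, idx])
    d
  }))
  csize <- tapply(rep(1, length(labels)), labels, sum)
  out$fraction_of_cluster <- out$n_cells / as.numeric(csize[as.character(out$cluster)])
  out <- out[order(out$cluster, out$status),
             c("cluster", "status", "n_cells", "fraction_of_cluster",
               paste0("mean_", markers))]
  rownames(out) <- NULL
  out
}

#' Pairwise Spearman correlations between marker genes
#'
#' Rank correlation (average ranks for ties) with a two-sided p-value over a
#' cell subset, reported for every marker pair. A constant gene yields `NA`
#' with a warning.
#'
#' @param x A `SingleCellExperiment` with a `lognorm` assay, or a genes x
#'   cells normalized matrix.
#' @param markers Marker gene identifiers.
#' @param cells Optional cell subset (names or indices); default all.
#' @return data.frame: `gene_a`, `gene_b`, `rho`, `p_value`, `n`.
#' @export
marker_correlations <- function(x, markers, cells = NULL) {
  mat <- as_norm_matrix(x)
  missing <- setdiff(markers, rownames(mat))
  if (length(missing))
    stop("unknown marker gene id(s): ", paste(missing, collapse = ", "))
  if (!is.null(cells)) mat <- mat[, cells, drop = FALSE]
  if (ncol(mat) < 3L) stop("need at least 3 cells")
  mm <- as.matrix(mat[markers, , drop = FALSE])
  prs <- utils::combn(markers, 2L)
  out <- do.call(rbind, lapply(seq_len(ncol(prs)), function(i) {
    a <- mm[prs[1, i], ]; b <- mm[prs[2, i], ]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      warning(sprintf("constant gene in pair %s vs %s; correlation undefined",
                      prs[1, i], prs[2, i]))
      return(data.frame(gene_a = prs[1, i], gene_b = prs[2, i],
                        rho = NA_real_, p_value = NA_real_, n = length(a)))
    }
    ct <- suppressWarnings(stats::cor.test(a, b, method = "spearman",
                                           exact = FALSE))
    data.frame(gene_a = prs[1, i], gene_b = prs[2, i],
               rho = unname(ct$estimate), p_value = ct$p.value,
               n = length(a))
  }))
  rownames(out) <- NULL
  out
}

#' Marker-score cluster annotation (stand-in utility)
#'
#' A deliberately simple stand-in for reference-database cell-type
#' annotation: each cluster is labelled by the marker set with the highest
#' mean z-scored expression. Intended for exploration and labelling of
#' synthetic data, not as a validated cell-typing method.
#'
#' @param x A `SingleCellExperiment` with a `lognorm` assay, or a genes x
#'   cells normalized matrix.
#' @param labels Cluster labels, one per cell.
#' @param marker_sets Named list of character vectors of gene ids.
#' @return data.frame: `cluster`, `label`, `score`.
#' @export
annotate_by_markers <- function(x, labels, marker_sets) {
  mat <- as_norm_matrix(x)
  genes <- unique(unlist(marker_sets))
  missing <- setdiff(genes, rownames(mat))
  if (length(missing))
    stop("unknown marker gene id(s): ", paste(missing, collapse = ", "))
  mm <- as.matrix(mat[genes, , drop = FALSE])
  z <- t(scale(t(mm)))
  z[!is.finite(z)] <- 0
  out <- do.call(rbind, lapply(sort(unique(labels)), function(cl) {
    idx <- labels == cl
    sc <- vapply(marker_sets,
                 function(gs) mean(z[gs, idx, drop = FALSE]), numeric(1))
    data.frame(cluster = cl, label = names(which.max(sc)),
               score = max(sc))
  }))
  rownames(out) <- NULL
  out
}
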