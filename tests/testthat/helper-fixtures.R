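# Shared fixtures and independent oracles for the test suite.

# marker_mask from a 0/1 matrix through the public fixed-threshold path
as_marker_mask <- function(m, min_signal_area = 1) {
  segment_marker(m * 1, method = "fixed", threshold = 0.5,
                 min_signal_area = min_signal_area)
}

# Exhaustive nearest-centroid scan: full pixel x seed distance matrix,
# argmin per pixel, ties to the lowest seed index.
voronoi_oracle <- function(seeds, h, w) {
  pr <- rep(seq_len(h), times = w)
  pc <- rep(seq_len(w), each = h)
  D <- outer(pr, seeds[, 1], "-")^2 + outer(pc, seeds[, 2], "-")^2
  matrix(max.col(-D, ties.method = "first"), h, w)
}

# Exact two-sided rank-sum p by enumeration of all rank assignments
# (doubled smaller tail including the observed value, capped at 1).
ranksum_enum_p <- function(x, y) {
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  idx <- utils::combn(m + n, m)
  ws <- apply(idx, 2, function(i) sum(r[i])) - m * (m + 1) / 2
  pl <- mean(ws <= w_obs); pu <- mean(ws >= w_obs)
  min(1, 2 * min(pl, pu))
}

# Exact two-sided signed-rank p by enumeration of all sign patterns
# (zero differences dropped before ranking, as in the implementation).
signedrank_enum_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.vector(signs %*% r)
  pl <- mean(vs <= v_obs); pu <- mean(vs >= v_obs)
  min(1, 2 * min(pl, pu))
}

# Kruskal-Wallis H from the direct rank formula with tie correction.
kruskal_H_oracle <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, groups, function(ri) length(ri) * mean(ri)^2)) -
    3 * (N + 1)
  ties <- table(values)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# 500-cell matrix with exactly 10 planted violators of each QC rule
# (30 distinct cells) built by deterministic surgery on a generated set.
qc_violator_fixture <- function(seed = 42L) {
  spec <- expr_sim_spec(n_cells = 500L, n_genes = 800L,
                        n_reference_cells = 0L, cancer_fraction = 0,
                        libsize_lognormal = c(mu = log(6000), sigma = 0.2),
                        mito_beta = c(2, 60), seed = seed)
  sce <- generate_expression_matrix(spec)
  counts <- as.matrix(SummarizedExperiment::assay(sce, "counts"))
  is_mito <- SummarizedExperiment::rowData(sce)$is_mito
  # cap natural mito tails so the base population passes every rule
  mf <- colSums(counts[is_mito, ]) / colSums(counts)
  for (j in which(mf > 0.08))
    counts[is_mito, j] <- floor(counts[is_mito, j] * 0.05 / mf[j])
  stopifnot(all(colSums(counts) > 1000),
            all(colSums(counts > 0) > 500 & colSums(counts > 0) < 5000),
            all(colSums(counts[is_mito, ]) / colSums(counts) < 0.10))
  low_umi <- 1:10; low_genes <- 11:20; high_mito <- 21:30
  for (j in low_umi) {                     # exactly 1000 total UMIs (strict >)
    x <- counts[, j]
    nz <- which(x > 0)
    x <- round(x * 900 / sum(x))
    excess <- sum(x) - 1000
    adj <- order(x, decreasing = TRUE)[seq_len(abs(excess))]
    x[adj] <- x[adj] - sign(excess)
    counts[, j] <- pmax(x, 0)
    stopifnot(sum(counts[, j]) == 1000)
  }
  for (j in low_genes) {                   # exactly 500 genes detected
    x <- counts[, j]
    nz <- which(x > 0)
    drop <- nz[-seq_len(500)]
    keep500 <- nz[seq_len(500)]
    x[drop] <- 0
    x[keep500[1]] <- x[keep500[1]] + 600   # keep UMIs comfortably above 1000
    counts[, j] <- x
    stopifnot(sum(counts[, j] > 0) == 500, sum(counts[, j]) > 1000)
  }
  for (j in high_mito) {                   # mito fraction >= 0.10
    x <- counts[, j]
    target <- ceiling(0.12 * sum(x[!is_mito]) / 0.88)
    mt <- which(is_mito)
    x[mt] <- 0
    x[mt[1]] <- target
    counts[, j] <- x
    stopifnot(sum(x[is_mito]) / sum(x) >= 0.10)
  }
  out <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = methods::as(counts, "CsparseMatrix")),
    rowData = SummarizedExperiment::rowData(sce),
    colData = SummarizedExperiment::colData(sce))
  list(sce = compute_qc(out), violators = 1:30)
}

# Small null frequency tables drawn at the post-averaging level: iid Beta
# frequencies with no group effect, used for type-I calibration.
null_table_two_groups <- function(n_per_group = 16L) {
  data.frame(case_id = sprintf("c%02d", seq_len(2 * n_per_group)),
             resection = 1L,
             category = rep(c("margin", "tumour_adjacent_to_margin"),
                            each = n_per_group),
             freq = stats::rbeta(2 * n_per_group, 2, 18))
}

null_table_paired <- function(n_cases = 16L) {
  data.frame(case_id = rep(sprintf("c%02d", seq_len(n_cases)), 2),
             resection = 1L,
             category = rep(c("margin", "tumour_adjacent_to_margin"),
                            each = n_cases),
             freq = stats::rbeta(2 * n_cases, 2, 18))
}

null_table_resections <- function(n_per_group = 16L) {
  data.frame(case_id = sprintf("c%02d", seq_len(3 * n_per_group)),
             resection = rep(1:3, each = n_per_group),
             category = "tumour_other",
             freq = stats::rbeta(3 * n_per_group, 2, 18))
}

# Match detected nuclei to ground-truth cells by nearest centroid.
match_nuclei_to_truth <- function(nuc_table, truth) {
  vapply(seq_len(nrow(nuc_table)), function(i)
    which.min((truth$row - nuc_table$row[i])^2 +
                (truth$col - nuc_table$col[i])^2), integer(1))
}
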