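#' Specification for a synthetic single-cell UMI count matrix
#'
#' Describes a tumour population (a "cancer" subset carrying a chromosome-7
#' expression gain and a chromosome-10 loss, plus "normal" cells) and a
#' separate aberration-free "reference" population standing in for foetal
#' brain cells. Counts are Poisson with per-gene Gamma-distributed rates
#' (negative-binomial marginals); per-cell totals follow a lognormal library
#' size; the aggregate mitochondrial share per cell is Beta-distributed.
#'
#' @param n_cells Tumour cells (cancer + normal).
#' @param n_genes Total genes, including the mitochondrial block (the first
#'   `ceiling(0.01 * n_genes)` genes, named `MT-*` and placed on chromosome
#'   `"MT"`); the rest are split as evenly as possible over
#'   `n_chromosomes` autosomes `chr1..chrN`.
#' @param n_chromosomes Number of autosomes carrying the non-MT genes.
#' @param cancer_fraction Fraction of tumour cells that are cancer;
#'   `round(cancer_fraction * n_cells)` cells are labelled cancer.
#' @param chr7_gain_factor Multiplicative fold (>= 1) on chromosome-7 gene
#'   means in cancer cells.
#' @param chr10_loss_factor Multiplicative fold in `(0, 1]` on chromosome-10
#'   gene means in cancer cells.
#' @param libsize_lognormal `c(mu, sigma)` of the per-cell expected total
#'   UMI count on the log scale.
#' @param mito_beta `c(a, b)` Beta parameters of the per-cell mitochondrial
#'   fraction.
#' @param n_reference_cells Aberration-free reference cells appended after
#'   the tumour cells.
#' @param marker_gene_ids Names given to the three marker genes standing for
#'   DCX, OLIG2 and NES (placed on chromosome 1, high-expressed).
#' @param marker_correlation Target Spearman correlation among the marker
#'   genes within cancer cells, induced through a Gaussian copula on
#'   per-cell marker abundance multipliers.
#' @param nb_dispersion Gamma shape of the per-cell-per-gene rate noise
#'   (negative-binomial size).
#' @param seed Integer seed.
#' @return An object of class `expr_sim_spec`.
#' @export
expr_sim_spec <- function(n_cells = 2000L, n_genes = 3333L,
                          n_chromosomes = 22L, cancer_fraction = 0.40,
                          chr7_gain_factor = 1.5, chr10_loss_factor = 0.5,
                          libsize_lognormal = c(mu = log(8000), sigma = 0.35),
                          mito_beta = c(a = 2, b = 38),
                          n_reference_cells = 300L,
                          marker_gene_ids = c(DCX = "DCX", OLIG2 = "OLIG2",
                                              NES = "NES"),
                          marker_correlation = 0.3,
                          nb_dispersion = 2,
                          seed = 1L) {
  spec <- list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
               n_chromosomes = as.integer(n_chromosomes),
               cancer_fraction = cancer_fraction,
               chr7_gain_factor = chr7_gain_factor,
               chr10_loss_factor = chr10_loss_factor,
               libsize_lognormal = libsize_lognormal,
               mito_beta = mito_beta,
               n_reference_cells = as.integer(n_reference_cells),
               marker_gene_ids = marker_gene_ids,
               marker_correlation = marker_correlation,
               nb_dispersion = nb_dispersion,
               seed = as.integer(seed))
  class(spec) <- "expr_sim_spec"
  validate_expr_sim_spec(spec)
  spec
}

validate_expr_sim_spec <- function(spec) {
  stopifnot(inherits(spec, "expr_sim_spec"))
  if (spec$n_genes < spec$n_chromosomes)
    stop("n_genes must be >= n_chromosomes")
  if (spec$cancer_fraction < 0 || spec$cancer_fraction > 1)
    stop("cancer_fraction must lie in [0, 1]")
  if (spec$chr7_gain_factor < 1)
    stop("chr7_gain_factor must be >= 1")
  if (spec$chr10_loss_factor <= 0 || spec$chr10_loss_factor > 1)
    stop("chr10_loss_factor must lie in (0, 1]")
  if (spec$n_chromosomes < 10)
    stop("need at least 10 autosomes so chr7 and chr10 exist")
  invisible(spec)
}

#' Generate a ground-truthed synthetic UMI count matrix
#'
#' @param spec An [expr_sim_spec()].
#' @return A [SingleCellExperiment::SingleCellExperiment] with sparse integer
#'   assay `counts`; `rowData` columns `gene_id`, `chromosome`, `start`,
#'   `is_mito`; `colData` columns `barcode` and `truth_label`
#'   (`cancer` / `normal` / `reference`). Cancer cells' chromosome-7 gene
#'   expectations are multiplied by `chr7_gain_factor` and chromosome-10 by
#'   `chr10_loss_factor` before count sampling; reference cells carry no
#'   aberration.
#' @export
generate_expression_matrix <- function(spec) {
  validate_expr_sim_spec(spec)
  set.seed(spec$seed)
  n_mito <- as.integer(ceiling(0.01 * spec$n_genes))
  n_auto <- spec$n_genes - n_mito
  chr_sizes <- diff(round(seq(0, n_auto, length.out = spec$n_chromosomes + 1)))
  chrom <- c(rep("MT", n_mito),
             rep(paste0("chr", seq_len(spec$n_chromosomes)), chr_sizes))
  start <- c(seq_len(n_mito), unlist(lapply(chr_sizes, seq_len))) * 1000L
  gene_id <- character(spec$n_genes)
  gene_id[seq_len(n_mito)] <- sprintf("MT-%03d", seq_len(n_mito))
  gene_id[(n_mito + 1L):spec$n_genes] <-
    sprintf("G%05d", seq_len(n_auto))

  # three marker genes on chr1, high-expressed so rank structure survives
  # Poisson sampling
  chr1_idx <- which(chrom == "chr1")
  mk_idx <- chr1_idx[seq_len(3L)]
  gene_id[mk_idx] <- unname(spec$marker_gene_ids[c("DCX", "OLIG2", "NES")])

  n_tum <- spec$n_cells
  n_ref <- spec$n_reference_cells
  n_all <- n_tum + n_ref
  n_cancer <- as.integer(round(spec$cancer_fraction * n_tum))
  truth <- c(rep("cancer", n_cancer), rep("normal", n_tum - n_cancer),
             rep("reference", n_ref))

  # per-gene base relative abundance (Gamma across genes, heavy-ish tail)
  base <- stats::rgamma(spec$n_genes, shape = 0.9, scale = 1) + 0.05
  # marker genes: high-expressed but a small library share, so one marker's
  # abundance spike cannot depress the others through normalisation
  base[mk_idx] <- stats::quantile(base, 0.99) * c(0.8, 1.0, 1.2)

  libsize <- stats::rlnorm(n_all, spec$libsize_lognormal[[1]],
                           spec$libsize_lognormal[[2]])
  mito_frac <- stats::rbeta(n_all, spec$mito_beta[[1]], spec$mito_beta[[2]])

  is_cancer <- truth == "cancer"
  i7 <- chrom == "chr7"; i10 <- chrom == "chr10"
  disp <- spec$nb_dispersion
  cols <- vector("list", n_all)
  mk_lam0 <- matrix(0, n_all, 3L)   # marker rate at unit multiplier
  for (c_i in seq_len(n_all)) {
    w <- base * stats::rgamma(spec$n_genes, shape = disp, scale = 1 / disp)
    if (is_cancer[c_i]) {
      w[i7] <- w[i7] * spec$chr7_gain_factor
      w[i10] <- w[i10] * spec$chr10_loss_factor
    }
    w[mk_idx] <- base[mk_idx]
    # impose the drawn mitochondrial share, then the library size
    m <- mito_frac[c_i]
    smt <- sum(w[seq_len(n_mito)]); sau <- sum(w[-seq_len(n_mito)])
    w[seq_len(n_mito)] <- w[seq_len(n_mito)] / smt * m
    w[-seq_len(n_mito)] <- w[-seq_len(n_mito)] / sau * (1 - m)
    lam <- w * libsize[c_i]
    mk_lam0[c_i, ] <- lam[mk_idx]
    x <- stats::rpois(spec$n_genes, lam)
    nz <- which(x > 0)
    cols[[c_i]] <- list(i = nz, x = x[nz])
  }
  nnz <- vapply(cols, function(z) length(z$i), integer(1))
  counts <- Matrix::sparseMatrix(
    i = unlist(lapply(cols, `[[`, "i")),
    j = rep.int(seq_len(n_all), nnz),
    x = unlist(lapply(cols, `[[`, "x")),
    dims = c(spec$n_genes, n_all))
  counts <- draw_marker_counts(counts, mk_idx, mk_lam0, n_cancer,
                               spec$marker_correlation)
  rownames(counts) <- gene_id
  barcodes <- sprintf("CELL-%05d", seq_len(n_all))
  colnames(counts) <- barcodes

  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(gene_id = gene_id, chromosome = chrom,
                                   start = start,
                                   is_mito = seq_len(spec$n_genes) <= n_mito),
    colData = S4Vectors::DataFrame(barcode = barcodes, truth_label = truth))
  compute_qc(sce)
}

# Final marker-count draw with NORTA-style calibration: lognormal abundance
# multipliers are coupled through a Gaussian copula among cancer cells, and
# the latent correlation is iteratively adjusted so that the library-size-
# normalized log counts of the emitted cells hit the requested Spearman
# correlation (the output channel -- Poisson sampling plus normalisation --
# attenuates any latent correlation, so solving for the latent value is the
# only way the generator can honour its stated target).
draw_marker_counts <- function(counts, mk_idx, mk_lam0, n_cancer, rho_target,
                               sig_m = 0.9, n_iter = 3L) {
  n_all <- ncol(counts)
  base_tot <- Matrix::colSums(counts) - Matrix::colSums(counts[mk_idx, ,
                                                               drop = FALSE])
  # independent multipliers for non-cancer cells, drawn once
  mult <- matrix(stats::rlnorm(n_all * 3L, -sig_m^2 / 2, sig_m), n_all, 3L)
  draw <- function(rho_lat) {
    m <- mult
    if (n_cancer > 0 && rho_lat != 0) {
      S <- matrix(rho_lat, 3, 3); diag(S) <- 1
      Z <- matrix(stats::rnorm(n_cancer * 3L), n_cancer, 3L) %*% chol(S)
      m[seq_len(n_cancer), ] <- exp(sig_m * Z - sig_m^2 / 2)
    }
    x <- matrix(stats::rpois(n_all * 3L, as.vector(mk_lam0 * m)), n_all, 3L)
    x
  }
  rho_lat <- 2 * sin(pi * rho_target / 6)   # bivariate-normal inversion
  x <- draw(rho_lat)
  if (n_cancer >= 200 && rho_target != 0) {
    for (it in seq_len(n_iter)) {
      tot <- base_tot + rowSums(x)
      v <- log1p(1e4 * x[seq_len(n_cancer), ] / tot[seq_len(n_cancer)])
      obs <- mean(c(stats::cor(v[, 1], v[, 2], method = "spearman"),
                    stats::cor(v[, 1], v[, 3], method = "spearman"),
                    stats::cor(v[, 2], v[, 3], method = "spearman")))
      if (abs(obs - rho_target) < 0.005) break
      rho_lat <- min(max(rho_lat + (rho_target - obs), -0.9), 0.9)
      x <- draw(rho_lat)
    }
  }
  counts[mk_idx, ] <- t(x)
  Matrix::drop0(counts)
}

#' Write / read an expression set as MatrixMarket MTX plus TSV sidecars
#'
#' `genes.tsv` carries `gene_id`, `chromosome`, `start`, `is_mito`;
#' `barcodes.tsv` carries `barcode` and any further cell annotations.
#'
#' @param sce A `SingleCellExperiment` with a `counts` assay.
#' @param dir Output directory (created if missing).
#' @return `write_expression_mtx` returns `dir` invisibly;
#'   `read_expression_mtx` returns a `SingleCellExperiment`.
#' @export
write_expression_mtx <- function(sce, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(SummarizedExperiment::assay(sce, "counts"),
                  file.path(dir, "counts.mtx"))
  utils::write.table(as.data.frame(SummarizedExperiment::rowData(sce)),
                     file.path(dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(SummarizedExperiment::colData(sce)),
                     file.path(dir, "barcodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_expression_mtx
#' @export
read_expression_mtx <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "counts.mtx")),
                        "CsparseMatrix")
  genes <- utils::read.delim(file.path(dir, "genes.tsv"))
  cells <- utils::read.delim(file.path(dir, "barcodes.tsv"))
  rownames(counts) <- genes$gene_id
  colnames(counts) <- cells$barcode
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(genes),
    colData = S4Vectors::DataFrame(cells))
  compute_qc(sce)
}
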