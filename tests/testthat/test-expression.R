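test_that("expression spec validation enforces its invariants", {
  expect_error(expr_sim_spec(n_genes = 10, n_chromosomes = 22), "n_genes")
  expect_error(expr_sim_spec(chr7_gain_factor = 0.8), "chr7_gain_factor")
  expect_error(expr_sim_spec(chr10_loss_factor = 1.4), "chr10_loss_factor")
  expect_error(expr_sim_spec(cancer_fraction = 1.2), "cancer_fraction")
})

test_that("generator output is reproducible and correctly annotated", {
  spec <- expr_sim_spec(n_cells = 150, n_genes = 300, n_reference_cells = 40,
                        seed = 5)
  a <- generate_expression_matrix(spec)
  b <- generate_expression_matrix(spec)
  expect_identical(SummarizedExperiment::assay(a, "counts"),
                   SummarizedExperiment::assay(b, "counts"))
  rd <- SummarizedExperiment::rowData(a)
  expect_equal(sum(rd$is_mito), ceiling(0.01 * 300))
  expect_true(all(startsWith(rd$gene_id[rd$is_mito], "MT-")))
  expect_setequal(unique(rd$chromosome),
                  c("MT", paste0("chr", 1:22)))
  expect_equal(ncol(a), 190)
  expect_true(all(c("DCX", "OLIG2", "NES") %in% rownames(a)))
})

test_that("cancer cell count follows the rounding rule", {
  spec <- expr_sim_spec(n_cells = 10000, n_genes = 130, cancer_fraction = 0.3977,
                        n_reference_cells = 0, seed = 3)
  sce <- generate_expression_matrix(spec)
  expect_equal(sum(sce$truth_label == "cancer"), 3977)
  expect_equal(sum(sce$truth_label == "normal"), 6023)
})

test_that("planted chromosome folds surface as group mean-expression ratios", {
  spec <- expr_sim_spec(n_cells = 1000, n_genes = 1100,
                        n_reference_cells = 50, seed = 8)
  sce <- generate_expression_matrix(spec)
  counts <- SummarizedExperiment::assay(sce, "counts")
  chrom <- SummarizedExperiment::rowData(sce)$chromosome
  cancer <- sce$truth_label == "cancer"; normal <- sce$truth_label == "normal"
  ratio <- function(ch)
    mean(as.matrix(counts[chrom == ch, cancer])) /
      mean(as.matrix(counts[chrom == ch, normal]))
  # per-cell renormalisation to the drawn library size shifts the realised
  # fold slightly below/above the nominal factor; allow 7%
  expect_lt(abs(ratio("chr7") - 1.5), 0.105)
  expect_lt(abs(ratio("chr10") - 0.5), 0.035)
  expect_lt(abs(ratio("chr3") - 1.0), 0.07)
})

test_that("null aberration makes cancer and normal cells exchangeable", {
  spec <- expr_sim_spec(n_cells = 400, n_genes = 440, chr7_gain_factor = 1,
                        chr10_loss_factor = 1, n_reference_cells = 30,
                        seed = 12)
  sce <- generate_expression_matrix(spec)
  counts <- SummarizedExperiment::assay(sce, "counts")
  chrom <- SummarizedExperiment::rowData(sce)$chromosome
  cancer <- sce$truth_label == "cancer"; normal <- sce$truth_label == "normal"
  for (ch in c("chr7", "chr10")) {
    r <- mean(as.matrix(counts[chrom == ch, cancer])) /
      mean(as.matrix(counts[chrom == ch, normal]))
    expect_lt(abs(r - 1), 0.12)
  }
})

test_that("QC filter retains exactly the predicate-satisfying cells, strictly", {
  fx <- qc_violator_fixture()
  filtered <- qc_filter(fx$sce)
  expect_equal(ncol(filtered), 470)
  kept <- match(colnames(filtered), colnames(fx$sce))
  expect_false(any(fx$violators %in% kept))
  # a cell with exactly 1000 UMIs is removed (strict >)
  expect_true(all(fx$sce$total_umis[1:10] == 1000))
  # idempotence
  again <- qc_filter(filtered)
  expect_identical(colnames(again), colnames(filtered))
  expect_identical(SummarizedExperiment::assay(again, "counts"),
                   SummarizedExperiment::assay(filtered, "counts"))
})

test_that("QC metrics are recomputable and match their definitions", {
  spec <- expr_sim_spec(n_cells = 80, n_genes = 200, n_reference_cells = 0,
                        seed = 2)
  sce <- generate_expression_matrix(spec)
  counts <- SummarizedExperiment::assay(sce, "counts")
  expect_equal(sce$total_umis, unname(Matrix::colSums(counts)))
  expect_equal(sce$genes_detected, unname(as.integer(Matrix::colSums(counts > 0))))
  mito <- SummarizedExperiment::rowData(sce)$is_mito
  expect_equal(sce$mito_fraction,
               unname(Matrix::colSums(counts[mito, ]) / Matrix::colSums(counts)))
})

test_that("downsampling is uniform, seeded and boundary-safe", {
  spec <- expr_sim_spec(n_cells = 120, n_genes = 150, n_reference_cells = 0,
                        seed = 4)
  sce <- generate_expression_matrix(spec)
  a <- downsample_cells(sce, 50, seed = 9)
  b <- downsample_cells(sce, 50, seed = 9)
  expect_identical(colnames(a), colnames(b))
  expect_equal(ncol(a), 50)
  expect_identical(colnames(downsample_cells(sce, 120, seed = 1)),
                   colnames(sce))
  expect_warning(downsample_cells(sce, 500, seed = 1), "returning all")
})

test_that("log-normalisation matches hand arithmetic and its identity", {
  counts <- Matrix::Matrix(c(90, 10, 5, 0), 2, 2, sparse = TRUE)
  rownames(counts) <- c("g1", "g2"); colnames(counts) <- c("c1", "c2")
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(gene_id = c("g1", "g2"),
                                   is_mito = c(FALSE, FALSE)))
  norm <- SummarizedExperiment::assay(log_normalize(sce), "lognorm")
  expect_equal(norm[, "c1"], c(g1 = log(1 + 9000), g2 = log(1 + 1000)))
  expect_equal(norm["g2", "c2"], 0)                      # zero count -> 0
  # per-cell identity: sum(exp(v) - 1) == scale
  spec <- expr_sim_spec(n_cells = 60, n_genes = 150, n_reference_cells = 0,
                        seed = 6)
  big <- log_normalize(generate_expression_matrix(spec))
  v <- SummarizedExperiment::assay(big, "lognorm")
  sums <- Matrix::colSums(expm1(as.matrix(v)))
  expect_equal(sums, stats::setNames(rep(1e4, 60), colnames(big)),
               tolerance = 1e-8)
  # zero-total cell errors
  zero <- sce
  SummarizedExperiment::assay(zero, "counts")[, 2] <- 0
  expect_error(log_normalize(zero), "zero total")
})

test_that("MTX round-trip preserves counts and annotations", {
  spec <- expr_sim_spec(n_cells = 40, n_genes = 120, n_reference_cells = 10,
                        seed = 7)
  sce <- generate_expression_matrix(spec)
  dir <- withr::local_tempdir()
  write_expression_mtx(sce, dir)
  expect_true(all(file.exists(file.path(dir, c("counts.mtx", "genes.tsv",
                                               "barcodes.tsv")))))
  back <- read_expression_mtx(dir)
  expect_equal(as.matrix(SummarizedExperiment::assay(back, "counts")),
               as.matrix(SummarizedExperiment::assay(sce, "counts")))
  expect_equal(back$truth_label, sce$truth_label)
  expect_equal(SummarizedExperiment::rowData(back)$chromosome,
               SummarizedExperiment::rowData(sce)$chromosome)
})
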