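# small expression fixture shared across CNV tests
cnv_fixture <- function(seed = 10, n_cells = 500, genes_per_chr = 100,
                        n_chr = 12, ...) {
  n_genes <- genes_per_chr * n_chr + ceiling(0.01 * genes_per_chr * n_chr)
  spec <- expr_sim_spec(n_cells = n_cells, n_genes = n_genes,
                        n_chromosomes = n_chr, n_reference_cells = 100,
                        seed = seed, ...)
  sce <- log_normalize(qc_filter(generate_expression_matrix(spec)))
  list(sce = sce,
       ref = colnames(sce)[sce$truth_label == "reference"])
}

test_that("reference centring makes reference mean scores exactly zero", {
  fx <- cnv_fixture()
  sc <- cnv_score(fx$sce, reference = fx$ref, window = 21)
  ref_rows <- rownames(sc) %in% fx$ref
  expect_lt(max(abs(colMeans(sc[ref_rows, ]))), 1e-10)
  expect_true(all(is.finite(sc)))
})

test_that("window = 1 degenerates to the per-chromosome mean residual", {
  fx <- cnv_fixture(n_cells = 120)
  sce <- fx$sce
  sc1 <- cnv_score(sce, reference = fx$ref, window = 1)
  # independent computation: order genes, centre on reference, average
  mat <- as.matrix(SummarizedExperiment::assay(sce, "lognorm"))
  rd <- as.data.frame(SummarizedExperiment::rowData(sce))
  resid <- mat - rowMeans(mat[, fx$ref])
  for (ch in c("chr2", "chr7", "MT")) {
    g <- which(rd$chromosome == ch)
    expect_equal(sc1[, ch], colMeans(resid[g, ]), tolerance = 1e-12)
  }
})

test_that("smoothing window truncates at chromosome ends and preserves means", {
  fx <- cnv_fixture(n_cells = 100)
  sc_narrow <- cnv_score(fx$sce, reference = fx$ref, window = 1)
  sc_wide <- cnv_score(fx$sce, reference = fx$ref, window = 51)
  # a truncated centred moving average is mean-preserving only approximately;
  # scores must stay strongly concordant across windows
  expect_gt(stats::cor(sc_narrow[, "chr7"], sc_wide[, "chr7"]), 0.95)
  # chromosomes with fewer than window/4 genes are flagged
  expect_true("MT" %in% attr(cnv_score(fx$sce, reference = fx$ref,
                                       window = 201), "low_confidence"))
  expect_false("chr1" %in% attr(cnv_score(fx$sce, reference = fx$ref,
                                          window = 51), "low_confidence"))
})

test_that("adding a constant to one gene leaves scores unchanged", {
  fx <- cnv_fixture(n_cells = 80)
  mat <- as.matrix(SummarizedExperiment::assay(fx$sce, "lognorm"))
  rd <- as.data.frame(SummarizedExperiment::rowData(fx$sce))
  sc_a <- cnv_score(mat, gene_pos = rd, reference = fx$ref, window = 31)
  mat2 <- mat; mat2[200, ] <- mat2[200, ] + 5
  sc_b <- cnv_score(mat2, gene_pos = rd, reference = fx$ref, window = 31)
  expect_equal(sc_a, sc_b, tolerance = 1e-12)
})

test_that("chr7 scores separate planted cancer from normal cells", {
  fx <- cnv_fixture(n_cells = 500, genes_per_chr = 200)
  sc <- cnv_score(fx$sce, reference = fx$ref)
  lab <- fx$sce$truth_label
  s7c <- sc[lab == "cancer", "chr7"]; s7n <- sc[lab == "normal", "chr7"]
  # empirical AUC via the rank-sum identity
  auc <- (sum(rank(c(s7c, s7n))[seq_along(s7c)]) -
            length(s7c) * (length(s7c) + 1) / 2) /
    (length(s7c) * length(s7n))
  expect_gte(auc, 0.95)
  expect_gt(mean(s7c), mean(s7n))
})

test_that("scores increase monotonically with the planted fold change", {
  means <- vapply(c(1, 1.3, 1.6), function(f) {
    fx <- cnv_fixture(n_cells = 150, seed = 33, chr7_gain_factor = f)
    sc <- cnv_score(fx$sce, reference = fx$ref, window = 51)
    mean(sc[fx$sce$truth_label == "cancer", "chr7"])
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("the malignancy rule is an OR over chr7 gain and chr10 loss", {
  sc <- matrix(0, 4, 12, dimnames = list(paste0("c", 1:4),
                                         paste0("chr", 1:12)))
  sc[2, "chr7"] <- 0.4                      # gain only
  sc[3, "chr10"] <- -0.4                    # loss only
  sc[4, "chr7"] <- 0.4; sc[4, "chr10"] <- -0.4
  calls <- classify_malignancy(sc)
  expect_equal(calls$status, c("normal", "cancer", "cancer", "cancer"))
  expect_equal(calls$chr7_call, c("neutral", "gain", "neutral", "gain"))
  expect_equal(calls$chr10_call, c("neutral", "neutral", "loss", "loss"))
  # all-zero scores -> all normal
  expect_true(all(classify_malignancy(sc * 0)$status == "normal"))
  # threshold sign validation
  expect_error(classify_malignancy(sc, gain_threshold = -0.1), "positive")
  expect_error(classify_malignancy(sc, loss_threshold = 0.1), "negative")
})

test_that("planted cancer fraction is recovered within five points", {
  fx <- cnv_fixture(n_cells = 600, genes_per_chr = 150, seed = 21)
  sc <- cnv_score(fx$sce, reference = fx$ref)
  calls <- classify_malignancy(sc)
  tum <- fx$sce$truth_label != "reference"
  rec <- mean(calls$status[tum] == "cancer")
  truth <- mean(fx$sce$truth_label[tum] == "cancer")
  expect_lt(abs(rec - truth), 0.05)
})

test_that("input validation catches malformed CNV requests", {
  fx <- cnv_fixture(n_cells = 60)
  expect_error(cnv_score(fx$sce, reference = fx$ref[1:5]), "at least 20")
  expect_error(cnv_score(fx$sce, reference = c(fx$ref[-1], "NOPE")),
               "unknown reference")
  mat <- as.matrix(SummarizedExperiment::assay(fx$sce, "lognorm"))
  expect_error(cnv_score(mat, reference = fx$ref), "gene_pos")
})
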