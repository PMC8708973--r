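#' Genomically smoothed CNV scores from normalized expression
#'
#' A deliberately simple, fully specified copy-number scorer in the spirit of
#' windowed residual-smoothing methods: (1) genes are ordered by
#' (chromosome, start); (2) each gene's normalized expression is centred on
#' its mean over the reference cells; (3) within each chromosome every cell's
#' residual profile is smoothed with a centred moving average of `window`
#' genes, the window truncating at chromosome ends (never crossing a
#' chromosome boundary); (4) the chromosome score is the mean smoothed
#' residual over that chromosome's genes. By construction the mean score of
#' the reference cells is exactly zero on every chromosome.
#'
#' @param x A `SingleCellExperiment` carrying a `lognorm` assay and
#'   `chromosome` / `start` in `rowData`, or a genes x cells normalized
#'   matrix (then `gene_pos` is required).
#' @param gene_pos data.frame with `chromosome` and `start` per gene, in
#'   matrix row order (ignored when `x` is a `SingleCellExperiment`).
#' @param reference Cell identifiers (column names or indices) of the
#'   non-cancer reference population used for centring; at least 20.
#' @param window Moving-average span in genes (odd; default 101).
#' @return A cells x chromosomes numeric matrix of scores, with attribute
#'   `low_confidence`: chromosome names carrying fewer than `window / 4`
#'   genes.
#' @export
cnv_score <- function(x, gene_pos = NULL, reference, window = 101L) {
  if (methods::is(x, "SingleCellExperiment")) {
    gene_pos <- as.data.frame(SummarizedExperiment::rowData(x))
    mat <- as_norm_matrix(x)
  } else {
    mat <- x
    if (is.null(gene_pos)) stop("gene_pos required for a plain matrix")
  }
  stopifnot(all(c("chromosome", "start") %in% names(gene_pos)),
            nrow(gene_pos) == nrow(mat))
  if (window < 1L) stop("window must be >= 1")
  ref_idx <- if (is.character(reference)) match(reference, colnames(mat))
             else as.integer(reference)
  if (anyNA(ref_idx)) stop("unknown reference cell identifier(s)")
  if (length(ref_idx) < 20L)
    stop("need at least 20 reference cells for a stable centring")

  chroms <- unique(gene_pos$chromosome)  # order of appearance
  mat <- as.matrix(mat)
  ref_mean <- rowMeans(mat[, ref_idx, drop = FALSE])
  resid <- mat - ref_mean

  scores <- matrix(NA_real_, ncol(mat), length(chroms),
                   dimnames = list(colnames(mat), chroms))
  low_conf <- character(0)
  half <- (window - 1) / 2
  for (ch in chroms) {
    g <- which(gene_pos$chromosome == ch)
    g <- g[order(gene_pos$start[g])]
    n <- length(g)
    if (n < window / 4) low_conf <- c(low_conf, ch)
    r <- resid[g, , drop = FALSE]
    if (window > 1L && n > 1L) {
      # truncated centred moving average via cumulative sums
      cs <- rbind(0, apply(r, 2, cumsum))
      lo <- pmax(seq_len(n) - half, 1)
      hi <- pmin(seq_len(n) + half, n)
      r <- (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) /
        (hi - lo + 1)
    }
    scores[, ch] <- colMeans(r)
  }
  attr(scores, "low_confidence") <- low_conf
  scores
}

#' Cancer/normal call from the chromosome-7 / chromosome-10 rule
#'
#' Applies the canonical glioblastoma aberration rule: a cell is called
#' cancer when its chromosome-7 score shows gain (score >= `gain_threshold`)
#' OR its chromosome-10 score shows loss (score <= `loss_threshold`).
#'
#' @param scores Cells x chromosomes score matrix from [cnv_score()].
#' @param gain_threshold Gain cut-off (> 0, default +0.15).
#' @param loss_threshold Loss cut-off (< 0, default -0.15).
#' @param gain_chrom,loss_chrom Chromosome names carrying the rule.
#' @return A data.frame of class `cnv_call_set`: `cell`, `chr7_score`,
#'   `chr10_score`, `chr7_call` (`gain`/`neutral`), `chr10_call`
#'   (`loss`/`neutral`), `status` (`cancer`/`normal`).
#' @export
classify_malignancy <- function(scores, gain_threshold = 0.15,
                                loss_threshold = -0.15,
                                gain_chrom = "chr7", loss_chrom = "chr10") {
  if (gain_threshold <= 0)
    stop("gain_threshold must be positive (a gain is an elevated score)")
  if (loss_threshold >= 0)
    stop("loss_threshold must be negative (a loss is a depressed score)")
  stopifnot(all(c(gain_chrom, loss_chrom) %in% colnames(scores)))
  s7 <- scores[, gain_chrom]; s10 <- scores[, loss_chrom]
  if (any(!is.finite(s7)) || any(!is.finite(s10)))
    stop("non-finite CNV scores")
  chr7_call <- ifelse(s7 >= gain_threshold, "gain", "neutral")
  chr10_call <- ifelse(s10 <= loss_threshold, "loss", "neutral")
  out <- data.frame(
    cell = if (!is.null(rownames(scores))) rownames(scores)
           else seq_len(nrow(scores)),
    chr7_score = s7, chr10_score = s10,
    chr7_call = chr7_call, chr10_call = chr10_call,
    status = ifelse(chr7_call == "gain" | chr10_call == "loss",
                    "cancer", "normal"),
    row.names = NULL)
  class(out) <- c("cnv_call_set", "data.frame")
  out
}
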