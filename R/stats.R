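#' Average counting-spot subsamples per image
#'
#' All subsamples (spots) of the same image are averaged: each measure is
#' the arithmetic mean over that image's spots, with undefined (`NA`)
#' per-spot values excluded from that measure's mean. Result: one row per
#' image.
#'
#' @param spots data.frame of per-spot records carrying `image_id` and
#'   numeric measure columns.
#' @param measures Columns to average; default every `freq_*` column plus
#'   `total_cells`.
#' @param roi_info Optional data.frame keyed by `image_id` (e.g. the `rois`
#'   table of [generate_study()]) merged onto the result.
#' @return data.frame with one row per image: `image_id`, `n_spots`, the
#'   averaged measures, and any `roi_info` columns.
#' @export
average_subsamples <- function(spots, measures = NULL, roi_info = NULL) {
  stopifnot("image_id" %in% names(spots))
  if (is.null(measures))
    measures <- intersect(c("total_cells",
                            grep("^freq_", names(spots), value = TRUE)),
                          names(spots))
  ids <- unique(spots$image_id)
  g <- factor(spots$image_id, levels = ids)
  out <- data.frame(image_id = ids,
                    n_spots = as.integer(tabulate(g, nbins = length(ids))))
  for (m in measures) {
    x <- spots[[m]]
    ok <- !is.na(x)
    sums <- rowsum(ifelse(ok, x, 0), g)[, 1]
    cnt <- rowsum(as.numeric(ok), g)[, 1]
    out[[m]] <- ifelse(cnt > 0, sums / cnt, NA_real_)
  }
  rownames(out) <- NULL
  if (!is.null(roi_info))
    out <- merge(roi_info, out, by = "image_id", sort = FALSE)
  rownames(out) <- NULL
  out
}

test_result <- function(test, measure, groups, n, statistic = NA_real_,
                        df = NA_real_, p_value = NA_real_, skipped = FALSE,
                        reason = NA_character_) {
  data.frame(test = test, measure = measure,
             groups = paste(groups, collapse = " vs "),
             n = paste(n, collapse = ","),
             statistic = statistic, df = df, p_value = p_value,
             skipped = skipped, reason = reason)
}

#' Unpaired two-group site comparison (Wilcoxon rank-sum / Mann-Whitney)
#'
#' Two-sided rank-sum test of one measure between two tissue categories
#' (exact for small tie-free samples, normal approximation with continuity
#' and tie correction otherwise).
#'
#' @param table A frequency table from [average_subsamples()] with a
#'   `category` column.
#' @param measure Measure column name.
#' @param groups Length-2 character: the categories compared.
#' @param group_col Grouping column (default `"category"`).
#' @return One-row data.frame (`test`, `measure`, `groups`, `n`,
#'   `statistic`, `df`, `p_value`, `skipped`, `reason`).
#' @export
compare_sites_unpaired <- function(table, measure,
                                   groups = c("tumour_other",
                                              "tumour_adjacent_to_margin"),
                                   group_col = "category") {
  x <- table[[measure]][table[[group_col]] == groups[1]]
  y <- table[[measure]][table[[group_col]] == groups[2]]
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L)
    return(test_result("wilcoxon_rank_sum", measure, groups,
                       c(length(x), length(y)), skipped = TRUE,
                       reason = "fewer than 2 observations in a group"))
  wt <- suppressWarnings(stats::wilcox.test(x, y))
  test_result("wilcoxon_rank_sum", measure, groups, c(length(x), length(y)),
              statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Paired margin vs adjacent-tumour comparison (Wilcoxon signed-rank)
#'
#' Pairs the margin and tumour-adjacent-to-margin measurements within case
#' and resection (values averaged within case x resection x category first),
#' then applies the two-sided signed-rank test on the paired differences;
#' zero differences are dropped (the standard convention).
#'
#' @param table Frequency table with `case_id`, `resection`, `category`.
#' @param measure Measure column name.
#' @param groups Length-2 character: the paired categories
#'   (first minus second).
#' @return One-row data.frame as in [compare_sites_unpaired()].
#' @export
compare_margin_adjacent_paired <- function(table, measure,
                                           groups = c("margin",
                                                      "tumour_adjacent_to_margin")) {
  sub <- table[table$category %in% groups & !is.na(table[[measure]]), ]
  ag <- stats::aggregate(sub[[measure]],
                         by = list(case_id = sub$case_id,
                                   resection = sub$resection,
                                   category = sub$category),
                         FUN = mean)
  wide <- merge(ag[ag$category == groups[1], c("case_id", "resection", "x")],
                ag[ag$category == groups[2], c("case_id", "resection", "x")],
                by = c("case_id", "resection"),
                suffixes = c("_a", "_b"))
  d <- wide$x_a - wide$x_b
  n_pairs <- length(d)
  if (n_pairs < 2L)
    return(test_result("wilcoxon_signed_rank", measure, groups, n_pairs,
                       skipped = TRUE, reason = "fewer than 2 usable pairs"))
  if (all(d == 0))
    return(test_result("wilcoxon_signed_rank", measure, groups, n_pairs,
                       skipped = TRUE,
                       reason = "all paired differences are zero"))
  wt <- suppressWarnings(stats::wilcox.test(wide$x_a, wide$x_b,
                                            paired = TRUE))
  test_result("wilcoxon_signed_rank", measure, groups, n_pairs,
              statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Trend over sequential resections (Kruskal-Wallis)
#'
#' Kruskal-Wallis rank-sum test of one measure over the resection groups
#' (tie-corrected H; df = groups - 1, so 2 for the three sequential
#' resections).
#'
#' @param table Frequency table with a `resection` column.
#' @param measure Measure column name.
#' @return One-row data.frame as in [compare_sites_unpaired()].
#' @export
resection_trend <- function(table, measure) {
  sub <- table[!is.na(table[[measure]]), ]
  groups <- sort(unique(sub$resection))
  ns <- vapply(groups, function(g) sum(sub$resection == g), integer(1))
  if (length(groups) < 2L)
    return(test_result("kruskal_wallis", measure,
                       paste0("resection", groups), ns, skipped = TRUE,
                       reason = "fewer than 2 resection groups"))
  kt <- stats::kruskal.test(sub[[measure]], factor(sub$resection))
  test_result("kruskal_wallis", measure, paste0("resection", groups), ns,
              statistic = unname(kt$statistic),
              df = unname(kt$parameter), p_value = kt$p.value)
}

#' Spearman correlation structure across sites and markers
#'
#' Builds one column per (measure, site) pair — the per-case mean of the
#' measure at that site — and returns the Spearman correlation matrix with
#' two-sided p-values over cases observed at both sites of each pair.
#' Constant columns give `NA` entries with a warning.
#'
#' @param table Frequency table with `case_id` and `category`.
#' @param measures Measure columns (default the single-marker frequencies).
#' @param sites Categories included (default all present).
#' @return A list with matrices `r`, `p` and `n` (symmetric; unit diagonal
#'   in `r`).
#' @export
site_marker_correlations <- function(table,
                                     measures = c("freq_dcx", "freq_olig2",
                                                  "freq_nes"),
                                     sites = NULL) {
  if (is.null(sites)) sites <- sort(unique(table$category))
  cases <- sort(unique(table$case_id))
  cols <- list()
  for (m in measures) for (s in sites) {
    v <- vapply(cases, function(cs) {
      x <- table[[m]][table$case_id == cs & table$category == s]
      x <- x[!is.na(x)]
      if (length(x)) mean(x) else NA_real_
    }, numeric(1))
    cols[[paste(m, s, sep = ".")]] <- v
  }
  mat <- do.call(cbind, cols)
  k <- ncol(mat)
  r <- matrix(NA_real_, k, k, dimnames = list(colnames(mat), colnames(mat)))
  p <- r; nmat <- r
  for (i in seq_len(k)) for (j in i:k) {
    ok <- stats::complete.cases(mat[, i], mat[, j])
    nmat[i, j] <- nmat[j, i] <- sum(ok)
    if (i == j) { r[i, j] <- 1; p[i, j] <- NA; next }
    if (sum(ok) < 3L) next
    a <- mat[ok, i]; b <- mat[ok, j]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      warning("constant column in correlation pair ",
              colnames(mat)[i], " / ", colnames(mat)[j])
      next
    }
    ct <- suppressWarnings(stats::cor.test(a, b, method = "spearman",
                                           exact = FALSE))
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  list(r = r, p = p, n = nmat)
}
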