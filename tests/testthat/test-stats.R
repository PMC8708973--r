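test_that("subsample averaging is a per-image mean that ignores NA measures", {
  spots <- data.frame(image_id = c("i1", "i2", "i2", "i3", "i3"),
                      freq_dcx = c(0.4, 0.1, 0.3, NA, 0.2),
                      total_cells = c(10, 20, 30, 0, 40))
  tab <- average_subsamples(spots)
  # one spot per image -> identity
  expect_equal(tab$freq_dcx[tab$image_id == "i1"], 0.4)
  # (0.1, 0.3) -> 0.2 by hand
  expect_equal(tab$freq_dcx[tab$image_id == "i2"], 0.2)
  # NA spot excluded from that measure's mean
  expect_equal(tab$freq_dcx[tab$image_id == "i3"], 0.2)
  expect_equal(tab$n_spots, c(1L, 2L, 2L))
  # permuting spot order changes nothing
  perm <- spots[c(5, 3, 1, 4, 2), ]
  tab2 <- average_subsamples(perm)
  expect_equal(tab2[order(tab2$image_id), -1],
               tab[order(tab$image_id), -1], ignore_attr = TRUE)
})

test_that("rank-sum test matches its exact enumeration oracle", {
  # the canonical fully separated 3 vs 3 case: two-sided exact p = 0.1
  tab <- data.frame(category = rep(c("a", "b"), each = 3),
                    m = c(1, 2, 3, 4, 5, 6))
  res <- compare_sites_unpaired(tab, "m", c("a", "b"))
  expect_equal(res$p_value, 0.1)
  expect_equal(res$p_value, ranksum_enum_p(1:3, 4:6))
  # random tie-free cases across group sizes
  set.seed(31)
  for (rep in 1:10) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    x <- stats::rnorm(n1); y <- stats::rnorm(n2, 0.5)
    tab <- data.frame(category = rep(c("a", "b"), c(n1, n2)), m = c(x, y))
    res <- compare_sites_unpaired(tab, "m", c("a", "b"))
    expect_equal(res$p_value, ranksum_enum_p(x, y), tolerance = 1e-12)
  }
  # an empty group is skipped with a reason
  res <- compare_sites_unpaired(data.frame(category = "a", m = 1), "m",
                                c("a", "b"))
  expect_true(res$skipped)
})

test_that("signed-rank test matches its sign-pattern enumeration oracle", {
  # differences {+1,+2,+3}: two-sided exact p = 0.25
  tab <- data.frame(case_id = rep(c("c1", "c2", "c3"), 2), resection = 1,
                    category = rep(c("margin", "tumour_adjacent_to_margin"),
                                   each = 3),
                    m = c(2, 3, 4, 1, 1, 1))
  res <- compare_margin_adjacent_paired(tab, "m")
  expect_equal(res$p_value, 0.25)
  expect_equal(res$p_value, signedrank_enum_p(c(1, 2, 3)))
  set.seed(17)
  for (rep in 1:8) {
    n <- sample(3:8, 1)
    a <- stats::rnorm(n, 0.3); b <- stats::rnorm(n)
    tab <- data.frame(case_id = rep(sprintf("c%d", 1:n), 2), resection = 1,
                      category = rep(c("margin", "tumour_adjacent_to_margin"),
                                     each = n),
                      m = c(a, b))
    res <- compare_margin_adjacent_paired(tab, "m")
    expect_equal(res$p_value, signedrank_enum_p(a - b), tolerance = 1e-12)
  }
})

test_that("degenerate pairings are reported as skipped, not errors", {
  tab <- data.frame(case_id = rep(c("c1", "c2"), 2), resection = 1,
                    category = rep(c("margin", "tumour_adjacent_to_margin"),
                                   each = 2),
                    m = c(1, 2, 1, 2))
  res <- compare_margin_adjacent_paired(tab, "m")
  expect_true(res$skipped)
  expect_match(res$reason, "zero")
  one <- tab[c(1, 3), ]
  expect_true(compare_margin_adjacent_paired(one, "m")$skipped)
})

test_that("pairing is invariant to row order and respects case+resection keys", {
  set.seed(9)
  tab <- data.frame(case_id = rep(sprintf("c%d", 1:6), each = 2),
                    resection = rep(1:2, 6),
                    category = rep(c("margin", "tumour_adjacent_to_margin"), 6),
                    m = stats::runif(12))
  # rebuild so each case x resection has both categories
  tab <- rbind(tab, transform(tab,
    category = ifelse(category == "margin",
                      "tumour_adjacent_to_margin", "margin"),
    m = stats::runif(12)))
  a <- compare_margin_adjacent_paired(tab, "m")
  b <- compare_margin_adjacent_paired(tab[sample(nrow(tab)), ], "m")
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$n, b$n)
})

test_that("Kruskal-Wallis matches the direct rank formula and reports df = 2", {
  # three resection groups of two, hand-rankable
  tab <- data.frame(resection = rep(1:3, each = 2),
                    m = c(1.2, 0.8, 2.1, 1.9, 3.3, 2.8))
  res <- resection_trend(tab, "m")
  expect_equal(res$df, 2)
  expect_equal(res$statistic, kruskal_H_oracle(tab$m, tab$resection),
               tolerance = 1e-12)
  expect_equal(res$p_value,
               stats::pchisq(res$statistic, 2, lower.tail = FALSE))
  # identical group distributions at large n: H small, p near 1
  set.seed(2)
  big <- data.frame(resection = rep(1:3, each = 300),
                    m = rep(stats::rnorm(300), 3))
  expect_gt(resection_trend(big, "m")$p_value, 0.95)
  # tie-corrected agreement on data with ties
  tied <- data.frame(resection = rep(1:3, each = 4),
                     m = c(1, 1, 2, 3, 2, 2, 3, 4, 1, 3, 3, 4))
  res <- resection_trend(tied, "m")
  expect_equal(res$statistic, kruskal_H_oracle(tied$m, tied$resection),
               tolerance = 1e-12)
})

test_that("site correlations respect rank invariances and planted signs", {
  set.seed(13)
  n <- 20
  base <- stats::runif(n, 0.1, 0.5)
  # planted structure: NES in tumour decreases when DCX in margin increases
  tab <- rbind(
    data.frame(case_id = sprintf("c%d", 1:n), resection = 1,
               category = "margin", freq_dcx = base,
               freq_olig2 = stats::runif(n), freq_nes = stats::runif(n)),
    data.frame(case_id = sprintf("c%d", 1:n), resection = 1,
               category = "tumour_other", freq_dcx = stats::runif(n),
               freq_olig2 = stats::runif(n),
               freq_nes = 0.6 - base + stats::rnorm(n, 0, 0.02)))
  sc <- site_marker_correlations(tab)
  expect_equal(unname(diag(sc$r)), rep(1, ncol(sc$r)))
  expect_true(isSymmetric(sc$r))
  expect_lt(sc$r["freq_dcx.margin", "freq_nes.tumour_other"], -0.8)
  # strictly monotone transform of a column leaves its correlations unchanged
  tab2 <- tab
  tab2$freq_dcx <- tab2$freq_dcx^3
  sc2 <- site_marker_correlations(tab2)
  expect_equal(sc2$r, sc$r)
})
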