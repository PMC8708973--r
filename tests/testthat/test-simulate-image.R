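test_that("spec validation rejects degenerate inputs", {
  expect_error(image_sim_spec(n_cells = 0), "n_cells")
  expect_error(image_sim_spec(width = 10, height = 10), "twice the maximum")
  expect_error(image_sim_spec(nucleus_eccentricity_max = 1), "eccentricity")
  expect_error(image_sim_spec(marker_fractions = c(OLIG2 = 1.2, NES = 0, DCX = 0)),
               "0, 1")
  expect_error(
    generate_if_image(image_sim_spec(width = 120, height = 120, n_cells = 200)),
    "packing failure")
})

test_that("generation is bit-identical under a fixed spec and seed", {
  spec <- image_sim_spec(width = 250, height = 250, n_cells = 40, seed = 9)
  a <- generate_if_image(spec)
  b <- generate_if_image(spec)
  expect_identical(a$image, b$image)
  expect_identical(a$labels, b$labels)
  expect_identical(a$truth, b$truth)
})

test_that("zero marker fractions give all-negative truth and pure-noise channels", {
  spec <- image_sim_spec(width = 250, height = 250, n_cells = 50, seed = 1,
                         marker_fractions = c(OLIG2 = 0, NES = 0, DCX = 0))
  sim <- generate_if_image(spec)
  expect_equal(nrow(sim$truth), 50)
  expect_false(any(sim$truth$olig2 | sim$truth$nes | sim$truth$dcx))
  # marker channels contain background noise only
  for (ch in c("OLIG2", "NES", "DCX"))
    expect_lt(max(sim$image[[ch]]), spec$background + 6 * spec$noise_sd)
})

test_that("ground truth is well-formed and NES positives equal the seeded binomial draw", {
  spec <- image_sim_spec(width = 620, height = 620, n_cells = 200, seed = 7,
                         marker_fractions = c(OLIG2 = 0, NES = 0.2, DCX = 0))
  sim <- generate_if_image(spec)
  tr <- sim$truth
  expect_identical(tr$cell_id, 1:200)
  expect_true(all(tr$row >= 1 & tr$row <= 620 & tr$col >= 1 & tr$col <= 620))
  expect_setequal(unique(sim$labels[sim$labels > 0]), 1:200)
  # centroid of each labelled nucleus sits at the recorded truth centroid
  px <- which(sim$labels == 17, arr.ind = TRUE)
  expect_lt(abs(mean(px[, 1]) - tr$row[17]), 1.5)
  expect_lt(abs(mean(px[, 2]) - tr$col[17]), 1.5)
  # the drawn positive count under this seed, recorded as the fixture truth
  expect_identical(sum(tr$nes), 43L)
})

test_that("morphology contract: OLIG2 inside nuclei, DCX/NES outside all nuclei", {
  spec <- image_sim_spec(width = 400, height = 400, n_cells = 90, seed = 3,
                         marker_fractions = c(OLIG2 = 0.5, NES = 0.5, DCX = 0.5),
                         noise_sd = 0)                 # isolate rendered signal
  sim <- generate_if_image(spec)
  fg <- function(ch) sim$image[[ch]] > spec$background + 0.2
  # every OLIG2 foreground pixel lies in a nucleus of an OLIG2-true cell
  o <- which(fg("OLIG2"))
  expect_true(all(sim$labels[o] > 0))
  expect_true(all(sim$truth$olig2[sim$labels[o]]))
  # DCX/NES foreground never enters a nucleus interior
  expect_true(all(sim$labels[which(fg("NES"))] == 0))
  expect_true(all(sim$labels[which(fg("DCX"))] == 0))
})

test_that("empirical marker fractions converge to the spec fractions", {
  # the joint truth draw at large n (2 s.e. tolerance per marker)
  set.seed(3)
  n <- 5000
  tr <- glioquant:::draw_marker_truth(
    n, c(OLIG2 = 0.10, NES = 0.20, DCX = 0.05),
    c(OLIG2.NES = 1, OLIG2.DCX = 1, NES.DCX = 1))
  for (m in c("OLIG2", "NES", "DCX")) {
    p <- c(OLIG2 = 0.10, NES = 0.20, DCX = 0.05)[[m]]
    expect_lt(abs(mean(tr[[m]]) - p), 2 * sqrt(p * (1 - p) / n))
  }
  # and through the full rendered generator at moderate n
  sim <- generate_if_image(image_sim_spec(width = 950, height = 950,
                                          n_cells = 600, seed = 2))
  expect_lt(abs(mean(sim$truth$nes) - 0.20), 2 * sqrt(0.2 * 0.8 / 600))
})

test_that("pair enrichment shifts co-positivity in the stated direction", {
  set.seed(5)
  frac <- c(OLIG2 = 0.3, NES = 0.3, DCX = 0.3)
  ind <- glioquant:::draw_marker_truth(4000, frac,
    c(OLIG2.NES = 1, OLIG2.DCX = 1, NES.DCX = 1))
  enr <- glioquant:::draw_marker_truth(4000, frac,
    c(OLIG2.NES = 8, OLIG2.DCX = 1, NES.DCX = 1))
  expect_gt(mean(enr$OLIG2 & enr$NES), mean(ind$OLIG2 & ind$NES))
})

test_that("multi-page TIFF round-trip preserves channels to quantisation accuracy", {
  sim <- generate_if_image(image_sim_spec(width = 150, height = 150,
                                          n_cells = 12, seed = 4))
  path <- withr::local_tempfile(fileext = ".tif")
  write_mif_tiff(sim$image, path)
  back <- read_mif_tiff(path)
  expect_identical(attr(back, "channels"), attr(sim$image, "channels"))
  for (ch in attr(back, "channels"))
    expect_lt(max(abs(back[[ch]] - sim$image[[ch]])), 2 / 65535)
})
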