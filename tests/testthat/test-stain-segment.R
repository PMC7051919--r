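test_that("a pure-white image deconvolves to (almost) zero in both channels", {
  img <- array(255, dim = c(16, 16, 3))
  sm <- deconvolve_stains(img)
  expect_lt(max(sm$hematoxylin), 0.5)
  expect_lt(max(sm$dab), 0.5)
  expect_equal(dim(sm$dab), c(16, 16))
})

test_that("collinear stain vectors are rejected", {
  v <- rbind(c(0.6, 0.6, 0.5), c(0.6, 0.6, 0.5))
  expect_error(deconvolve_stains(array(255, dim = c(4, 4, 3)), vectors = v),
               "collinear")
})

test_that("render-deconvolve round trip recovers the planted membrane OD", {
  # one positive cell whose membrane DAB OD is exactly 0.8
  lay <- generate_cell_layout(1, immune_fraction = 0, field_size = c(128, 128),
                              seed = 1)
  lay$cells$latent <- 0.8
  prof <- assay_profile("exact", dab_gain = 1, dab_background = 0,
                        noise_sd = 0)
  r <- render_assay_image(lay, prof, seed = 1)
  sm <- deconvolve_stains(r$image)
  # oracle: the rendering equation paints the ring at radius (r+2, r+5]
  cx <- lay$cells$x; cy <- lay$cells$y; rad <- lay$cells$radius
  d <- sqrt(outer((seq_len(128) - cy)^2, (seq_len(128) - cx)^2, "+"))
  ring <- d > rad + 2 & d <= rad + 5
  expect_equal(mean(sm$dab[ring]), od_to_units(0.8), tolerance = 0.03)
  # hematoxylin-only nucleus: DAB stays at background inside the nucleus
  expect_lt(mean(sm$dab[d <= rad]), 1)
  expect_gt(mean(sm$hematoxylin[d <= rad]), od_to_units(0.5))
})

test_that("segmentation recovers the planted cell count on a non-touching field", {
  lay <- planted_layout(300, tps = 0.4, field = c(768, 768), seed = 13)
  r <- render_assay_image(lay, sp263ish(), seed = 2)
  labels <- segment_nuclei(deconvolve_stains(r$image))
  expect_lt(abs(max(labels) - 300) / 300, 0.05)
})

test_that("a blank field yields an empty labelling, not an error", {
  sm <- deconvolve_stains(array(255, dim = c(64, 64, 3)))
  labels <- segment_nuclei(sm)
  expect_equal(max(labels), 0)
  cells <- build_cell_objects(labels, sm)
  expect_equal(nrow(cells$cells), 0)
})

test_that("doubling min_area can only reduce the object count", {
  lay <- planted_layout(120, tps = 0.3, field = c(512, 512), seed = 17)
  sm <- deconvolve_stains(render_assay_image(lay, sp263ish(), seed = 1)$image)
  n <- vapply(c(20, 40, 80, 160), function(a)
    max(segment_nuclei(sm, segmentation_params(min_area = a))), numeric(1))
  expect_true(all(diff(n) <= 0))
})

test_that("membrane ring geometry matches the analytic annulus", {
  # one rasterized disk of radius 8; ring width 3 at offset 2 -> annulus (10, 13]
  H <- 64
  d <- sqrt(outer((seq_len(H) - 32)^2, (seq_len(H) - 32)^2, "+"))
  labels <- matrix(0L, H, H); labels[d <= 8] <- 1L
  sm <- structure(list(hematoxylin = matrix(0, H, H),
                       dab = matrix(10, H, H), scale_note = ""),
                  class = "stain_maps")
  cells <- build_cell_objects(labels, sm, ring_offset = 2, ring_width = 3)
  ring_n <- length(cells$masks[[1]]$ring)
  expect_lt(abs(ring_n - pi * (13^2 - 10^2)) / (pi * (13^2 - 10^2)), 0.10)
  # uniform DAB: both means equal the constant, ratio exactly 1
  expect_equal(cells$cells$feat_mem_dab, 10)
  expect_equal(cells$cells$feat_cell_dab, 10)
  expect_equal(cells$cells$feat_ratio, 1.0)
})

test_that("DAB confined to the ring drives the ratio above 1", {
  H <- 64
  d <- sqrt(outer((seq_len(H) - 32)^2, (seq_len(H) - 32)^2, "+"))
  labels <- matrix(0L, H, H); labels[d <= 8] <- 1L
  dab <- matrix(0, H, H); dab[d > 10 & d <= 13] <- 50
  sm <- structure(list(hematoxylin = matrix(0, H, H), dab = dab, scale_note = ""),
                  class = "stain_maps")
  cells <- build_cell_objects(labels, sm)
  expect_gt(cells$cells$feat_ratio, 1)
  expect_gt(cells$cells$feat_mem_dab, cells$cells$feat_cell_dab)
})

test_that("membrane pixels between neighbouring cells are split at the midline", {
  H <- 64
  labels <- matrix(0L, H, H)
  d1 <- sqrt(outer((seq_len(H) - 32)^2, (seq_len(H) - 20)^2, "+"))
  d2 <- sqrt(outer((seq_len(H) - 32)^2, (seq_len(H) - 44)^2, "+"))
  labels[d1 <= 6] <- 1L; labels[d2 <= 6] <- 2L
  sm <- structure(list(hematoxylin = matrix(0, H, H), dab = matrix(1, H, H),
                       scale_note = ""), class = "stain_maps")
  cells <- build_cell_objects(labels, sm)
  m <- cells$masks
  expect_length(intersect(m[[1]]$whole, m[[2]]$whole), 0)
  # each ring pixel is closer to (or equidistant from) its own nucleus
  rc <- function(idx) cbind((idx - 1) %% H + 1, (idx - 1) %/% H + 1)
  p1 <- rc(m[[1]]$ring)
  own <- sqrt((p1[, 1] - 32)^2 + (p1[, 2] - 20)^2)
  other <- sqrt((p1[, 1] - 32)^2 + (p1[, 2] - 44)^2)
  expect_true(all(own <= other + 1e-9))
})

test_that("stored features are recomputable from masks bit-identically", {
  lay <- planted_layout(80, tps = 0.5, field = c(448, 448), seed = 23)
  sm <- deconvolve_stains(render_assay_image(lay, sp263ish(), seed = 3)$image)
  cells <- build_cell_objects(segment_nuclei(sm), sm)
  re <- recompute_features(cells, sm)
  expect_identical(cells$cells$feat_mem_dab, re$feat_mem_dab)
  expect_identical(cells$cells$feat_cell_dab, re$feat_cell_dab)
  expect_identical(cells$cells$feat_ratio, re$feat_ratio)
})

test_that("tumor/immune classification recovers the planted classes", {
  lay <- planted_layout(250, tps = 0.4, immune_fraction = 0.2,
                        field = c(768, 768), seed = 29)
  r <- render_assay_image(lay, sp263ish(), seed = 4)
  sm <- deconvolve_stains(r$image)
  cells <- classify_cells(build_cell_objects(segment_nuclei(sm), sm))
  # match detected cells to planted cells by nearest centroid
  df <- cells$cells
  nearest <- vapply(seq_len(nrow(df)), function(i)
    which.min((lay$cells$x - df$x[i])^2 + (lay$cells$y - df$y[i])^2),
    integer(1))
  acc <- mean(df$class == lay$cells$class[nearest])
  expect_gte(acc, 0.95)
})

test_that("classification cutoffs behave monotonically and uniformly", {
  df <- data.frame(nucleus_area = c(30, 60, 120, 200),
                   circularity = c(0.9, 0.9, 0.9, 0.9))
  out <- classify_cells(df, area_cutoff = 80, circularity_cutoff = 0.6)
  expect_equal(out$class, c("immune", "immune", "tumor", "tumor"))
  n_immune <- vapply(c(20, 50, 100, 250), function(a)
    sum(classify_cells(df, area_cutoff = a)$class == "immune"), numeric(1))
  expect_true(all(diff(n_immune) >= 0))
  # identical cells all land in the same class
  same <- data.frame(nucleus_area = rep(100, 5), circularity = rep(0.8, 5))
  expect_length(unique(classify_cells(same)$class), 1)
})

test_that("mismatched label and stain shapes are rejected", {
  sm <- deconvolve_stains(array(255, dim = c(32, 32, 3)))
  expect_error(build_cell_objects(matrix(0L, 16, 16), sm), "dimensions")
})
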