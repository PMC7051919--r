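test_that("cell layouts respect counts, spacing and field bounds", {
  lay <- generate_cell_layout(200, immune_fraction = 0.2,
                              field_size = c(768, 768), seed = 7)
  cells <- lay$cells
  expect_equal(nrow(cells), 200)
  expect_true(all(cells$class %in% c("tumor", "immune")))
  # immune count is a binomial draw around 40
  expect_gt(sum(cells$class == "immune"), 20)
  expect_lt(sum(cells$class == "immune"), 60)
  # minimum pairwise spacing
  d <- as.matrix(stats::dist(cells[, c("x", "y")]))
  diag(d) <- Inf
  expect_gte(min(d), lay$min_spacing - 1e-9)
  # fully inside the field (nucleus plus membrane ring)
  expect_true(all(cells$x - cells$radius - 5 >= 0))
  expect_true(all(cells$y - cells$radius - 5 >= 0))
  expect_true(all(cells$x + cells$radius + 5 <= 768))
  expect_true(all(cells$y + cells$radius + 5 <= 768))
})

test_that("a single tumor cell can be placed and layouts are seed-deterministic", {
  lay1 <- generate_cell_layout(1, immune_fraction = 0, field_size = c(256, 256), seed = 1)
  expect_equal(nrow(lay1$cells), 1)
  expect_equal(lay1$cells$class, "tumor")
  lay2 <- generate_cell_layout(120, field_size = c(640, 640), seed = 42)
  lay3 <- generate_cell_layout(120, field_size = c(640, 640), seed = 42)
  expect_identical(lay2, lay3)
})

test_that("an overcrowded field errors rather than looping forever", {
  expect_error(
    generate_cell_layout(500, field_size = c(128, 128), seed = 1,
                         max_attempts = 5000),
    "field too small")
})

test_that("rendered ground truth matches the planted positivity exactly", {
  lay <- generate_cell_layout(10, immune_fraction = 0, field_size = c(384, 384),
                              seed = 3)
  # 4 of 10 tumor cells above the staining threshold
  lay$cells$latent <- c(rep(0.8, 4), rep(0.1, 6))
  r <- render_assay_image(lay, sp263ish(), seed = 1)
  expect_equal(r$truth$true_tps, 40.0)
  expect_equal(sum(r$truth$per_cell_positive), 4)
  # recomputing the score from per-cell truth reproduces true_tps exactly
  tumor <- r$truth$cell_class == "tumor"
  expect_identical(
    100 * sum(r$truth$per_cell_positive & tumor) / sum(tumor),
    r$truth$true_tps)
})

test_that("an all-negative slide has zero TPS and only background DAB", {
  lay <- generate_cell_layout(20, immune_fraction = 0, field_size = c(384, 384),
                              seed = 5)
  lay$cells$latent <- 0
  prof <- assay_profile("quiet", dab_gain = 0.75, dab_background = 0.05,
                        noise_sd = 0)
  r <- render_assay_image(lay, prof, seed = 1)
  expect_equal(r$truth$true_tps, 0)
  sm <- deconvolve_stains(r$image)
  # nothing above the cytoplasmic background (plus quantisation slack)
  expect_lt(max(sm$dab), od_to_units(0.05) + 1.5)
})

test_that("positivity depends on latent expression, not on DAB gain", {
  lay <- planted_layout(60, tps = 0.5, field = c(512, 512), seed = 9)
  p_hi <- assay_profile("hi", dab_gain = 0.9)
  p_lo <- assay_profile("lo", dab_gain = 0.4)
  r_hi <- render_assay_image(lay, p_hi, seed = 1)
  r_lo <- render_assay_image(lay, p_lo, seed = 1)
  expect_identical(r_hi$truth$per_cell_positive, r_lo$truth$per_cell_positive)
  expect_identical(r_hi$truth$true_tps, r_lo$truth$true_tps)
  sm_hi <- deconvolve_stains(r_hi$image)
  sm_lo <- deconvolve_stains(r_lo$image)
  expect_gt(max(sm_hi$dab), max(sm_lo$dab) + 10)
})

test_that("raising the expression offset never lowers true TPS", {
  lay <- planted_layout(100, tps = 0.4, seed = 11)
  offsets <- c(-0.2, -0.1, 0, 0.1, 0.2)
  tps <- vapply(offsets, function(off) {
    pr <- assay_profile("p", expression_offset = off)
    render_assay_image(lay, pr, seed = 1)$truth$true_tps
  }, numeric(1))
  expect_true(all(diff(tps) >= 0))
})

test_that("pathologist simulation is unbiased, snaps to grid and clips", {
  rd0 <- reader_model(bias = 0, sd = 0)
  expect_equal(simulate_pathologist_score(0, rd0), 0)
  rd5 <- reader_model(bias = 5, sd = 0, rounding_grid = 0:100)
  expect_equal(simulate_pathologist_score(50, rd5), 55)
  # Monte-Carlo mean against the stated noise model
  rd <- reader_model(bias = 0, sd = 5)
  draws <- simulate_pathologist_score(rep(30, 10000), rd, seed = 99)
  expect_lt(abs(mean(draws) - 30), 0.2)
  expect_true(all(draws >= 0 & draws <= 100))
  # coarse rounding grid
  rdg <- reader_model(bias = 0, sd = 0, rounding_grid = c(0, 1, seq(5, 100, 5)))
  expect_equal(simulate_pathologist_score(c(2, 12, 98), rdg), c(1, 10, 100))
})

test_that("cohort generation is deterministic and reproduces the zero-inflation weight", {
  # the target score distribution carries the planted zero mass ...
  tps <- sample_tps_distribution(1000, zero_weight = 0.4, seed = 21)
  expect_lt(abs(mean(tps == 0) - 0.40), 0.04)
  expect_true(all(tps >= 0 & tps <= 100))
  # ... and realized cohort truth can only add zeros (finite-cell samples
  # whose tiny target prevalence realizes no positive cell)
  prof <- list(sp263_like = sp263ish())
  co1 <- generate_cohort(250, profiles = prof, readers = list(),
                         n_cells = 60, field_size = c(448, 448),
                         tps = list(zero_weight = 0.4, shape1 = 0.6, shape2 = 1.6),
                         seed = 21, render = FALSE)
  frac0 <- mean(co1$truth$true_tps == 0)
  expect_gte(frac0, 0.40 - 0.07)
  expect_lte(frac0, 0.40 + 0.12)
  co2 <- generate_cohort(3, profiles = default_assay_profiles()[1:2],
                         readers = list(reader_model()), n_cells = 60,
                         field_size = c(448, 448), seed = 5, render = FALSE)
  expect_equal(nrow(co2$truth), 6)   # 3 samples x 2 assays
  co3 <- generate_cohort(3, profiles = default_assay_profiles()[1:2],
                         readers = list(reader_model()), n_cells = 60,
                         field_size = c(448, 448), seed = 5, render = FALSE)
  expect_identical(co2$reads, co3$reads)
  expect_identical(co2$truth, co3$truth)
})

test_that("serial sections record the transform that re-aligns them", {
  lay <- planted_layout(80, tps = 0.3, field = c(384, 384), seed = 2)
  img <- render_assay_image(lay, sp263ish(), seed = 1)$image
  # identity transform, no jitter: output equals input
  ss0 <- render_serial_section(img, rigid_transform(0, 0, 0))
  expect_equal(ss0$image, img, tolerance = 1e-12)
  ss <- render_serial_section(img, rigid_transform(3, 12, -8))
  expect_equal(ss$transform$rotation_deg, 3)
  expect_equal(c(ss$transform$tx, ss$transform$ty), c(12, -8))
  expect_error(render_serial_section(img, rigid_transform(60, 0, 0)),
               "45 degrees")
})

test_that("warping by a transform and then its inverse is a near-identity", {
  lay <- planted_layout(80, tps = 0.3, field = c(384, 384), seed = 4)
  noise_free <- assay_profile("nf", dab_gain = 0.75, noise_sd = 0)
  img <- render_assay_image(lay, noise_free, seed = 1)$image[, , 2]
  ctr <- c((384 + 1) / 2, (384 + 1) / 2)
  tr <- rigid_transform(5, 9, -4, center = ctr)
  back <- warp_image_rigid(warp_image_rigid(img, tr), invert_transform(tr))
  interior <- 60:324
  err <- abs(back[interior, interior] - img[interior, interior])
  # double bilinear resampling only blurs the sharp nucleus/ring edges;
  # away from edges (the vast majority of a mostly-white field) the
  # round trip is exact, and the images stay essentially identical
  expect_lt(stats::median(err), 0.5)
  br <- EBImage::makeBrush(5, "box")
  local_range <- as.matrix(EBImage::dilate(EBImage::Image(img / 255), br)) -
    as.matrix(EBImage::erode(EBImage::Image(img / 255), br))
  off_edge <- local_range[interior, interior] * 255 < 20
  expect_lt(mean(err[off_edge] > 25), 0.001)
  expect_gt(stats::cor(as.vector(back[interior, interior]),
                       as.vector(img[interior, interior])), 0.98)
  # and point mapping round-trips to machine precision
  pts <- cbind(c(10, 100, 300), c(20, 200, 350))
  expect_lt(max(abs(apply_transform(apply_transform(pts, tr),
                                    invert_transform(tr)) - pts)), 1e-6)
})

test_that("planted artifacts are recorded as exclusion polygons", {
  lay <- planted_layout(40, tps = 0.3, field = c(384, 384), seed = 6)
  img <- render_assay_image(lay, sp263ish(), seed = 1)$image
  pa <- plant_artifacts(img, n_pen = 1, n_blur = 1, seed = 3)
  expect_s3_class(pa$exclusions, "annotation_set")
  expect_length(pa$exclusions$polygons, 2)
  expect_true(all(vapply(pa$exclusions$polygons, `[[`, character(1), "label")
                  == "exclusion"))
  expect_false(identical(pa$image, img))
})
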