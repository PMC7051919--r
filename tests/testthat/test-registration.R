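test_that("registering an image against itself gives the identity", {
  lay <- planted_layout(90, tps = 0.3, field = c(448, 448), seed = 31)
  img <- render_assay_image(lay, sp263ish(), seed = 1)$image
  est <- register_images(img, img)
  expect_transform_close(est, rigid_transform(0, 0, 0), tol_px = 0.5,
                         tol_deg = 0.1)
})

test_that("a planted serial-section transform is recovered", {
  lay <- planted_layout(150, tps = 0.3, field = c(512, 512), seed = 37)
  img <- render_assay_image(lay, sp263ish(), seed = 1)$image
  ss <- render_serial_section(img, rigid_transform(3, 12, -8))
  est <- register_images(img, ss$image)
  expect_transform_close(est, ss$transform)
  expect_gt(attr(est, "confidence"), 0.2)
  # applying the estimate really re-aligns the section
  aligned <- warp_image_rigid(ss$image[, , 1], est)
  interior <- 80:432
  expect_lt(mean(abs(aligned[interior, interior] - img[interior, interior, 1])), 6)
})

test_that("random planted transforms across the capture range are recovered", {
  lay <- planted_layout(150, tps = 0.3, field = c(512, 512), seed = 41)
  img <- render_assay_image(lay, sp263ish(), seed = 1)$image
  set.seed(43)
  for (k in 1:8) {
    tr <- rigid_transform(runif(1, -10, 10), runif(1, -50, 50), runif(1, -50, 50))
    ss <- render_serial_section(img, tr)
    est <- register_images(img, ss$image)
    expect_transform_close(est, ss$transform)
  }
})

test_that("pure noise fails registration with a classed condition", {
  set.seed(5)
  n1 <- array(runif(128 * 128 * 3) * 255, dim = c(128, 128, 3))
  n2 <- array(runif(128 * 128 * 3) * 255, dim = c(128, 128, 3))
  expect_error(register_images(n1, n2), class = "registration_failed")
  flat <- array(128, dim = c(96, 96, 3))
  expect_error(register_images(flat, flat), class = "registration_failed")
})

test_that("transforms compose and invert exactly", {
  a <- rigid_transform(4, 3, -2, center = c(50, 50))
  b <- rigid_transform(-1.5, 10, 7, center = c(50, 50))
  pts <- cbind(runif(20, 0, 100), runif(20, 0, 100))
  via_compose <- apply_transform(pts, compose_transforms(a, b))
  step_wise <- apply_transform(apply_transform(pts, a), b)
  expect_equal(via_compose, step_wise, tolerance = 1e-10)
  expect_lt(max(abs(apply_transform(apply_transform(pts, a),
                                    invert_transform(a)) - pts)), 1e-6)
  expect_error(compose_transforms(a, rigid_transform(1, 0, 0, center = c(0, 0))),
               "centre")
})

test_that("annotation transfer maps, clips and preserves labels", {
  ann <- annotation_set(list(
    list(label = "tumor_center", vertices = square_poly(10, 10, 40, 40)),
    list(label = "exclusion", vertices = square_poly(20, 20, 10, 10))
  ), sample_id = "s1", assay = "a")
  # identity: polygons unchanged
  id <- rigid_transform(0, 0, 0)
  out <- transfer_annotations(ann, id, c(100, 100))
  expect_equal(out$polygons[[1]]$vertices, ann$polygons[[1]]$vertices)
  # pure translation shifts every vertex by exactly (10, 0)
  out <- transfer_annotations(ann, rigid_transform(0, 10, 0), c(100, 100))
  expect_equal(out$polygons[[1]]$vertices,
               ann$polygons[[1]]$vertices + cbind(rep(10, 4), rep(0, 4)))
  expect_equal(vapply(out$polygons, `[[`, character(1), "label"),
               c("tumor_center", "exclusion"))
})

test_that("clipping a partially off-image polygon keeps the exact intersection area", {
  sq <- square_poly(-20, 30, 60, 60)  # sticks out on the left
  ann <- annotation_set(list(list(label = "tumor_center", vertices = sq)))
  out <- transfer_annotations(ann, rigid_transform(0, 0, 0), c(100, 100))
  clipped <- out$polygons[[1]]$vertices
  # geometric oracle: rectangle intersection [0.5,40] x [30,90]
  expect_equal(polygon_area(clipped), (40 - 0.5) * 60, tolerance = 0.01)
  expect_gte(min(clipped[, 1]), 0.5)
})

test_that("the comparable region is the tumor intersection minus exclusions", {
  a1 <- annotation_set(list(list(label = "tumor_center",
                                 vertices = square_poly(10, 10, 60, 60))))
  a2 <- annotation_set(list(
    list(label = "tumor_center", vertices = square_poly(40, 10, 60, 60)),
    list(label = "exclusion", vertices = square_poly(45, 15, 10, 10))
  ))
  mask <- comparable_region(list(a1, a2), c(100, 100))
  # oracle: overlap is [40,70] x [10,70] minus the 10 x 10 exclusion
  expect_equal(sum(mask), 30 * 60 - 10 * 10, tolerance = 0.05 * 30 * 60)
  # identical annotations: mask equals the tumor polygon minus its exclusion
  mask_same <- comparable_region(list(a2, a2), c(100, 100))
  expect_equal(sum(mask_same), 60 * 60 - 10 * 10,
               tolerance = 0.05 * 60 * 60)
  # disjoint tumor polygons: flagged, not silently empty
  a3 <- annotation_set(list(list(label = "tumor_center",
                                 vertices = square_poly(80, 80, 15, 15))))
  expect_error(comparable_region(list(a1, a3), c(100, 100)),
               class = "no_comparable_tissue")
})

test_that("adding an exclusion polygon never grows the comparable region", {
  a1 <- annotation_set(list(list(label = "tumor_center",
                                 vertices = square_poly(10, 10, 70, 70))))
  base <- sum(comparable_region(list(a1), c(100, 100)))
  set.seed(61)
  prev <- base
  polys <- list(list(label = "tumor_center", vertices = square_poly(10, 10, 70, 70)))
  for (k in 1:5) {
    polys[[k + 1]] <- list(label = "exclusion",
                           vertices = square_poly(runif(1, 10, 60),
                                                  runif(1, 10, 60), 12, 12))
    cur <- sum(comparable_region(list(annotation_set(polys)), c(100, 100)))
    expect_lte(cur, prev)
    prev <- cur
  }
})

test_that("only cells with centroids inside the mask are scored", {
  cells <- data.frame(x = c(20, 50, 90), y = c(20, 50, 90),
                      class = "tumor", feat_ratio = 2, feat_mem_dab = 50)
  ann <- annotation_set(list(list(label = "tumor_center",
                                  vertices = square_poly(10, 10, 50, 50))))
  mask <- comparable_region(list(ann), c(100, 100))
  kept <- cells_in_region(cells, mask)
  expect_equal(kept$x, c(20, 50))
})

test_that("transforms and annotations round-trip through JSON", {
  tr <- rigid_transform(2.5, -7, 11, center = c(128.5, 128.5))
  f <- tempfile(fileext = ".json")
  write_transform(tr, f)
  expect_equal(read_transform(f), tr)
  ann <- annotation_set(list(list(label = "tumor_center",
                                  vertices = square_poly(5, 5, 20, 30))),
                        sample_id = "s9", assay = "sp263_like")
  fa <- tempfile(fileext = ".json")
  write_annotations(ann, fa)
  back <- read_annotations(fa)
  expect_equal(back$polygons[[1]]$vertices, ann$polygons[[1]]$vertices)
  expect_equal(back$sample_id, "s9")
})
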