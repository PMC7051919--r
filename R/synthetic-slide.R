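# Synthetic H-DAB slide generator with planted ground truth.
#
# Fields hold non-overlapping round nuclei (tumor cells, plus smaller round
# immune cells at half the tumor nucleus radius). Each cell carries a latent
# PD-L1 expression level in [0, 1]; an assay profile maps latent expression
# to rendered membrane DAB optical density, so the same tissue layout can be
# "stained" under several assay sensitivities. The renderer and the
# deconvolution module share one stain basis and one Beer-Lambert model, so
# every downstream stage can be tested against exactly known truth.

#' Generate a random field of non-overlapping cells
#'
#' Places `n_cells` nuclei by dart throwing with a hard minimum
#' centre-to-centre spacing, so nuclei (and, with the default spacing, their
#' membrane rings) never overlap. Immune cells are round nuclei at
#' `immune_size_factor` times the tumor nucleus radius. Latent expression is
#' drawn uniformly on `[0, 1]`, independently for tumor and immune cells;
#' cohort-level generators overwrite it to hit a target prevalence.
#'
#' @param n_cells number of cells to place (>= 1).
#' @param immune_fraction probability that a cell is an immune cell.
#' @param field_size `c(H, W)` in pixels.
#' @param seed integer seed; layouts are pure functions of it.
#' @param nucleus_radius mean tumor nucleus radius in pixels.
#' @param radius_sd standard deviation of the nucleus radius (clipped at
#'   2.5 sd).
#' @param immune_size_factor immune nucleus radius relative to tumor.
#' @param min_spacing minimum centroid spacing in pixels; the default keeps
#'   whole cells (nucleus + membrane ring) disjoint.
#' @param max_attempts rejection-sampling budget before giving up with a
#'   "field too small" error.
#' @param sample_id identifier stored on the layout.
#' @return an object of class `cell_layout`: a list with `cells` (data frame
#'   `cell_id, x, y, radius, class, latent`), `field_size`, `sample_id`,
#'   `min_spacing`.
#' @export
#' @examples
#' lay <- generate_cell_layout(50, immune_fraction = 0.2,
#'                             field_size = c(256, 256), seed = 1)
#' table(lay$cells$class)
generate_cell_layout <- function(n_cells, immune_fraction = 0.2,
                                 field_size = c(1024, 1024), seed = 1,
                                 nucleus_radius = 7, radius_sd = 0.6,
                                 immune_size_factor = 0.5,
                                 min_spacing = NULL,
                                 max_attempts = 200 * n_cells,
                                 sample_id = "sample_01") {
  stopifnot(n_cells >= 1, immune_fraction >= 0, immune_fraction <= 1,
            length(field_size) == 2, all(field_size >= 32))
  H <- field_size[1]; W <- field_size[2]
  r_max <- nucleus_radius + 2.5 * radius_sd
  spacing <- min_spacing %||% max(1.6 * nucleus_radius, 2 * (r_max + 5) + 0.5)
  margin <- r_max + 6
  if (W - 2 * margin < 1 || H - 2 * margin < 1)
    stop("field too small: margin leaves no room for cell centres")

  with_seed(seed, {
    is_immune <- stats::runif(n_cells) < immune_fraction
    radius <- nucleus_radius + pmin(pmax(stats::rnorm(n_cells, 0, radius_sd),
                                         -2.5 * radius_sd), 2.5 * radius_sd)
    radius[is_immune] <- radius[is_immune] * immune_size_factor
    latent <- stats::runif(n_cells)  # immune latent independent of tumor

    xs <- ys <- numeric(n_cells)
    # spatial hash with cell size = spacing for O(1) neighbour checks
    nbx <- max(1L, ceiling(W / spacing)); nby <- max(1L, ceiling(H / spacing))
    bins <- vector("list", nbx * nby)
    bin_of <- function(x, y) {
      bx <- min(nbx, max(1L, ceiling(x / spacing)))
      by <- min(nby, max(1L, ceiling(y / spacing)))
      (by - 1L) * nbx + bx
    }
    placed <- 0L; attempts <- 0L
    while (placed < n_cells) {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stop(sprintf("field too small: placed %d of %d cells after %d attempts",
                     placed, n_cells, attempts))
      x <- stats::runif(1, margin, W - margin)
      y <- stats::runif(1, margin, H - margin)
      bx <- min(nbx, max(1L, ceiling(x / spacing)))
      by <- min(nby, max(1L, ceiling(y / spacing)))
      ok <- TRUE
      for (dx in -1:1) for (dy in -1:1) {
        jx <- bx + dx; jy <- by + dy
        if (jx < 1 || jx > nbx || jy < 1 || jy > nby) next
        idx <- bins[[(jy - 1L) * nbx + jx]]
        if (length(idx) &&
            any((xs[idx] - x)^2 + (ys[idx] - y)^2 < spacing^2)) {
          ok <- FALSE
          break
        }
      }
      if (!ok) next
      placed <- placed + 1L
      xs[placed] <- x; ys[placed] <- y
      b <- bin_of(x, y)
      bins[[b]] <- c(bins[[b]], placed)
    }
    cells <- data.frame(
      cell_id = seq_len(n_cells),
      x = xs, y = ys, radius = radius,
      class = ifelse(is_immune, "immune", "tumor"),
      latent = latent,
      stringsAsFactors = FALSE
    )
  })
  structure(list(cells = cells, field_size = c(H, W), sample_id = sample_id,
                 min_spacing = spacing),
            class = "cell_layout")
}

#' @export
print.cell_layout <- function(x, ...) {
  cat(sprintf("<cell_layout> %s: %d cells (%d tumor, %d immune) in %d x %d px\n",
              x$sample_id, nrow(x$cells), sum(x$cells$class == "tumor"),
              sum(x$cells$class == "immune"), x$field_size[1], x$field_size[2]))
  invisible(x)
}

#' Add extra immune cells to an existing layout
#'
#' Keeps existing cells fixed and dart-throws additional immune cells under
#' the same spacing constraint; used to test that immune cells never move a
#' sample's tumor proportion score.
#'
#' @param layout a [generate_cell_layout()] result.
#' @param n_extra number of immune cells to add.
#' @param seed integer seed.
#' @param latent latent expression values for the new cells (recycled);
#'   values above the rendering threshold yield DAB-positive immune cells.
#' @return a new `cell_layout` with `n_extra` additional immune cells.
#' @export
add_immune_cells <- function(layout, n_extra, seed = 1, latent = NULL) {
  cells <- layout$cells
  H <- layout$field_size[1]; W <- layout$field_size[2]
  spacing <- layout$min_spacing
  r_imm <- 0.5 * mean(cells$radius[cells$class == "tumor"])
  if (!is.finite(r_imm)) r_imm <- 3.5
  margin <- max(cells$radius) + 6
  with_seed(seed, {
    lat <- if (is.null(latent)) stats::runif(n_extra) else rep_len(latent, n_extra)
    xs <- cells$x; ys <- cells$y
    added <- 0L; attempts <- 0L
    nx <- ny <- numeric(n_extra)
    while (added < n_extra) {
      attempts <- attempts + 1L
      if (attempts > 2000 * n_extra)
        stop("field too small: cannot place additional immune cells")
      x <- stats::runif(1, margin, W - margin)
      y <- stats::runif(1, margin, H - margin)
      if (any((xs - x)^2 + (ys - y)^2 < spacing^2)) next
      added <- added + 1L
      nx[added] <- x; ny[added] <- y
      xs <- c(xs, x); ys <- c(ys, y)
    }
    extra <- data.frame(
      cell_id = max(cells$cell_id) + seq_len(n_extra),
      x = nx, y = ny,
      radius = r_imm + stats::rnorm(n_extra, 0, 0.2),
      class = "immune", latent = lat, stringsAsFactors = FALSE
    )
  })
  layout$cells <- rbind(cells, extra)
  layout
}

#' Staining profile of one immunohistochemistry assay
#'
#' Maps latent PD-L1 expression to rendered staining. A cell is rendered
#' with a membrane ring when `latent + expression_offset >
#' positivity_threshold_latent`; the ring's DAB optical density is
#' `dab_gain * latent + dab_background`. Lower `dab_gain` emulates a
#' lower-titration, less sensitive assay whose positive membranes stain
#' faintly (an "SP142-like" profile); `expression_offset` shifts which cells
#' stain at all.
#'
#' @param name assay label.
#' @param dab_gain positive multiplier from latent expression to membrane
#'   DAB OD.
#' @param dab_background baseline cytoplasmic DAB OD painted over the whole
#'   cell.
#' @param expression_offset additive shift applied to latent expression when
#'   deciding positivity.
#' @param noise_sd per-pixel Gaussian OD noise (both channels).
#' @param positivity_threshold_latent latent level above which a cell stains.
#' @return an object of class `assay_profile`.
#' @export
assay_profile <- function(name, dab_gain = 0.75, dab_background = 0.04,
                          expression_offset = 0, noise_sd = 0.02,
                          positivity_threshold_latent = 0.3) {
  stopifnot(dab_gain > 0, noise_sd >= 0,
            positivity_threshold_latent >= 0, positivity_threshold_latent <= 1)
  structure(list(name = name, dab_gain = dab_gain,
                 dab_background = dab_background,
                 expression_offset = expression_offset, noise_sd = noise_sd,
                 positivity_threshold_latent = positivity_threshold_latent),
            class = "assay_profile")
}

#' @export
print.assay_profile <- function(x, ...) {
  cat(sprintf("<assay_profile> %s: gain %.2f, background OD %.3f, offset %+.2f, noise sd %.3f, latent threshold %.2f\n",
              x$name, x$dab_gain, x$dab_background, x$expression_offset,
              x$noise_sd, x$positivity_threshold_latent))
  invisible(x)
}

#' Default four-assay profile set
#'
#' Three concordant profiles with similar sensitivity and one low-titration
#' profile whose positive membranes stain much more faintly, mimicking the
#' divergent behaviour of the SP142 assay relative to SP263/22C3/28-8.
#'
#' @return named list of [assay_profile()] objects.
#' @export
default_assay_profiles <- function() {
  list(
    sp263_like = assay_profile("sp263_like", dab_gain = 0.75, expression_offset = 0),
    d22c3_like = assay_profile("d22c3_like", dab_gain = 0.62, expression_offset = -0.02),
    d28_8_like = assay_profile("d28_8_like", dab_gain = 0.70, expression_offset = 0.01),
    sp142_like = assay_profile("sp142_like", dab_gain = 0.35, dab_background = 0.03,
                               expression_offset = -0.10)
  )
}

#' Render one assay's stained image of a cell layout
#'
#' Paints hematoxylin optical density over nuclei and DAB optical density
#' over cytoplasm (background level) and membrane rings (positive cells
#' only; ring at nucleus radius +2 to +5 px), adds per-pixel OD noise, and
#' converts to 8-bit RGB by inverse Beer-Lambert mixing of the H-DAB stain
#' vectors. The returned ground truth records exactly which cells were
#' rendered positive and the resulting true % positive tumor cells.
#'
#' @param layout a [generate_cell_layout()] result.
#' @param profile an [assay_profile()].
#' @param seed seed for the rendering noise.
#' @param hema_od,hema_sd mean and per-cell sd of nuclear hematoxylin OD.
#' @param ring_offset,ring_width membrane ring geometry in pixels outside
#'   the nucleus boundary.
#' @param vectors stain basis shared with [deconvolve_stains()].
#' @return a list with `image` (H x W x 3 array, 0-255) and `truth`, an
#'   object of class `slide_ground_truth` holding `per_cell_positive`
#'   (logical, all cells), `true_tps`, `n_tumor_cells`, `n_immune_cells`.
#' @export
render_assay_image <- function(layout, profile, seed = 1,
                               hema_od = 0.75, hema_sd = 0.05,
                               ring_offset = 2, ring_width = 3,
                               vectors = stain_vectors_hdab()) {
  stopifnot(inherits(layout, "cell_layout"), inherits(profile, "assay_profile"))
  H <- layout$field_size[1]; W <- layout$field_size[2]
  cells <- layout$cells
  odh <- matrix(0, H, W); odd <- matrix(0, H, W)
  positive <- cells$latent + profile$expression_offset >
    profile$positivity_threshold_latent

  with_seed(seed, {
    cell_hema <- pmax(stats::rnorm(nrow(cells), hema_od, hema_sd), 0.2)
    for (i in seq_len(nrow(cells))) {
      r <- cells$radius[i]
      r_out <- r + ring_offset + ring_width
      rr <- max(1L, floor(cells$y[i] - r_out)):min(H, ceiling(cells$y[i] + r_out))
      cc <- max(1L, floor(cells$x[i] - r_out)):min(W, ceiling(cells$x[i] + r_out))
      d <- sqrt(outer((rr - cells$y[i])^2, (cc - cells$x[i])^2, "+"))
      nuc <- d <= r
      whole <- d <= r_out
      odh[rr, cc][nuc] <- cell_hema[i]
      odd[rr, cc][whole] <- pmax(odd[rr, cc][whole], profile$dab_background)
      if (positive[i]) {
        ring <- d > (r + ring_offset) & d <= r_out
        odd[rr, cc][ring] <- profile$dab_gain * cells$latent[i] + profile$dab_background
      }
    }
    if (profile$noise_sd > 0) {
      odh <- odh + matrix(stats::rnorm(H * W, 0, profile$noise_sd), H, W)
      odd <- odd + matrix(stats::rnorm(H * W, 0, profile$noise_sd), H, W)
    }
  })
  odh[odh < 0] <- 0; odd[odd < 0] <- 0

  img <- array(0, dim = c(H, W, 3))
  for (ch in 1:3) {
    od_ch <- odh * vectors[1, ch] + odd * vectors[2, ch]
    img[, , ch] <- pmin(pmax(round(256 * 10^(-od_ch) - 1), 0), 255)
  }

  tumor <- cells$class == "tumor"
  truth <- structure(list(
    sample_id = layout$sample_id,
    assay_name = profile$name,
    cell_id = cells$cell_id,
    cell_class = cells$class,
    per_cell_positive = positive,
    true_tps = if (any(tumor)) 100 * sum(positive & tumor) / sum(tumor) else NA_real_,
    n_tumor_cells = sum(tumor),
    n_immune_cells = sum(!tumor)
  ), class = "slide_ground_truth")
  list(image = img, truth = truth)
}

#' @export
print.slide_ground_truth <- function(x, ...) {
  cat(sprintf("<slide_ground_truth> %s / %s: true TPS %.1f%% (%d tumor, %d immune cells)\n",
              x$sample_id, x$assay_name, x$true_tps, x$n_tumor_cells, x$n_immune_cells))
  invisible(x)
}

#' Simulate a consecutive tissue section of a rendered slide
#'
#' Resamples the image so that applying `transform` to the output re-aligns
#' it with the input: the recorded transform is exactly the moving-to-fixed
#' transform a registration step should recover. Optional smooth random
#' jitter emulates local tissue displacement between sections.
#'
#' @param image H x W x 3 array (or matrix).
#' @param transform a [rigid_transform()]; rotations beyond +/-45 degrees
#'   are rejected (outside the registration capture range).
#' @param jitter_sd standard deviation (pixels) of the local displacement
#'   field, interpolated from a coarse 8 x 8 grid of Gaussian draws.
#' @param seed seed for the jitter field.
#' @return list with `image` (the warped section) and `transform` (the
#'   recorded moving-to-fixed transform, centre set to the image centre).
#' @export
render_serial_section <- function(image, transform, jitter_sd = 0, seed = 1) {
  if (abs(transform$rotation_deg) > 45)
    stop("rotation outside +/-45 degrees is not supported")
  dims <- dim(image)
  ctr <- image_center(dims[1:2])
  tr <- rigid_transform(transform$rotation_deg, transform$tx, transform$ty, ctr)
  disp <- NULL
  if (jitter_sd > 0) {
    disp <- with_seed(seed, {
      k <- 8
      gx <- matrix(stats::rnorm(k * k, 0, jitter_sd), k, k)
      gy <- matrix(stats::rnorm(k * k, 0, jitter_sd), k, k)
      up <- function(g) {
        rs <- seq(1, k, length.out = dims[1])
        cs <- seq(1, k, length.out = dims[2])
        bilinear_sample(g, matrix(cs, dims[1], dims[2], byrow = TRUE),
                        matrix(rs, dims[1], dims[2]), fill = 0)
      }
      list(dx = up(gx), dy = up(gy))
    })
  }
  moving <- warp_image_rigid(image, invert_transform(tr), fill = 255,
                             displacement = disp)
  moving <- pmin(pmax(moving, 0), 255)  # guard against bilinear float drift
  list(image = moving, transform = tr)
}

#' Noisy pathologist read of a true score
#'
#' @param bias systematic offset in percentage points.
#' @param sd read noise in percentage points; with `heteroscedastic = TRUE`
#'   the sd scales as `sd * min(score, 100 - score) / 50`, vanishing at the
#'   scale ends where pathologists are most certain.
#' @param heteroscedastic logical.
#' @param rounding_grid allowed reported values; reads snap to the nearest.
#' @param seed default seed used by [simulate_pathologist_score()].
#' @param name rater label.
#' @return an object of class `reader_model`.
#' @export
reader_model <- function(bias = 0, sd = 5, heteroscedastic = FALSE,
                         rounding_grid = 0:100, seed = 1, name = "pathologist") {
  stopifnot(sd >= 0, all(rounding_grid >= 0 & rounding_grid <= 100))
  structure(list(bias = bias, sd = sd, heteroscedastic = heteroscedastic,
                 rounding_grid = sort(unique(rounding_grid)), seed = seed,
                 name = name),
            class = "reader_model")
}

#' @rdname reader_model
#' @param true_tps numeric vector of true % positive tumor cells.
#' @param reader a `reader_model`.
#' @param seed seed for the read noise; defaults to the reader's own.
#' @return simulated reads, clipped to `[0, 100]` and snapped to the
#'   reader's rounding grid.
#' @export
simulate_pathologist_score <- function(true_tps, reader, seed = reader$seed) {
  stopifnot(inherits(reader, "reader_model"))
  n <- length(true_tps)
  with_seed(seed, {
    sd_i <- if (reader$heteroscedastic)
      reader$sd * pmin(true_tps, 100 - true_tps) / 50 else rep(reader$sd, n)
    raw <- true_tps + reader$bias + stats::rnorm(n, 0, sd_i)
  })
  grid <- reader$rounding_grid
  snapped <- grid[pmax(1, findInterval(raw, (grid[-length(grid)] + grid[-1]) / 2) + 1)]
  pmin(pmax(snapped, 0), 100)
}

#' Draw true tumor proportion scores for a cohort
#'
#' Zero-inflated mixture: a point mass at 0 (PD-L1 negative samples) plus a
#' `Beta(shape1, shape2)` component scaled to `[0, 100]`. The default
#' weights make negative samples outnumber positive ones at most cutoffs,
#' the regime in which overall percentage agreement is dominated by
#' concordant negatives.
#'
#' @param n number of samples.
#' @param zero_weight probability of a structural zero.
#' @param shape1,shape2 Beta parameters of the positive component.
#' @param seed integer seed.
#' @return numeric vector of true TPS values in `[0, 100]`.
#' @export
sample_tps_distribution <- function(n, zero_weight = 0.35, shape1 = 0.6,
                                    shape2 = 1.6, seed = 1) {
  with_seed(seed, {
    zero <- stats::runif(n) < zero_weight
    tps <- 100 * stats::rbeta(n, shape1, shape2)
    tps[zero] <- 0
    tps
  })
}

#' Generate a synthetic multi-assay cohort with planted truth
#'
#' One shared cell layout per sample; each assay profile renders its own
#' image of that layout (serial sections under per-assay rigid transforms if
#' requested), and each reader model produces a noisy "pathologist" read of
#' each assay's true score. Tumor-cell latent expression is planted to match
#' a per-sample target prevalence drawn from [sample_tps_distribution()]:
#' positive cells draw latent uniformly above the staining threshold plus a
#' margin, negative cells below it, giving the bimodal expression typical of
#' PD-L1.
#'
#' @param n_samples number of samples.
#' @param profiles named list of [assay_profile()] objects.
#' @param readers list of [reader_model()] objects.
#' @param n_cells,immune_fraction,field_size layout parameters, see
#'   [generate_cell_layout()].
#' @param tps list with `zero_weight`, `shape1`, `shape2` for the true score
#'   distribution.
#' @param latent_margin half-width of the expression gap straddling the
#'   staining threshold.
#' @param immune_positive_rate fraction of immune cells planted with
#'   above-threshold latent expression (DAB-positive immune cells that the
#'   classifier must exclude).
#' @param seed root seed; all stages draw from named substreams of it.
#' @param render if `FALSE`, skip image rendering and return truth and reads
#'   only (fast score-level cohorts for concordance analyses).
#' @param serial_transforms optional list, one [rigid_transform()] per
#'   assay name, applied via [render_serial_section()].
#' @return an object of class `ihc_cohort`: list with `layouts`, `images`
#'   (nested `[[sample]][[assay]]`, or `NULL`), `truth` (data frame:
#'   `sample_id, assay, true_tps, n_tumor_cells, n_immune_cells`),
#'   `truth_cells` (per-image `slide_ground_truth` objects), `reads` (score
#'   table of simulated pathologist reads), `transforms`.
#' @export
generate_cohort <- function(n_samples, profiles = default_assay_profiles(),
                            readers = list(reader_model()),
                            n_cells = 500, immune_fraction = 0.2,
                            field_size = c(1024, 1024),
                            tps = list(zero_weight = 0.35, shape1 = 0.6, shape2 = 1.6),
                            latent_margin = 0.05, immune_positive_rate = 0.3,
                            seed = 1, render = TRUE, serial_transforms = NULL) {
  stopifnot(n_samples >= 1, length(profiles) >= 1)
  if (is.null(names(profiles)))
    names(profiles) <- vapply(profiles, `[[`, character(1), "name")
  base_thr <- profiles[[1]]$positivity_threshold_latent
  target <- sample_tps_distribution(n_samples, tps$zero_weight, tps$shape1,
                                    tps$shape2, seed = substream_seed(seed, "tps"))
  sample_ids <- sprintf("sample_%03d", seq_len(n_samples))

  layouts <- vector("list", n_samples); names(layouts) <- sample_ids
  images <- if (render) stats::setNames(vector("list", n_samples), sample_ids) else NULL
  truth_cells <- stats::setNames(vector("list", n_samples), sample_ids)
  transforms <- stats::setNames(vector("list", n_samples), sample_ids)
  truth_rows <- list(); read_rows <- list()

  for (i in seq_len(n_samples)) {
    sid <- sample_ids[i]
    lay <- generate_cell_layout(
      n_cells, immune_fraction, field_size,
      seed = substream_seed(seed, "layout", sid), sample_id = sid)
    lay$cells$latent <- plant_latent(
      lay$cells$class, target[i] / 100, base_thr, latent_margin,
      immune_positive_rate, seed = substream_seed(seed, "latent", sid))
    layouts[[sid]] <- lay
    truth_cells[[sid]] <- list()
    if (render) images[[sid]] <- list()
    transforms[[sid]] <- list()

    for (an in names(profiles)) {
      if (render) {
        r <- render_assay_image(lay, profiles[[an]],
                                seed = substream_seed(seed, "render", sid, an))
        img <- r$image
        tr_rec <- rigid_transform(0, 0, 0, image_center(field_size))
        if (!is.null(serial_transforms[[an]])) {
          ss <- render_serial_section(img, serial_transforms[[an]],
                                      seed = substream_seed(seed, "serial", sid, an))
          img <- ss$image
          tr_rec <- ss$transform
        }
        images[[sid]][[an]] <- img
        transforms[[sid]][[an]] <- tr_rec
        tru <- r$truth
      } else {
        pos <- lay$cells$latent + profiles[[an]]$expression_offset >
          profiles[[an]]$positivity_threshold_latent
        tumor <- lay$cells$class == "tumor"
        tru <- structure(list(
          sample_id = sid, assay_name = an, cell_id = lay$cells$cell_id,
          cell_class = lay$cells$class, per_cell_positive = pos,
          true_tps = if (any(tumor)) 100 * sum(pos & tumor) / sum(tumor) else NA_real_,
          n_tumor_cells = sum(tumor), n_immune_cells = sum(!tumor)
        ), class = "slide_ground_truth")
      }
      truth_cells[[sid]][[an]] <- tru
      truth_rows[[length(truth_rows) + 1]] <- data.frame(
        sample_id = sid, assay = an, true_tps = tru$true_tps,
        n_tumor_cells = tru$n_tumor_cells, n_immune_cells = tru$n_immune_cells,
        stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, truth_rows)

  for (rd in readers) {
    for (an in names(profiles)) {
      sel <- truth$assay == an
      reads <- simulate_pathologist_score(
        truth$true_tps[sel], rd, seed = substream_seed(seed, "reader", rd$name, an))
      read_rows[[length(read_rows) + 1]] <- data.frame(
        sample_id = truth$sample_id[sel], assay = an, rater = rd$name,
        score = reads, n_tumor_cells = truth$n_tumor_cells[sel], valid = TRUE,
        stringsAsFactors = FALSE)
    }
  }
  reads <- if (length(read_rows)) do.call(rbind, read_rows) else NULL

  structure(list(layouts = layouts, images = images, truth = truth,
                 truth_cells = truth_cells, reads = reads,
                 transforms = transforms, profiles = profiles, seed = seed),
            class = "ihc_cohort")
}

#' @export
print.ihc_cohort <- function(x, ...) {
  cat(sprintf("<ihc_cohort> %d sample(s) x %d assay(s); images %s; %d simulated read(s)\n",
              length(x$layouts), length(x$profiles),
              if (is.null(x$images)) "not rendered" else "rendered",
              if (is.null(x$reads)) 0L else nrow(x$reads)))
  invisible(x)
}

# Plant per-cell latent expression so that the fraction of tumor cells above
# `thr` is a Bernoulli(p) draw; expression is bimodal with a +/- margin gap
# around the staining threshold.
plant_latent <- function(class, p, thr, margin, immune_positive_rate, seed) {
  n <- length(class)
  with_seed(seed, {
    lo <- max(thr - margin, 1e-3); hi <- min(thr + margin, 1 - 1e-3)
    pos <- ifelse(class == "tumor",
                  stats::runif(n) < p,
                  stats::runif(n) < immune_positive_rate)
    ifelse(pos, stats::runif(n, hi, 1), stats::runif(n, 0, lo))
  })
}

#' Plant exclusion-worthy artifacts on a rendered image
#'
#' Adds a dark pen-mark rectangle and/or a blurred patch, each recorded as
#' an exclusion polygon, so annotation-based exclusion handling can be
#' exercised on synthetic slides.
#'
#' @param image H x W x 3 array.
#' @param n_pen,n_blur number of pen-mark rectangles and blur patches.
#' @param seed integer seed.
#' @return list with `image` and `exclusions` (an [annotation_set()]).
#' @export
plant_artifacts <- function(image, n_pen = 1, n_blur = 1, seed = 1) {
  dims <- dim(image); H <- dims[1]; W <- dims[2]
  polys <- list()
  with_seed(seed, {
    for (k in seq_len(n_pen)) {
      w <- round(stats::runif(1, 0.08, 0.15) * W)
      h <- round(stats::runif(1, 0.08, 0.15) * H)
      x0 <- round(stats::runif(1, 1, W - w)); y0 <- round(stats::runif(1, 1, H - h))
      image[y0:(y0 + h), x0:(x0 + w), ] <- image[y0:(y0 + h), x0:(x0 + w), ] * 0.15
      polys[[length(polys) + 1]] <- list(
        label = "exclusion",
        vertices = cbind(c(x0, x0 + w, x0 + w, x0), c(y0, y0, y0 + h, y0 + h)))
    }
    for (k in seq_len(n_blur)) {
      w <- round(stats::runif(1, 0.10, 0.18) * W)
      h <- round(stats::runif(1, 0.10, 0.18) * H)
      x0 <- round(stats::runif(1, 1, W - w)); y0 <- round(stats::runif(1, 1, H - h))
      for (ch in 1:3) {
        patch <- image[y0:(y0 + h), x0:(x0 + w), ch]
        image[y0:(y0 + h), x0:(x0 + w), ch] <-
          as.matrix(EBImage::gblur(EBImage::Image(patch), sigma = 4))
      }
      polys[[length(polys) + 1]] <- list(
        label = "exclusion",
        vertices = cbind(c(x0, x0 + w, x0 + w, x0), c(y0, y0, y0 + h, y0 + h)))
    }
  })
  list(image = image, exclusions = annotation_set(polys))
}
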