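# Nucleus segmentation, membrane-ring compartments and per-cell DAB
# features. Cells are segmented from the hematoxylin channel regardless of
# the presence of DAB stain; the membrane compartment is a dilation band
# around each nucleus, clipped at equidistant boundaries between
# neighbouring cells so every membrane pixel belongs to exactly one cell.

#' Segmentation parameters
#'
#' @param smooth_sigma Gaussian smoothing of the hematoxylin map before
#'   thresholding (pixels; 0 disables).
#' @param threshold `"otsu"` for a global Otsu threshold, or a numeric value
#'   on the `[0, 255]` stain scale.
#' @param min_area minimum nucleus area in px^2; smaller objects are
#'   discarded as debris.
#' @param watershed_tolerance minimum object-separation depth passed to the
#'   distance-transform watershed that splits touching nuclei.
#' @return a list of class `segmentation_params`.
#' @export
segmentation_params <- function(smooth_sigma = 1, threshold = "otsu",
                                min_area = 20, watershed_tolerance = 1) {
  structure(list(smooth_sigma = smooth_sigma, threshold = threshold,
                 min_area = min_area, watershed_tolerance = watershed_tolerance),
            class = "segmentation_params")
}

#' Segment nuclei from a hematoxylin stain map
#'
#' Smooths the hematoxylin channel, applies a global threshold (Otsu by
#' default), splits touching nuclei by a distance-transform watershed and
#' removes objects below `min_area`. An empty field yields an all-zero
#' labelling, not an error.
#'
#' @param stains a `stain_maps` object from [deconvolve_stains()], or a
#'   hematoxylin matrix on the `[0, 255]` scale.
#' @param params a [segmentation_params()] list.
#' @return an integer label matrix (background 0, nuclei 1..n).
#' @export
segment_nuclei <- function(stains, params = segmentation_params()) {
  hema <- if (inherits(stains, "stain_maps")) stains$hematoxylin else stains
  stopifnot(is.matrix(hema))
  hs <- hema
  if (params$smooth_sigma > 0)
    hs <- as.matrix(EBImage::gblur(EBImage::Image(hema / 255),
                                   sigma = params$smooth_sigma)) * 255
  thr <- params$threshold
  if (identical(thr, "otsu")) {
    rng <- range(hs)
    if (diff(rng) < 1e-6) return(matrix(0L, nrow(hema), ncol(hema)))
    thr <- EBImage::otsu(EBImage::Image(hs / 255), range = c(0, 1)) * 255
  }
  mask <- hs > thr
  if (!any(mask)) return(matrix(0L, nrow(hema), ncol(hema)))
  dm <- EBImage::distmap(EBImage::Image(mask * 1))
  labels <- EBImage::watershed(dm, tolerance = params$watershed_tolerance, ext = 1)
  labels <- as.matrix(EBImage::imageData(labels))
  # drop small objects, relabel 1..n preserving spatial order of first pixel
  if (max(labels) > 0) {
    sizes <- tabulate(labels, nbins = max(labels))
    keep <- which(sizes >= params$min_area)
    map <- integer(max(labels))
    map[keep] <- seq_along(keep)
    labels[] <- ifelse(labels > 0, map[pmax(labels, 1)], 0L)
  }
  storage.mode(labels) <- "integer"
  labels
}

#' Build cell objects with membrane compartments and DAB features
#'
#' For each nucleus the membrane ring is the set of pixels at Euclidean
#' distance `(ring_offset, ring_offset + ring_width]` from the nucleus,
#' restricted to pixels whose nearest nucleus is this one (equidistant
#' boundaries between neighbours; ties resolve to the lower label). The
#' whole-cell compartment is the nucleus plus everything out to the ring's
#' outer edge. Features are plain mask means over the DAB map, so they can
#' be recomputed bit-identically from the stored masks:
#' `feat_mem_dab` (mean membrane DAB), `feat_cell_dab` (mean whole-cell
#' DAB), and `feat_ratio = feat_mem_dab / max(feat_cell_dab, 1e-6)` --
#' values above 1 indicate a membranous staining pattern.
#'
#' @param labels integer label matrix from [segment_nuclei()].
#' @param stains a `stain_maps` object of the same shape.
#' @param ring_offset gap between nucleus boundary and ring, in pixels.
#' @param ring_width ring width in pixels.
#' @return an object of class `cell_objects`: list with `cells` (data frame
#'   `cell_id, x, y, nucleus_area, perimeter, circularity, feat_mem_dab,
#'   feat_cell_dab, feat_ratio, class`), `masks` (per cell: integer pixel
#'   indices of `nucleus`, `ring`, `whole`), and `dim`.
#' @export
build_cell_objects <- function(labels, stains, ring_offset = 2, ring_width = 3) {
  stopifnot(inherits(stains, "stain_maps"))
  dab <- stains$dab
  if (!all(dim(labels) == dim(dab)))
    stop("label image and stain maps must have identical dimensions")
  n <- max(labels)
  empty <- data.frame(cell_id = integer(0), x = numeric(0), y = numeric(0),
                      nucleus_area = numeric(0), perimeter = numeric(0),
                      circularity = numeric(0), feat_mem_dab = numeric(0),
                      feat_cell_dab = numeric(0), feat_ratio = numeric(0),
                      class = character(0), stringsAsFactors = FALSE)
  if (n == 0)
    return(structure(list(cells = empty, masks = list(), dim = dim(labels)),
                     class = "cell_objects"))

  # ownership: nearest nucleus by geodesic propagation (Voronoi for a flat
  # cost image); distance to the owning nucleus from the distance transform
  owner <- EBImage::propagate(EBImage::Image(matrix(0, nrow(labels), ncol(labels))),
                              seeds = EBImage::Image(labels), lambda = 1e8)
  owner <- as.matrix(EBImage::imageData(owner))
  dist_bg <- EBImage::distmap(EBImage::Image((labels == 0) * 1))
  dist_bg <- as.matrix(EBImage::imageData(dist_bg))  # 0 inside nuclei

  r_out <- ring_offset + ring_width
  in_ring <- dist_bg > ring_offset & dist_bg <= r_out
  in_whole <- dist_bg <= r_out

  idx_all <- seq_along(labels)
  ring_idx <- split(idx_all[in_ring], owner[in_ring])
  whole_idx <- split(idx_all[in_whole], owner[in_whole])
  nuc_idx <- split(idx_all[labels > 0], labels[labels > 0])

  shp <- EBImage::computeFeatures.shape(EBImage::Image(labels))
  area <- shp[, "s.area"]
  perim <- shp[, "s.perimeter"]
  circ <- pmin(4 * pi * area / pmax(perim, 1)^2, 1)

  H <- nrow(labels)
  cells <- data.frame(
    cell_id = seq_len(n), x = NA_real_, y = NA_real_,
    nucleus_area = as.numeric(area), perimeter = as.numeric(perim),
    circularity = as.numeric(circ),
    feat_mem_dab = NA_real_, feat_cell_dab = NA_real_, feat_ratio = NA_real_,
    class = NA_character_, stringsAsFactors = FALSE
  )
  masks <- vector("list", n)
  for (i in seq_len(n)) {
    key <- as.character(i)
    nuc <- nuc_idx[[key]] %||% integer(0)
    ring <- ring_idx[[key]] %||% integer(0)
    whole <- sort(unique(c(nuc, whole_idx[[key]] %||% integer(0))))
    masks[[i]] <- list(nucleus = nuc, ring = ring, whole = whole)
    cells$x[i] <- mean((nuc - 1) %/% H + 1)
    cells$y[i] <- mean((nuc - 1) %% H + 1)
    cells$feat_mem_dab[i] <- if (length(ring)) mean(dab[ring]) else 0
    cells$feat_cell_dab[i] <- if (length(whole)) mean(dab[whole]) else 0
    cells$feat_ratio[i] <- cells$feat_mem_dab[i] / max(cells$feat_cell_dab[i], 1e-6)
  }
  structure(list(cells = cells, masks = masks, dim = dim(labels)),
            class = "cell_objects")
}

#' @export
print.cell_objects <- function(x, ...) {
  cl <- table(factor(x$cells$class, levels = c("tumor", "immune")))
  cat(sprintf("<cell_objects> %d cell(s) in %d x %d px (%d tumor, %d immune, %d unclassified)\n",
              nrow(x$cells), x$dim[1], x$dim[2], cl[["tumor"]], cl[["immune"]],
              sum(is.na(x$cells$class))))
  invisible(x)
}

#' Classify cells as tumor or immune
#'
#' Rule-based morphology gate: cells with `nucleus_area < area_cutoff` and
#' `circularity > circularity_cutoff` are labelled immune (small round
#' lymphocyte-like nuclei); everything else is tumor. Raising `area_cutoff`
#' can only grow the immune set.
#'
#' @param cells a `cell_objects` object (or its `cells` data frame).
#' @param area_cutoff nucleus area cutoff in px^2.
#' @param circularity_cutoff circularity cutoff in `[0, 1]`.
#' @return the input with the `class` column filled in.
#' @export
classify_cells <- function(cells, area_cutoff = 80, circularity_cutoff = 0.6) {
  df <- if (inherits(cells, "cell_objects")) cells$cells else cells
  immune <- df$nucleus_area < area_cutoff & df$circularity > circularity_cutoff
  df$class <- ifelse(immune, "immune", "tumor")
  if (inherits(cells, "cell_objects")) {
    cells$cells <- df
    cells
  } else df
}

#' Recompute cell features directly from stored masks
#'
#' Features on `cell_objects` are defined as mask means over the DAB map;
#' this helper recomputes them from scratch (used to assert bit-identical
#' reproducibility).
#'
#' @param cells a `cell_objects` object.
#' @param stains the `stain_maps` the features were computed from.
#' @return data frame with `cell_id, feat_mem_dab, feat_cell_dab, feat_ratio`.
#' @export
recompute_features <- function(cells, stains) {
  stopifnot(inherits(cells, "cell_objects"), inherits(stains, "stain_maps"))
  dab <- stains$dab
  out <- lapply(seq_along(cells$masks), function(i) {
    m <- cells$masks[[i]]
    mem <- if (length(m$ring)) mean(dab[m$ring]) else 0
    whole <- if (length(m$whole)) mean(dab[m$whole]) else 0
    data.frame(cell_id = cells$cells$cell_id[i], feat_mem_dab = mem,
               feat_cell_dab = whole, feat_ratio = mem / max(whole, 1e-6))
  })
  do.call(rbind, out)
}
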