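# Rigid co-registration of serial-section images and annotation transfer.
#
# Consecutive sections of one block are modelled as rigidly displaced views
# of the same tissue: a rotation about the image centre plus a translation.
# Rotation is estimated by phase correlation of log-polar resampled Fourier
# magnitudes (rotation becomes a shift along the angle axis), then refined
# and disambiguated by maximising the translation phase-correlation peak;
# translation follows by standard phase correlation with sub-pixel
# (parabolic) peak interpolation.

#' Rigid 2-D transform
#'
#' Represents `p' = R(theta) (p - center) + center + (tx, ty)` in pixel
#' coordinates (origin top-left, x rightward, y downward; positive angles
#' rotate x toward y).
#'
#' @param rotation_deg rotation angle in degrees.
#' @param tx,ty translation in pixels.
#' @param center length-2 rotation centre `(x, y)`; conventionally the image
#'   centre.
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation_deg = 0, tx = 0, ty = 0, center = c(0, 0)) {
  stopifnot(is.numeric(rotation_deg), length(rotation_deg) == 1,
            is.finite(rotation_deg), length(center) == 2)
  structure(list(rotation_deg = rotation_deg, tx = tx, ty = ty,
                 center = as.numeric(center)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> rotation %.3f deg, t = (%.2f, %.2f) px, center (%.1f, %.1f)\n",
              x$rotation_deg, x$tx, x$ty, x$center[1], x$center[2]))
  invisible(x)
}

rotation_matrix <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
}

#' Apply, invert and compose rigid transforms
#'
#' @param xy an n x 2 matrix of `(x, y)` points.
#' @param transform,a,b `rigid_transform` objects; `compose_transforms(a, b)`
#'   applies `a` first, then `b` (both must share a rotation centre).
#' @return transformed points, or a new `rigid_transform`.
#' @export
apply_transform <- function(xy, transform) {
  xy <- matrix(as.numeric(xy), ncol = 2)
  R <- rotation_matrix(transform$rotation_deg)
  ctr <- matrix(transform$center, nrow(xy), 2, byrow = TRUE)
  out <- (xy - ctr) %*% t(R) + ctr
  out[, 1] <- out[, 1] + transform$tx
  out[, 2] <- out[, 2] + transform$ty
  out
}

#' @rdname apply_transform
#' @export
invert_transform <- function(transform) {
  R <- rotation_matrix(-transform$rotation_deg)
  t_new <- -as.vector(R %*% c(transform$tx, transform$ty))
  rigid_transform(-transform$rotation_deg, t_new[1], t_new[2], transform$center)
}

#' @rdname apply_transform
#' @export
compose_transforms <- function(a, b) {
  if (max(abs(a$center - b$center)) > 1e-9)
    stop("transforms must share a rotation centre to be composed")
  R_b <- rotation_matrix(b$rotation_deg)
  t_ab <- as.vector(R_b %*% c(a$tx, a$ty)) + c(b$tx, b$ty)
  rigid_transform(a$rotation_deg + b$rotation_deg, t_ab[1], t_ab[2], a$center)
}

image_center <- function(dim_hw) c((dim_hw[2] + 1) / 2, (dim_hw[1] + 1) / 2)

#' Resample an image under a rigid transform
#'
#' Inverse-mapping bilinear warp: output pixel `q` takes the value of the
#' input at `transform^{-1}(q)`, so content at `p` in the input appears at
#' `transform(p)` in the output.
#'
#' @param img matrix or H x W x 3 array.
#' @param transform a [rigid_transform()].
#' @param fill value used outside the input domain (255 = white background
#'   for brightfield RGB).
#' @param displacement optional list with matrices `dx`, `dy` (same size as
#'   the image) added to the inverse-mapped sampling coordinates; used by the
#'   synthetic generator to emulate local section-to-section tissue jitter.
#' @return warped image with the same dimensions as `img`.
#' @export
warp_image_rigid <- function(img, transform, fill = 255, displacement = NULL) {
  dims <- dim(img)
  H <- dims[1]; W <- dims[2]
  inv <- invert_transform(transform)
  grid <- cbind(rep(seq_len(W), each = H), rep(seq_len(H), times = W))
  src <- apply_transform(grid, inv)
  sx <- matrix(src[, 1], H, W); sy <- matrix(src[, 2], H, W)
  if (!is.null(displacement)) {
    sx <- sx + displacement$dx
    sy <- sy + displacement$dy
  }
  if (length(dims) == 2L) return(bilinear_sample(img, sx, sy, fill = fill))
  out <- array(0, dims)
  for (ch in seq_len(dims[3]))
    out[, , ch] <- bilinear_sample(img[, , ch], sx, sy, fill = fill)
  out
}

# --- phase correlation -------------------------------------------------------

# Phase correlation of equally sized matrices. Returns the shift (dx, dy)
# such that translating `b` by (dx, dy) best aligns it with `a`, plus the
# normalised correlation peak height.
phase_correlate <- function(a, b, window = TRUE, subpixel = TRUE) {
  stopifnot(all(dim(a) == dim(b)))
  H <- nrow(a); W <- ncol(a)
  if (window) {
    w <- hann_window(H, W)
    a <- (a - mean(a)) * w
    b <- (b - mean(b)) * w
  }
  Fa <- stats::fft(a); Fb <- stats::fft(b)
  cross <- Fa * Conj(Fb)
  denom <- Mod(cross)
  denom[denom < 1e-12] <- 1e-12
  r <- Re(stats::fft(cross / denom, inverse = TRUE)) / (H * W)
  peak <- which.max(r)
  pr <- (peak - 1) %% H + 1
  pc <- (peak - 1) %/% H + 1
  wrap <- function(i, n) ifelse(i - 1 > n / 2, i - 1 - n, i - 1)
  dy <- wrap(pr, H); dx <- wrap(pc, W)
  if (subpixel) {
    at <- function(rr, cc) r[(rr - 1) %% H + 1, (cc - 1) %% W + 1]
    para <- function(vm, v0, vp) {
      den <- vm - 2 * v0 + vp
      if (abs(den) < 1e-12) 0 else max(-0.5, min(0.5, 0.5 * (vm - vp) / den))
    }
    dy <- dy + para(at(pr - 1, pc), at(pr, pc), at(pr + 1, pc))
    dx <- dx + para(at(pr, pc - 1), at(pr, pc), at(pr, pc + 1))
  }
  list(dx = dx, dy = dy, peak = max(r))
}

# Log-polar resampling of an fftshifted magnitude spectrum: rows sweep the
# angle over [0, pi), columns sweep log-radius.
logpolar_magnitude <- function(mag, n_theta = 720, n_r = 128) {
  H <- nrow(mag); W <- ncol(mag)
  cy <- floor(H / 2) + 1; cx <- floor(W / 2) + 1
  r_max <- min(H, W) / 2 - 2
  rs <- exp(seq(log(3), log(r_max), length.out = n_r))
  th <- seq(0, pi, length.out = n_theta + 1)[seq_len(n_theta)]
  x <- cx + outer(cos(th), rs)
  y <- cy + outer(sin(th), rs)
  bilinear_sample(mag, x, y, fill = 0)
}

spectrum_magnitude <- function(mat) {
  m <- (mat - mean(mat)) * hann_window(nrow(mat), ncol(mat))
  lm <- log1p(Mod(stats::fft(m)))
  fftshift2(lm)
}

#' Condition signalled when two images cannot be co-registered
#' @param message description of the failure.
#' @keywords internal
#' @noRd
registration_failed <- function(message) {
  stop(structure(class = c("registration_failed", "error", "condition"),
                 list(message = message, call = sys.call(-1))))
}

#' Estimate the rigid transform aligning a moving image to a fixed image
#'
#' Rotation is estimated by phase correlation of log-polar resampled Fourier
#' magnitude spectra on a downsampled grayscale pair (the 180-degree
#' magnitude ambiguity is resolved by trying both signed candidates), then
#' refined by maximising the translation phase-correlation peak over a local
#' angle bracket. Translation is estimated at full resolution with
#' sub-pixel interpolation. The returned transform `T` satisfies
#' `warp_image_rigid(moving, T) ~ fixed`, i.e. it maps the moving image onto
#' the fixed frame.
#'
#' @param fixed,moving RGB arrays or grayscale matrices of identical size.
#' @param max_rotation_deg guaranteed capture range for the rotation
#'   estimate (degrees).
#' @param confidence_floor minimum acceptable translation phase-correlation
#'   peak; below it a `registration_failed` condition is signalled (the
#'   sample should then be excluded as lacking comparable tissue). The
#'   default `NULL` uses `max(0.05, 12 / min(dim))`: for incoherent images
#'   the expected peak decays like `1 / N`, so the floor tracks about three
#'   times the pure-noise peak at the working resolution.
#' @param target_size images are block-averaged down to about this size for
#'   the rotation stage.
#' @return a [rigid_transform()] with an attached `confidence` attribute.
#' @export
register_images <- function(fixed, moving, max_rotation_deg = 45,
                            confidence_floor = NULL, target_size = 256) {
  gf <- rgb_to_gray(fixed); gm <- rgb_to_gray(moving)
  if (!all(dim(gf) == dim(gm)))
    stop("fixed and moving images must have identical dimensions")
  confidence_floor <- confidence_floor %||% max(0.05, 12 / min(dim(gf)))
  gf <- 255 - gf; gm <- 255 - gm  # tissue bright on dark background
  if (stats::sd(gf) < 1e-9 || stats::sd(gm) < 1e-9)
    registration_failed("flat image: no structure to register")
  factor <- max(1L, floor(min(dim(gf)) / target_size))
  df <- downsample_mean(gf, factor); dm <- downsample_mean(gm, factor)
  ctr_ds <- image_center(dim(df))

  lp_f <- logpolar_magnitude(spectrum_magnitude(df))
  lp_m <- logpolar_magnitude(spectrum_magnitude(dm))
  pc_lp <- phase_correlate(lp_f, lp_m, window = FALSE, subpixel = TRUE)
  step <- 180 / nrow(lp_f)
  ang <- pc_lp$dy * step          # rows are angle bins
  cand <- unique(c(ang, -ang, ang - 180, ang + 180, -ang - 180, -ang + 180, 0))
  cand <- cand[abs(cand) <= max_rotation_deg + 1]
  if (!length(cand)) cand <- 0

  peak_at <- function(angle) {
    rot <- warp_image_rigid(dm, rigid_transform(angle, 0, 0, ctr_ds), fill = 0)
    phase_correlate(df, rot, subpixel = FALSE)$peak
  }
  peaks <- vapply(cand, peak_at, numeric(1))
  best <- cand[which.max(peaks)]
  # local refinement: parabolic fit through a bracket around the best angle
  br <- seq(best - 0.75, best + 0.75, by = 0.375)
  pv <- vapply(br, peak_at, numeric(1))
  i <- which.max(pv)
  angle <- br[i]
  if (i > 1 && i < length(br)) {
    den <- pv[i - 1] - 2 * pv[i] + pv[i + 1]
    if (abs(den) > 1e-12)
      angle <- br[i] + 0.375 * max(-0.5, min(0.5, 0.5 * (pv[i - 1] - pv[i + 1]) / den))
  }

  ctr <- image_center(dim(gf))
  rot_full <- warp_image_rigid(gm, rigid_transform(angle, 0, 0, ctr), fill = 0)
  pc <- phase_correlate(gf, rot_full)
  if (!is.finite(pc$peak) || pc$peak < confidence_floor)
    registration_failed(sprintf(
      "correlation peak %.4f below confidence floor %.4f", pc$peak, confidence_floor))
  out <- rigid_transform(angle, pc$dx, pc$dy, ctr)
  attr(out, "confidence") <- pc$peak
  out
}

# --- annotations -------------------------------------------------------------

#' Polygon annotations for one slide
#'
#' @param polygons list of polygons; each a list with `label`
#'   (`"tumor_center"` or `"exclusion"`) and `vertices` (an n x 2 matrix of
#'   `(x, y)` pixel coordinates, implicitly closed).
#' @param sample_id,assay identifiers.
#' @return an object of class `annotation_set`.
#' @export
annotation_set <- function(polygons, sample_id = NA_character_, assay = NA_character_) {
  for (p in polygons) {
    stopifnot(is.list(p), p$label %in% c("tumor_center", "exclusion"))
    v <- p$vertices
    if (!is.matrix(v) || ncol(v) != 2 || nrow(v) < 3 || !all(is.finite(v)))
      stop("each polygon needs an n x 2 matrix of finite vertices, n >= 3")
  }
  structure(list(polygons = polygons, sample_id = sample_id, assay = assay),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  labs <- vapply(x$polygons, `[[`, character(1), "label")
  cat(sprintf("<annotation_set> sample %s / assay %s: %d tumor_center, %d exclusion polygon(s)\n",
              x$sample_id, x$assay, sum(labs == "tumor_center"), sum(labs == "exclusion")))
  invisible(x)
}

#' Polygon area by the shoelace formula
#' @param vertices n x 2 matrix of `(x, y)` vertices (implicitly closed).
#' @return area in square pixels.
#' @export
polygon_area <- function(vertices) {
  x <- vertices[, 1]; y <- vertices[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

# Sutherland-Hodgman clipping of a polygon against an axis-aligned rectangle.
clip_polygon_rect <- function(vertices, xlim, ylim) {
  clip_edge <- function(poly, inside, intersect) {
    if (nrow(poly) == 0) return(poly)
    out <- list()
    n <- nrow(poly)
    for (i in seq_len(n)) {
      cur <- poly[i, ]; prev <- poly[if (i == 1) n else i - 1, ]
      ci <- inside(cur); prev_in <- inside(prev)
      if (ci) {
        if (!prev_in) out[[length(out) + 1]] <- intersect(prev, cur)
        out[[length(out) + 1]] <- cur
      } else if (prev_in) {
        out[[length(out) + 1]] <- intersect(prev, cur)
      }
    }
    if (!length(out)) return(matrix(numeric(0), 0, 2))
    do.call(rbind, out)
  }
  lerp_at <- function(p, q, t) p + t * (q - p)
  poly <- vertices
  edges <- list(
    list(function(p) p[1] >= xlim[1],
         function(p, q) lerp_at(p, q, (xlim[1] - p[1]) / (q[1] - p[1]))),
    list(function(p) p[1] <= xlim[2],
         function(p, q) lerp_at(p, q, (xlim[2] - p[1]) / (q[1] - p[1]))),
    list(function(p) p[2] >= ylim[1],
         function(p, q) lerp_at(p, q, (ylim[1] - p[2]) / (q[2] - p[2]))),
    list(function(p) p[2] <= ylim[2],
         function(p, q) lerp_at(p, q, (ylim[2] - p[2]) / (q[2] - p[2])))
  )
  for (e in edges) poly <- clip_edge(poly, e[[1]], e[[2]])
  poly
}

#' Map annotations through a rigid transform and clip to image bounds
#'
#' @param ann an [annotation_set()].
#' @param transform a [rigid_transform()] mapping the annotation frame into
#'   the target frame.
#' @param target_bounds `c(H, W)` of the target image; polygons are clipped
#'   to it and polygons that fall entirely outside are dropped.
#' @return a new `annotation_set` in target coordinates.
#' @export
transfer_annotations <- function(ann, transform, target_bounds) {
  H <- target_bounds[1]; W <- target_bounds[2]
  polys <- list()
  for (p in ann$polygons) {
    v <- apply_transform(p$vertices, transform)
    v <- clip_polygon_rect(v, c(0.5, W + 0.5), c(0.5, H + 0.5))
    if (nrow(v) >= 3 && polygon_area(v) > 0)
      polys[[length(polys) + 1]] <- list(label = p$label, vertices = v)
  }
  structure(list(polygons = polys, sample_id = ann$sample_id, assay = ann$assay),
            class = "annotation_set")
}

# Rasterize one polygon onto an H x W logical mask (pixel-centre test).
rasterize_polygon <- function(vertices, dim_hw) {
  H <- dim_hw[1]; W <- dim_hw[2]
  mask <- matrix(FALSE, H, W)
  rr <- max(1L, floor(min(vertices[, 2]))):min(H, ceiling(max(vertices[, 2])))
  cc <- max(1L, floor(min(vertices[, 1]))):min(W, ceiling(max(vertices[, 1])))
  if (!length(rr) || !length(cc) || min(vertices[, 2]) > H || min(vertices[, 1]) > W ||
      max(vertices[, 2]) < 1 || max(vertices[, 1]) < 1) return(mask)
  pts <- cbind(rep(cc, each = length(rr)), rep(rr, times = length(cc)))
  inside <- mgcv::in.out(rbind(vertices, vertices[1, , drop = FALSE]), pts)
  mask[cbind(rep(rr, times = length(cc)), rep(cc, each = length(rr)))] <- inside
  mask
}

#' Condition signalled when no tissue is comparable across assays
#' @keywords internal
#' @noRd
no_comparable_tissue <- function(message) {
  stop(structure(class = c("no_comparable_tissue", "error", "condition"),
                 list(message = message, call = sys.call(-1))))
}

#' Comparable-region mask across assays
#'
#' Intersects the tumor-center polygons of all assays (after transfer into a
#' common frame) and removes the union of all exclusion polygons, yielding
#' the tissue region on which cross-assay scoring is performed. Cells are
#' counted for scoring when their nucleus centroid falls inside this mask.
#'
#' @param annotation_sets list of [annotation_set()] objects, one per assay,
#'   already in a common coordinate frame.
#' @param dim_hw `c(H, W)` of the common frame.
#' @return an H x W logical mask. Signals a `no_comparable_tissue` condition
#'   if the intersection is empty.
#' @export
comparable_region <- function(annotation_sets, dim_hw) {
  tumor <- NULL
  excl <- matrix(FALSE, dim_hw[1], dim_hw[2])
  for (ann in annotation_sets) {
    tmask <- matrix(FALSE, dim_hw[1], dim_hw[2])
    for (p in ann$polygons) {
      m <- rasterize_polygon(p$vertices, dim_hw)
      if (p$label == "tumor_center") tmask <- tmask | m else excl <- excl | m
    }
    tumor <- if (is.null(tumor)) tmask else (tumor & tmask)
  }
  if (is.null(tumor)) no_comparable_tissue("no tumor_center annotations supplied")
  mask <- tumor & !excl
  if (!any(mask))
    no_comparable_tissue("tumor annotations do not overlap across assays")
  mask
}

#' Select cells whose nucleus centroid lies inside a region mask
#'
#' @param cells a `cell_objects` object or its `cells` data frame (columns
#'   `x`, `y`).
#' @param mask H x W logical mask from [comparable_region()].
#' @return the cell table restricted to in-mask centroids.
#' @export
cells_in_region <- function(cells, mask) {
  df <- if (inherits(cells, "cell_objects")) cells$cells else cells
  r <- pmin(pmax(round(df$y), 1), nrow(mask))
  c <- pmin(pmax(round(df$x), 1), ncol(mask))
  df[mask[cbind(r, c)], , drop = FALSE]
}

# --- JSON serialization ------------------------------------------------------

#' Read and write transforms and annotations as JSON
#'
#' Transforms serialize as `{rotation_deg, tx, ty, center}`; annotation sets
#' as polygon coordinate lists with labels.
#'
#' @param transform a [rigid_transform()]; `ann` an [annotation_set()].
#' @param path file path.
#' @name transform_io
#' @export
write_transform <- function(transform, path) {
  jsonlite::write_json(unclass(transform), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname transform_io
#' @export
read_transform <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(x$rotation_deg, x$tx, x$ty, x$center)
}

#' @rdname transform_io
#' @param ann an [annotation_set()].
#' @export
write_annotations <- function(ann, path) {
  payload <- list(
    sample_id = ann$sample_id, assay = ann$assay,
    polygons = lapply(ann$polygons, function(p)
      list(label = p$label, vertices = unname(p$vertices)))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname transform_io
#' @export
read_annotations <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  polys <- x$polygons
  if (is.data.frame(polys)) {
    polys <- lapply(seq_len(nrow(polys)), function(i)
      list(label = polys$label[i], vertices = polys$vertices[[i]]))
  } else {
    polys <- lapply(polys, function(p)
      list(label = p$label, vertices = matrix(unlist(p$vertices), ncol = 2,
                                              byrow = !is.matrix(p$vertices))))
  }
  polys <- lapply(polys, function(p) {
    v <- p$vertices
    if (!is.matrix(v)) v <- matrix(unlist(v), ncol = 2, byrow = TRUE)
    list(label = p$label, vertices = v)
  })
  annotation_set(polys, sample_id = x$sample_id %||% NA_character_,
                 assay = x$assay %||% NA_character_)
}
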