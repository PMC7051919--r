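#' H-DAB stain vectors
#'
#' Unit optical-density vectors for hematoxylin and DAB in RGB space
#' (Ruifrok & Johnston convention). Rows are stains, columns are R, G, B.
#' The synthetic renderer and [deconvolve_stains()] share these vectors by
#' default, so stain separation on synthetic slides is exact up to 8-bit
#' quantisation.
#'
#' @return a 2 x 3 numeric matrix with rownames `hematoxylin`, `dab`.
#' @export
#' @examples
#' stain_vectors_hdab()
stain_vectors_hdab <- function() {
  v <- rbind(
    hematoxylin = c(0.650, 0.704, 0.286),
    dab         = c(0.268, 0.570, 0.776)
  )
  v / sqrt(rowSums(v^2))
}

# One declared mapping from optical density to the 8-bit-like feature scale:
# OD 1.0 corresponds to 85 intensity units. All DAB thresholds in this
# package (including the 17.72 default) live on this scale.
OD_UNIT_SCALE <- 85

#' @rdname stain_vectors_hdab
#' @export
od_to_units <- function(od) od * OD_UNIT_SCALE

#' Colour-deconvolve an RGB field into hematoxylin and DAB channels
#'
#' Converts 8-bit RGB to per-channel optical density,
#' `OD = -log10((pixel + 1) / 256)`, projects the OD vectors onto the
#' two-stain basis by least squares, clips negative loadings at zero, and
#' rescales so that OD 1.0 maps to 85 on a `[0, 255]` scale.
#'
#' @param rgb an H x W x 3 array of 8-bit RGB values.
#' @param vectors 2 x 3 stain matrix, rows = (hematoxylin, dab); see
#'   [stain_vectors_hdab()].
#' @return an object of class `stain_maps`: a list with matrices
#'   `hematoxylin` and `dab` (same H x W shape as the input, values in
#'   `[0, 255]`) and a `scale_note` describing the OD mapping.
#' @export
#' @examples
#' img <- array(255, dim = c(8, 8, 3))  # pure white: no stain anywhere
#' sm <- deconvolve_stains(img)
#' max(sm$dab)
deconvolve_stains <- function(rgb, vectors = stain_vectors_hdab()) {
  assert_rgb8(rgb, "rgb")
  stopifnot(is.matrix(vectors), dim(vectors) == c(2, 3))
  cp <- crossprod_rows(vectors)
  if (abs(det(cp)) < 1e-8)
    stop("degenerate stain vectors: the two stains are collinear")
  H <- dim(rgb)[1]; W <- dim(rgb)[2]
  od <- -log10((matrix(rgb, H * W, 3) + 1) / 256)
  # least-squares stain loadings: C = OD M' (M M')^{-1}
  conc <- od %*% t(vectors) %*% solve(cp)
  conc[conc < 0] <- 0
  out <- list(
    hematoxylin = matrix(pmin(conc[, 1] * OD_UNIT_SCALE, 255), H, W),
    dab         = matrix(pmin(conc[, 2] * OD_UNIT_SCALE, 255), H, W),
    scale_note  = sprintf("OD = -log10((pixel+1)/256); OD 1.0 -> %d on [0,255]",
                          OD_UNIT_SCALE)
  )
  class(out) <- "stain_maps"
  out
}

crossprod_rows <- function(m) m %*% t(m)

#' @export
print.stain_maps <- function(x, ...) {
  cat(sprintf("<stain_maps> %d x %d px; hematoxylin range [%.1f, %.1f]; dab range [%.1f, %.1f]\n",
              nrow(x$hematoxylin), ncol(x$hematoxylin),
              min(x$hematoxylin), max(x$hematoxylin), min(x$dab), max(x$dab)))
  cat(" ", x$scale_note, "\n")
  invisible(x)
}
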