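# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible substream seed
#'
#' All randomness in the package flows from one root seed; named substreams
#' (layout, render, reader, split, ...) are derived deterministically so that
#' changing one stage's draws never perturbs another stage.
#'
#' @param root integer root seed.
#' @param ... character labels identifying the substream.
#' @return an integer seed in `[0, 2^31)`.
#' @keywords internal
#' @noRd
substream_seed <- function(root, ...) {
  label <- paste(c(...), collapse = "/")
  v <- utf8ToInt(label)
  h <- sum(v * seq_along(v)) %% 99991
  as.integer((as.numeric(root) %% 2147483647 * 7919 + h * 104729) %% 2147483647)
}

# Evaluate `code` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# --- image representation ----------------------------------------------------
# RGB images are numeric arrays dim c(H, W, 3) with values in 0..255;
# pixel (row r, column c) sits at coordinates x = c, y = r (y points down).

assert_rgb8 <- function(img, arg = "image") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop(sprintf("`%s` must be an H x W x 3 array of 8-bit RGB values", arg))
  if (min(img) < -1e-6 || max(img) > 255 + 1e-6)
    stop(sprintf("`%s` must contain values in [0, 255]", arg))
  invisible(img)
}

rgb_to_gray <- function(img) {
  if (is.matrix(img)) return(img)
  assert_rgb8(img)
  (img[, , 1] + img[, , 2] + img[, , 3]) / 3
}

# Bilinear interpolation of `mat` at (x, y) = (column, row); out-of-bounds
# positions return `fill`.
bilinear_sample <- function(mat, x, y, fill = 0) {
  H <- nrow(mat); W <- ncol(mat)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  pick <- function(r, c) {
    out <- rep(fill, length(r))
    ok <- r >= 1 & r <= H & c >= 1 & c <= W
    out[ok] <- mat[cbind(r[ok], c[ok])]
    out
  }
  v00 <- pick(y0, x0)
  v01 <- pick(y0, x0 + 1)
  v10 <- pick(y0 + 1, x0)
  v11 <- pick(y0 + 1, x0 + 1)
  val <- (1 - fy) * ((1 - fx) * v00 + fx * v01) +
    fy * ((1 - fx) * v10 + fx * v11)
  if (is.matrix(x)) matrix(val, nrow(x), ncol(x)) else val
}

# --- FFT helpers for phase correlation --------------------------------------

fftshift2 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  sr <- floor(H / 2); sc <- floor(W / 2)
  m[c((sr + 1):H, seq_len(sr)), c((sc + 1):W, seq_len(sc)), drop = FALSE]
}

hann_window <- function(H, W) {
  wr <- 0.5 - 0.5 * cos(2 * pi * seq_len(H) / (H + 1))
  wc <- 0.5 - 0.5 * cos(2 * pi * seq_len(W) / (W + 1))
  outer(wr, wc)
}

# Integer block-mean downsampling by `factor`.
downsample_mean <- function(mat, factor) {
  if (factor <= 1) return(mat)
  H <- nrow(mat) %/% factor * factor
  W <- ncol(mat) %/% factor * factor
  m <- mat[seq_len(H), seq_len(W), drop = FALSE]
  dim(m) <- c(factor, H %/% factor, factor, W %/% factor)
  colMeans(aperm(m, c(1, 3, 2, 4)), dims = 2)
}
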