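# Shared fixtures: small rendered samples with exactly known per-cell truth,
# and independent brute-force oracles for the agreement statistics.

# Layout with planted bimodal latent expression: a fraction `tps` of tumor
# cells sits well above the staining threshold (0.3), the rest well below.
planted_layout <- function(n_cells = 150, tps = 0.4, immune_fraction = 0.2,
                           field = c(512, 512), seed = 1,
                           immune_positive_rate = 0.3) {
  lay <- generate_cell_layout(n_cells, immune_fraction, field, seed = seed)
  set.seed(seed + 1000)
  n <- nrow(lay$cells)
  pos <- ifelse(lay$cells$class == "tumor",
                runif(n) < tps, runif(n) < immune_positive_rate)
  lay$cells$latent <- ifelse(pos, runif(n, 0.36, 1), runif(n, 0, 0.24))
  lay
}

sp263ish <- function() default_assay_profiles()$sp263_like

# Brute-force per-sample agreement counting: the independent oracle for
# confusion counts, OPA and F1 at one cutoff pair.
brute_agreement <- function(a, b, cutoff_a, cutoff_b) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  pa <- a >= cutoff_a; pb <- b >= cutoff_b
  tp <- 0L; tn <- 0L; fp <- 0L; fn <- 0L
  for (i in seq_along(a)) {            # one sample at a time, no vector tricks
    if (pa[i] && pb[i]) tp <- tp + 1L
    else if (!pa[i] && !pb[i]) tn <- tn + 1L
    else if (pa[i] && !pb[i]) fp <- fp + 1L
    else fn <- fn + 1L
  }
  list(TP = tp, TN = tn, FP = fp, FN = fn,
       opa = if (length(a) == 0) NA_real_ else (tp + tn) / length(a),
       f1 = if (2 * tp + fp + fn == 0) NA_real_ else 2 * tp / (2 * tp + fp + fn))
}

expect_transform_close <- function(est, truth, tol_px = 2, tol_deg = 0.5) {
  expect_lt(abs(est$rotation_deg - truth$rotation_deg), tol_deg)
  expect_lt(abs(est$tx - truth$tx), tol_px)
  expect_lt(abs(est$ty - truth$ty), tol_px)
}

square_poly <- function(x0, y0, w, h) {
  cbind(c(x0, x0 + w, x0 + w, x0), c(y0, y0, y0 + h, y0 + h))
}

# Bare numeric values of a concordance grid (drop class/attrs/dimnames so
# transposes compare value-wise).
grid_values <- function(g) {
  v <- unclass(g)
  attributes(v) <- list(dim = dim(v))
  v
}
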