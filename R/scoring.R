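# Assay-independent cell positivity criteria and per-sample tumor
# proportion scoring. Every cell, whatever the assay, is tested against the
# same two feature thresholds; the sample score is the percentage of tumor
# cells (immune cells excluded) with a positive membrane stain.

#' Cell positivity thresholds
#'
#' A cell is positive when its membrane-to-overall DAB ratio exceeds
#' `t_ratio` AND its mean membrane DAB exceeds `t_mem_dab` (both strict
#' inequalities). The defaults, ratio > 1.02 and membrane DAB > 17.72, are
#' the values obtained by correlation-maximising threshold optimization on
#' an NSCLC reference cohort; they are meaningful only on this package's
#' declared intensity scale (OD 1.0 = 85) and should be re-fitted with
#' [optimize_thresholds()] for any other scale or staining protocol.
#'
#' @param t_ratio unitless membrane/overall DAB ratio threshold (> 0).
#' @param t_mem_dab membrane DAB threshold on the `[0, 255]` scale (>= 0).
#' @return an object of class `positivity_thresholds`.
#' @export
positivity_thresholds <- function(t_ratio = 1.02, t_mem_dab = 17.72) {
  stopifnot(t_ratio > 0, t_mem_dab >= 0)
  structure(list(t_ratio = t_ratio, t_mem_dab = t_mem_dab),
            class = "positivity_thresholds")
}

#' @export
print.positivity_thresholds <- function(x, ...) {
  cat(sprintf("<positivity_thresholds> ratio > %.3f and membrane DAB > %.2f\n",
              x$t_ratio, x$t_mem_dab))
  invisible(x)
}

#' Test cells against the positivity criteria
#'
#' Vectorised over a cell table. Immune cells always return `FALSE`: they
#' never contribute positives to the tumor proportion score.
#'
#' @param cells a `cell_objects` object or data frame with columns
#'   `feat_ratio`, `feat_mem_dab` and `class`.
#' @param thresholds a [positivity_thresholds()] object.
#' @return logical vector, one element per cell.
#' @export
cell_positive <- function(cells, thresholds = positivity_thresholds()) {
  df <- if (inherits(cells, "cell_objects")) cells$cells else cells
  pos <- df$feat_ratio > thresholds$t_ratio & df$feat_mem_dab > thresholds$t_mem_dab
  pos & (is.na(df$class) | df$class == "tumor") & !is.na(pos)
}

#' Score one sample: % positive tumor cells
#'
#' Counts only cells classified as tumor. A sample with fewer than
#' `min_cells` tumor cells is reported but flagged invalid (score withheld
#' as `NA`); zero tumor cells is an invalid sample, not a division error.
#'
#' @param cells cells of one sample, already classified and restricted to
#'   the comparable region (a `cell_objects` object or data frame).
#' @param thresholds a [positivity_thresholds()] object.
#' @param min_cells minimum tumor-cell count for a valid score.
#' @param sample_id,assay,rater identifiers carried into the score row.
#' @return a one-row data frame: `sample_id, assay, rater, score,
#'   n_tumor_cells, n_positive, valid`.
#' @export
sample_score <- function(cells, thresholds = positivity_thresholds(),
                         min_cells = 100, sample_id = NA_character_,
                         assay = NA_character_, rater = "IA") {
  df <- if (inherits(cells, "cell_objects")) cells$cells else cells
  tumor <- !is.na(df$class) & df$class == "tumor"
  n_tumor <- sum(tumor)
  pos <- cell_positive(df, thresholds)
  n_pos <- sum(pos & tumor)
  valid <- n_tumor >= min_cells && n_tumor > 0
  data.frame(
    sample_id = sample_id, assay = assay, rater = rater,
    score = if (valid) 100 * n_pos / n_tumor else NA_real_,
    n_tumor_cells = n_tumor, n_positive = n_pos,
    valid = valid, stringsAsFactors = FALSE
  )
}
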