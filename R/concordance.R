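# Agreement statistics between two raters (assay x {image analysis,
# pathologist}): overall percentage agreement OPA = (TP + TN) / all samples,
# F1 = 2*TP / (2*TP + FN + FP), evaluated at single cutoff pairs or over the
# exhaustive 99 x 99 grid of cutoff pairs (1-99% in 1% steps).

#' Confusion counts for one cutoff pair
#'
#' A sample is called positive by a rater when its score is `>=` that
#' rater's cutoff (inclusive, matching clinical cutoff conventions such as
#' TC >= 1% or >= 50%; set `inclusive = FALSE` for strict `>`). Samples with
#' a missing score under either rater are dropped pairwise. FP and FN are
#' from rater A's perspective: FP means A positive, B negative.
#'
#' @param scores_a,scores_b paired numeric score vectors in `[0, 100]`
#'   (`NA` = invalid sample).
#' @param cutoff_a,cutoff_b cutoffs in percent.
#' @param inclusive logical; positivity is `score >= cutoff` when `TRUE`.
#' @return an object of class `confusion_counts`: list with `TP, TN, FP,
#'   FN, n, cutoff_a, cutoff_b`.
#' @export
#' @examples
#' confusion_counts(c(10, 40, 70), c(5, 45, 80), 25, 25)
confusion_counts <- function(scores_a, scores_b, cutoff_a, cutoff_b,
                             inclusive = TRUE) {
  stopifnot(length(scores_a) == length(scores_b))
  ok <- !is.na(scores_a) & !is.na(scores_b)
  a <- scores_a[ok]; b <- scores_b[ok]
  pa <- if (inclusive) a >= cutoff_a else a > cutoff_a
  pb <- if (inclusive) b >= cutoff_b else b > cutoff_b
  structure(list(
    TP = sum(pa & pb), TN = sum(!pa & !pb),
    FP = sum(pa & !pb), FN = sum(!pa & pb),
    n = length(a), cutoff_a = cutoff_a, cutoff_b = cutoff_b
  ), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> cutoffs (%s%%, %s%%): TP %d, TN %d, FP %d, FN %d (n = %d)\n",
              format(x$cutoff_a), format(x$cutoff_b), x$TP, x$TN, x$FP, x$FN, x$n))
  invisible(x)
}

#' Overall percentage agreement
#'
#' `OPA = (TP + TN) / (all samples)`: the fraction of samples on which the
#' two raters' binary calls agree.
#'
#' @param counts a [confusion_counts()] object.
#' @return OPA in `[0, 1]`, or `NA` when no samples were scored by both.
#' @export
opa <- function(counts) {
  n <- counts$TP + counts$TN + counts$FP + counts$FN
  if (n == 0) return(NA_real_)
  (counts$TP + counts$TN) / n
}

#' F1 concordance of positive calls
#'
#' `F1 = 2*TP / (2*TP + FN + FP)`. Symmetric in FP and FN, hence invariant
#' under swapping the two raters. Undefined (returns `NA`) when
#' `TP = FP = FN = 0`, i.e. when neither rater calls any sample positive:
#' 0/0 is no evidence of discordance.
#'
#' @param counts a [confusion_counts()] object.
#' @return F1 in `[0, 1]`, or `NA` when undefined.
#' @export
f1 <- function(counts) {
  denom <- 2 * counts$TP + counts$FN + counts$FP
  if (denom == 0) return(NA_real_)
  2 * counts$TP / denom
}

#' Concordance grid over all cutoff pairs
#'
#' Evaluates F1 or OPA at every cutoff pair on a 1-99% grid in 1% steps
#' (9801 cells). Undefined F1 cells are `NA`, never zero-filled.
#'
#' @param scores_a,scores_b paired score vectors (`NA` dropped pairwise).
#' @param metric `"F1"` or `"OPA"`.
#' @param cutoffs integer cutoffs defining both axes.
#' @param inclusive see [confusion_counts()].
#' @return an object of class `concordance_grid`: a `length(cutoffs)` square
#'   matrix (rows = cutoff for rater A, columns = rater B) with attributes
#'   `metric`, `cutoffs` and `n`.
#' @export
concordance_grid <- function(scores_a, scores_b, metric = c("F1", "OPA"),
                             cutoffs = 1:99, inclusive = TRUE) {
  metric <- match.arg(metric)
  stopifnot(length(scores_a) == length(scores_b))
  ok <- !is.na(scores_a) & !is.na(scores_b)
  a <- scores_a[ok]; b <- scores_b[ok]
  n <- length(a)
  cmp <- if (inclusive) `>=` else `>`
  A <- outer(a, cutoffs, cmp) * 1  # n x k indicator matrices
  B <- outer(b, cutoffs, cmp) * 1
  TP <- crossprod(A, B)
  FP <- crossprod(A, 1 - B)
  FN <- crossprod(1 - A, B)
  TN <- n - TP - FP - FN
  vals <- if (metric == "F1") {
    denom <- 2 * TP + FP + FN
    out <- 2 * TP / denom
    out[denom == 0] <- NA_real_
    out
  } else {
    if (n == 0) matrix(NA_real_, length(cutoffs), length(cutoffs))
    else (TP + TN) / n
  }
  dimnames(vals) <- list(cutoff_a = cutoffs, cutoff_b = cutoffs)
  structure(vals, metric = metric, cutoffs = cutoffs, n = n,
            class = c("concordance_grid", "matrix"))
}

#' @export
print.concordance_grid <- function(x, ...) {
  v <- unclass(x)
  cat(sprintf("<concordance_grid> %s, %d x %d cutoff pairs (%d-%d%%), n = %d; %d undefined cell(s)\n",
              attr(x, "metric"), nrow(v), ncol(v), min(attr(x, "cutoffs")),
              max(attr(x, "cutoffs")), attr(x, "n"), sum(is.na(v))))
  cat(sprintf("  matched-cutoff (diagonal) range: [%.3f, %.3f]\n",
              suppressWarnings(min(diag(v), na.rm = TRUE)),
              suppressWarnings(max(diag(v), na.rm = TRUE))))
  invisible(x)
}

#' Matched-cutoff curve (grid diagonal)
#'
#' The metric evaluated at 1:1 matched cutoffs, i.e. the diagonal of a
#' concordance grid.
#'
#' @param grid a [concordance_grid()].
#' @return data frame with `cutoff` and `value`.
#' @export
matched_cutoff_curve <- function(grid) {
  stopifnot(inherits(grid, "concordance_grid"))
  data.frame(cutoff = attr(grid, "cutoffs"), value = diag(unclass(grid)))
}

#' Correlation summary between two raters' continuous scores
#'
#' Pearson and Spearman correlations plus the least-squares line of B on A,
#' on pairwise-complete scores.
#'
#' @param scores_a,scores_b paired score vectors.
#' @return list of class `score_correlations`: `pearson`, `spearman`,
#'   `slope`, `intercept`, `n`.
#' @export
score_correlations <- function(scores_a, scores_b) {
  ok <- !is.na(scores_a) & !is.na(scores_b)
  a <- scores_a[ok]; b <- scores_b[ok]
  if (length(a) < 3 || stats::sd(a) == 0 || stats::sd(b) == 0)
    return(structure(list(pearson = NA_real_, spearman = NA_real_,
                          slope = NA_real_, intercept = NA_real_, n = length(a)),
                     class = "score_correlations"))
  fit <- stats::lm.fit(cbind(1, a), b)
  structure(list(
    pearson = stats::cor(a, b, method = "pearson"),
    spearman = stats::cor(a, b, method = "spearman"),
    slope = fit$coefficients[[2]], intercept = fit$coefficients[[1]],
    n = length(a)
  ), class = "score_correlations")
}

#' @export
print.score_correlations <- function(x, ...) {
  cat(sprintf("<score_correlations> n = %d: Pearson %.3f, Spearman %.3f, fit b = %.3f a %+.2f\n",
              x$n, x$pearson, x$spearman, x$slope, x$intercept))
  invisible(x)
}

#' Pivot a long score table into paired scores for two raters
#'
#' @param score_table data frame with columns `sample_id, assay, rater,
#'   score, valid` (the ScoreTable layout used throughout the package).
#' @param assay_a,rater_a,assay_b,rater_b identifiers of the two raters.
#' @return data frame `sample_id, score_a, score_b`, one row per sample
#'   scored by both (invalid scores become `NA`).
#' @export
pair_scores <- function(score_table, assay_a, rater_a, assay_b, rater_b) {
  pick <- function(assay, rater) {
    s <- score_table[score_table$assay == assay & score_table$rater == rater, ]
    s$score[!(s$valid %||% TRUE)] <- NA_real_
    s[, c("sample_id", "score")]
  }
  a <- pick(assay_a, rater_a); b <- pick(assay_b, rater_b)
  m <- merge(a, b, by = "sample_id", suffixes = c("_a", "_b"))
  names(m) <- c("sample_id", "score_a", "score_b")
  m
}
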