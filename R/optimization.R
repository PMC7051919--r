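# Threshold-optimization workflow: cells are segmented once regardless of
# stain and their features frozen; positivity thresholds are then swept over
# an exhaustive grid, each candidate rescoring every sample from the feature
# table alone, and the pair maximising correlation with a reference assay's
# scores on a training split is selected. The held-out split reports
# generalization but never influences selection.

#' Rescore samples from a frozen feature table
#'
#' Pure table operation (no image access): a cell is positive when
#' `feat_ratio > t_ratio` and `feat_mem_dab > t_mem_dab`; the sample score
#' is the percentage of its tumor cells that are positive.
#'
#' @param table feature table: data frame with columns `sample_id`,
#'   `feat_ratio`, `feat_mem_dab`, `class` (one row per segmented cell).
#' @param thresholds a [positivity_thresholds()] object.
#' @return data frame `sample_id, score, n_tumor_cells`, one row per sample
#'   (samples ordered by first appearance).
#' @export
rescore_with_thresholds <- function(table, thresholds) {
  stopifnot(all(c("sample_id", "feat_ratio", "feat_mem_dab", "class") %in% names(table)))
  tum <- table[table$class == "tumor", ]
  sid <- factor(tum$sample_id, levels = unique(tum$sample_id))
  pos <- tum$feat_ratio > thresholds$t_ratio &
    tum$feat_mem_dab > thresholds$t_mem_dab
  n <- tabulate(sid)
  npos <- as.vector(rowsum(as.numeric(pos), as.integer(sid)))
  data.frame(sample_id = levels(sid), score = 100 * npos / n,
             n_tumor_cells = n, stringsAsFactors = FALSE)
}

#' Split sample ids into training and testing groups
#'
#' @param sample_ids character vector of unique sample ids.
#' @param fraction training fraction.
#' @param seed integer seed; the split is deterministic per seed.
#' @return list with `train` and `test` (disjoint, exhaustive).
#' @export
split_cohort <- function(sample_ids, fraction = 0.5, seed = 1) {
  stopifnot(fraction > 0, fraction < 1, !anyDuplicated(sample_ids))
  n_train <- round(length(sample_ids) * fraction)
  train <- with_seed(seed, sample(sample_ids, n_train))
  list(train = sort(train), test = sort(setdiff(sample_ids, train)))
}

#' Exhaustive threshold search against a reference assay
#'
#' Evaluates every `(t_ratio, t_mem_dab)` pair on the grid, rescoring the
#' feature table and correlating the resulting sample scores with the
#' reference scores on the training samples. Ties on the objective break
#' toward larger `t_mem_dab`, then larger `t_ratio` (the most conservative
#' of the equally good rules). The full search trace is returned.
#'
#' @param table feature table as in [rescore_with_thresholds()].
#' @param reference reference scores: data frame `sample_id, score` or a
#'   named numeric vector. Must cover at least the training samples.
#' @param ratio_grid,dab_grid candidate thresholds (exhaustively crossed).
#' @param split either a list with `train`/`test` id vectors or a fraction
#'   passed to [split_cohort()].
#' @param seed seed for the split when `split` is a fraction.
#' @param objective correlation type to maximise.
#' @return an object of class `threshold_search`: list with `best`
#'   ([positivity_thresholds()]), `objective_train`, `objective_test`,
#'   `search_grid` (trace data frame), `split`, `objective`.
#' @export
optimize_thresholds <- function(table, reference,
                                ratio_grid = seq(0.90, 1.30, by = 0.02),
                                dab_grid = seq(0, 80, by = 2),
                                split = 0.5, seed = 1,
                                objective = c("pearson", "spearman")) {
  objective <- match.arg(objective)
  ref <- if (is.data.frame(reference))
    stats::setNames(reference$score, reference$sample_id)
  else reference
  ids <- unique(table$sample_id[table$class == "tumor"])
  if (is.numeric(split) && length(split) == 1)
    split <- split_cohort(ids, fraction = split, seed = seed)
  train <- intersect(split$train, ids)
  test <- intersect(split$test, ids)
  if (!all(train %in% names(ref)))
    stop("reference scores must cover all training samples")
  if (length(train) < 3 || stats::sd(ref[train]) == 0)
    stop("degenerate reference: constant or too few training scores")

  tum <- table[table$class == "tumor", ]
  sid <- factor(tum$sample_id, levels = ids)
  n_cells <- tabulate(sid)
  in_train <- ids %in% train
  in_test <- ids %in% test
  ref_train <- ref[ids[in_train]]
  ref_test <- if (all(test %in% names(ref))) ref[ids[in_test]] else NULL

  grid <- expand.grid(t_ratio = ratio_grid, t_mem_dab = dab_grid,
                      KEEP.OUT.ATTRS = FALSE)
  obj_train <- obj_test <- numeric(nrow(grid))
  ratio_ok_cache <- lapply(ratio_grid, function(tr) tum$feat_ratio > tr)
  names(ratio_ok_cache) <- as.character(ratio_grid)
  for (g in seq_len(nrow(grid))) {
    pos <- ratio_ok_cache[[as.character(grid$t_ratio[g])]] &
      tum$feat_mem_dab > grid$t_mem_dab[g]
    scores <- 100 * as.vector(rowsum(as.numeric(pos), as.integer(sid))) / n_cells
    obj_train[g] <- suppressWarnings(
      stats::cor(scores[in_train], ref_train, method = objective))
    obj_test[g] <- if (is.null(ref_test)) NA_real_ else suppressWarnings(
      stats::cor(scores[in_test], ref_test, method = objective))
  }
  obj_train[is.na(obj_train)] <- -Inf
  # ties toward larger t_mem_dab, then larger t_ratio
  ord <- order(obj_train, grid$t_mem_dab, grid$t_ratio, decreasing = TRUE)
  best_i <- ord[1]
  trace <- data.frame(grid, objective_train = obj_train,
                      objective_test = obj_test)
  trace$objective_train[!is.finite(trace$objective_train)] <- NA_real_
  structure(list(
    best = positivity_thresholds(grid$t_ratio[best_i], grid$t_mem_dab[best_i]),
    objective_train = trace$objective_train[best_i],
    objective_test = obj_test[best_i],
    search_grid = trace, split = split, objective = objective
  ), class = "threshold_search")
}

#' @export
print.threshold_search <- function(x, ...) {
  cat(sprintf("<threshold_search> best: ratio > %.3f, membrane DAB > %.2f (%s train %.4f / test %s over %d grid points)\n",
              x$best$t_ratio, x$best$t_mem_dab, x$objective, x$objective_train,
              ifelse(is.na(x$objective_test), "NA", sprintf("%.4f", x$objective_test)),
              nrow(x$search_grid)))
  invisible(x)
}

#' Skewness of the F1 ridge relative to the matched-cutoff diagonal
#'
#' For each cutoff of rater A, finds the cutoff of rater B maximising F1
#' (the ridge of the grid) and reports the mean signed offset of the ridge
#' from the diagonal. F1 plateaus are common -- any cutoff falling in the
#' same inter-sample gap gives identical counts -- so within a plateau of
#' maximal F1 the cutoff closest to the diagonal is taken; two raters with
#' identical scores therefore have offset exactly zero. A rater that
#' systematically under-scores relative to the other displaces the ridge
#' off the diagonal; successful threshold optimization should shrink the
#' offset toward zero.
#'
#' @param scores_a,scores_b paired score vectors, or `grid` a precomputed F1
#'   [concordance_grid()].
#' @param grid optional precomputed grid (overrides the score vectors).
#' @return an object of class `ridge_skewness`: list with `mean_offset`
#'   (percentage points; positive when rater B's best cutoffs sit above
#'   rater A's), `n_rows` (rows with a defined ridge), and `ridge` (per-row
#'   data frame).
#' @export
skewness_check <- function(scores_a = NULL, scores_b = NULL, grid = NULL) {
  if (is.null(grid)) grid <- concordance_grid(scores_a, scores_b, metric = "F1")
  stopifnot(identical(attr(grid, "metric"), "F1"))
  cutoffs <- attr(grid, "cutoffs")
  v <- unclass(grid)
  rows <- lapply(seq_along(cutoffs), function(i) {
    r <- v[i, ]
    # rows with no positive agreement anywhere (max F1 = 0 or undefined)
    # carry no ridge information
    if (all(is.na(r)) || max(r, na.rm = TRUE) <= 0) return(NULL)
    m <- max(r, na.rm = TRUE)
    at <- which(!is.na(r) & r >= m - 1e-12)
    best <- cutoffs[at[which.min(abs(cutoffs[at] - cutoffs[i]))]]
    data.frame(cutoff_a = cutoffs[i], best_cutoff_b = best, f1_max = m)
  })
  ridge <- do.call(rbind, rows)
  if (is.null(ridge))
    return(structure(list(mean_offset = NA_real_, n_rows = 0L,
                          ridge = data.frame()), class = "ridge_skewness"))
  offset <- ridge$best_cutoff_b - ridge$cutoff_a
  structure(list(mean_offset = mean(offset), n_rows = nrow(ridge),
                 ridge = ridge), class = "ridge_skewness")
}

#' @export
print.ridge_skewness <- function(x, ...) {
  cat(sprintf("<ridge_skewness> mean ridge offset %+.2f percentage points over %d cutoff rows\n",
              x$mean_offset, x$n_rows))
  invisible(x)
}

#' Simulate a feature-level cohort with a planted positivity rule
#'
#' Generates per-cell `(feat_ratio, feat_mem_dab)` tables without rendering
#' images: each sample draws its own feature distributions (Beta-shaped,
#' spanning the full ratio and DAB ranges), "measured" features add small
#' Gaussian noise on top of the latent ones, and reference scores are
#' computed from the noise-free features under `rule`. An optional
#' `dab_gain` scales the measured DAB of a second, less sensitive assay.
#'
#' @param n_samples,cells_per_sample cohort dimensions.
#' @param rule the planted [positivity_thresholds()].
#' @param noise_sd_ratio,noise_sd_dab measurement noise on the two features.
#' @param dab_gain multiplicative DAB sensitivity of the measured features.
#' @param seed integer seed.
#' @return list with `table` (measured feature table), `reference` (data
#'   frame `sample_id, score` from the noise-free features under `rule`),
#'   and `rule`.
#' @export
simulate_feature_table <- function(n_samples = 100, cells_per_sample = 200,
                                   rule = positivity_thresholds(1.10, 30),
                                   noise_sd_ratio = 0.01, noise_sd_dab = 1.0,
                                   dab_gain = 1.0, seed = 1) {
  with_seed(seed, {
    rows <- vector("list", n_samples)
    refs <- numeric(n_samples)
    ids <- sprintf("sample_%03d", seq_len(n_samples))
    for (i in seq_len(n_samples)) {
      u <- stats::runif(1); v <- stats::runif(1)
      ratio <- 0.9 + 0.4 * stats::rbeta(cells_per_sample, 1 + 2 * u, 1 + 2 * (1 - u))
      dab <- 80 * stats::rbeta(cells_per_sample, 1 + 2 * v, 1 + 2 * (1 - v))
      pos_true <- ratio > rule$t_ratio & dab > rule$t_mem_dab
      refs[i] <- 100 * mean(pos_true)
      rows[[i]] <- data.frame(
        sample_id = ids[i],
        feat_ratio = ratio + stats::rnorm(cells_per_sample, 0, noise_sd_ratio),
        feat_mem_dab = pmax(dab_gain * dab +
                              stats::rnorm(cells_per_sample, 0, noise_sd_dab), 0),
        class = "tumor", stringsAsFactors = FALSE)
    }
  })
  list(table = do.call(rbind, rows),
       reference = data.frame(sample_id = ids, score = refs,
                              stringsAsFactors = FALSE),
       rule = rule)
}
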