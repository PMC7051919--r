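# Figure assembly: correlation scatters with regression lines, F1/OPA
# cutoff-pair heatmaps (undefined cells drawn distinctly), matched-cutoff
# curves, and before/after optimization panels with agreement bands.

#' Heatmap of a concordance grid
#'
#' @param grid a [concordance_grid()].
#' @param title plot title.
#' @return a ggplot object; undefined cells are drawn in grey.
#' @export
plot_concordance_grid <- function(grid, title = NULL) {
  cutoffs <- attr(grid, "cutoffs")
  df <- data.frame(
    cutoff_a = rep(cutoffs, times = length(cutoffs)),
    cutoff_b = rep(cutoffs, each = length(cutoffs)),
    value = as.vector(unclass(grid))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cutoff_a, y = .data$cutoff_b,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "grey85",
                                  name = attr(grid, "metric")) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title %||% sprintf("%s over cutoff pairs (n = %d)",
                                             attr(grid, "metric"), attr(grid, "n")),
                  x = "cutoff, rater A (%)", y = "cutoff, rater B (%)") +
    ggplot2::theme_minimal()
}

#' Scatter of two raters' scores with regression line and agreement bands
#'
#' @param scores_a,scores_b paired score vectors.
#' @param bands absolute agreement band half-widths (percentage points)
#'   drawn around the identity line, in increasing order.
#' @param labels axis labels.
#' @return a ggplot object.
#' @export
plot_score_scatter <- function(scores_a, scores_b, bands = c(25, 50),
                               labels = c("rater A (%)", "rater B (%)")) {
  ok <- !is.na(scores_a) & !is.na(scores_b)
  df <- data.frame(a = scores_a[ok], b = scores_b[ok])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$b))
  for (i in rev(seq_along(bands)))
    p <- p + ggplot2::geom_ribbon(
      data = data.frame(a = c(0, 100)),
      ggplot2::aes(x = .data$a, ymin = pmax(.data$a - bands[i], 0),
                   ymax = pmin(.data$a + bands[i], 100)),
      inherit.aes = FALSE, fill = "red", alpha = 0.08 * i)
  p +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "blue", linewidth = 0.6) +
    ggplot2::coord_fixed(xlim = c(0, 100), ylim = c(0, 100)) +
    ggplot2::labs(x = labels[1], y = labels[2]) +
    ggplot2::theme_minimal()
}

#' Matched-cutoff curve plot
#'
#' @param curve data frame from [matched_cutoff_curve()] (or several row-bound
#'   together with an extra `pair` column).
#' @return a ggplot object.
#' @export
plot_matched_cutoff_curve <- function(curve) {
  aes <- if ("pair" %in% names(curve))
    ggplot2::aes(x = .data$cutoff, y = .data$value, colour = .data$pair)
  else ggplot2::aes(x = .data$cutoff, y = .data$value)
  ggplot2::ggplot(curve, aes) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "matched cutoff (%)", y = "F1 at 1:1 matched cutoffs") +
    ggplot2::theme_minimal()
}

#' Assemble the figures of a pipeline run into PNG files
#'
#' Reads the run's score table and grids and writes correlation scatters,
#' heatmaps and matched-cutoff curves under `<out_dir>/figures/`.
#'
#' @param run a `pipeline_run` object (or an `out_dir` containing one).
#' @return invisibly, the written file paths.
#' @export
render_report <- function(run) {
  out_dir <- if (is.character(run)) run else run$out_dir
  fig_dir <- file.path(out_dir, "figures")
  dir.create(fig_dir, showWarnings = FALSE, recursive = TRUE)
  score_table <- read_score_table(file.path(out_dir, "scores.csv"))
  config <- read_config(file.path(out_dir, "config_resolved.yaml"))
  reader_name <- config$readers[[1]]$name
  written <- character(0)
  save_plot <- function(p, name) {
    f <- file.path(fig_dir, name)
    grDevices::png(f, width = 900, height = 800, res = 130)
    print(p)
    grDevices::dev.off()
    written <<- c(written, f)
  }
  for (an in unique(score_table$assay)) {
    pr <- pair_scores(score_table, an, "IA", an, reader_name)
    if (nrow(pr) < 3 || all(is.na(pr$score_b))) next
    cc <- score_correlations(pr$score_a, pr$score_b)
    save_plot(plot_score_scatter(pr$score_a, pr$score_b,
                                 labels = c("image analysis (%)",
                                            sprintf("%s (%%)", reader_name))) +
                ggplot2::ggtitle(sprintf("%s: r = %.3f, rho = %.3f (n = %d)", an,
                                         cc$pearson, cc$spearman, cc$n)),
              sprintf("scatter_%s_IA_vs_reader.png", an))
    g <- concordance_grid(pr$score_a, pr$score_b, metric = "F1")
    save_plot(plot_concordance_grid(g, sprintf("%s: F1, IA vs %s", an, reader_name)),
              sprintf("f1_heatmap_%s_IA_vs_reader.png", an))
    save_plot(plot_matched_cutoff_curve(matched_cutoff_curve(g)) +
                ggplot2::ggtitle(sprintf("%s: matched cutoffs", an)),
              sprintf("matched_curve_%s.png", an))
  }
  invisible(written)
}
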