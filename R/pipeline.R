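# Pipeline orchestration and file formats. CSV for tabular data, JSON for
# geometry (polygons, transforms), YAML for configuration, PNG/TIFF for
# images. A run is reproducible from (config, seed) alone; the resolved
# configuration is written next to its outputs, and every sample that fails
# a stage is excluded with a recorded reason rather than crashing the run.

#' Default pipeline configuration
#'
#' One nested list holding every tunable of the pipeline: cohort and
#' rendering parameters, segmentation and classification settings, the
#' positivity thresholds, and the concordance options. All randomness flows
#' from the single root `seed` through named substreams.
#'
#' @param seed root seed.
#' @param n_samples,n_cells,immune_fraction,field_size cohort parameters.
#' @return a list of class `pipeline_config`.
#' @export
default_config <- function(seed = 1, n_samples = 6, n_cells = 250,
                           immune_fraction = 0.2, field_size = c(768, 768)) {
  structure(list(
    seed = seed,
    cohort = list(n_samples = n_samples, n_cells = n_cells,
                  immune_fraction = immune_fraction,
                  field_size = field_size,
                  tps = list(zero_weight = 0.35, shape1 = 0.6, shape2 = 1.6)),
    profiles = lapply(default_assay_profiles(), unclass),
    readers = list(list(name = "pathologist", bias = 0, sd = 5,
                        heteroscedastic = FALSE)),
    segmentation = list(smooth_sigma = 1, threshold = "otsu", min_area = 20,
                        watershed_tolerance = 1,
                        ring_offset = 2, ring_width = 3),
    classification = list(area_cutoff = 80, circularity_cutoff = 0.6),
    thresholds = list(t_ratio = 1.02, t_mem_dab = 17.72),
    min_cells = 100,
    concordance = list(inclusive = TRUE)
  ), class = "pipeline_config")
}

#' @rdname default_config
#' @param path YAML file path.
#' @param config a `pipeline_config` list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname default_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- unclass(default_config())
  merged <- utils::modifyList(base, cfg)
  # list-valued sections are taken wholesale, not merged element-wise
  for (field in c("profiles", "readers"))
    if (!is.null(cfg[[field]])) merged[[field]] <- cfg[[field]]
  structure(merged, class = "pipeline_config")
}

config_profiles <- function(config) {
  lapply(config$profiles, function(p) do.call(assay_profile, p))
}

config_readers <- function(config) {
  lapply(config$readers, function(r) do.call(reader_model, r))
}

# --- image files -------------------------------------------------------------

#' Read and write 8-bit RGB images (PNG or flat TIFF)
#'
#' The format follows the file extension. Images are H x W x 3 arrays with
#' values 0-255.
#'
#' @param image H x W x 3 array.
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @name image_io
#' @export
write_image <- function(image, path) {
  assert_rgb8(image)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") png::writePNG(image / 255, path)
  else if (ext %in% c("tif", "tiff")) tiff::writeTIFF(image / 255, path,
                                                      bits.per.sample = 8L)
  else stop("unsupported image extension: ", ext)
  invisible(path)
}

#' @rdname image_io
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") png::readPNG(path)
  else if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
  else stop("unsupported image extension: ", ext)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), dim = c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3]
  round(img * 255)
}

# --- score tables ------------------------------------------------------------

score_table_columns <- c("sample_id", "assay", "rater", "score",
                         "n_tumor_cells", "valid")

#' Read and write per-sample score tables (CSV)
#'
#' The ScoreTable schema is `sample_id, assay, rater, score, n_tumor_cells,
#' valid`; scores must lie in `[0, 100]` (or be `NA` for invalid samples).
#' Reading and writing validate the schema and round-trip exactly.
#'
#' @param table a score-table data frame.
#' @param path CSV file path.
#' @name score_table_io
#' @export
write_score_table <- function(table, path) {
  validate_score_table(table)
  utils::write.csv(table[, score_table_columns], path, row.names = FALSE)
  invisible(path)
}

#' @rdname score_table_io
#' @export
read_score_table <- function(path) {
  tb <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_score_table(tb)
  tb
}

validate_score_table <- function(table) {
  missing <- setdiff(score_table_columns, names(table))
  if (length(missing))
    stop("score table is missing column(s): ", paste(missing, collapse = ", "))
  bad <- !is.na(table$score) & (table$score < 0 | table$score > 100)
  if (any(bad))
    stop("score table contains scores outside [0, 100]")
  invisible(table)
}

#' Write and read a concordance grid as CSV
#'
#' Flat long format: `cutoff_a, cutoff_b, value` (undefined cells empty).
#'
#' @param grid a [concordance_grid()].
#' @param path CSV path.
#' @name grid_io
#' @export
write_grid_csv <- function(grid, path) {
  cutoffs <- attr(grid, "cutoffs")
  df <- data.frame(
    cutoff_a = rep(cutoffs, times = length(cutoffs)),
    cutoff_b = rep(cutoffs, each = length(cutoffs)),
    value = as.vector(unclass(grid))
  )
  attr_line <- sprintf("# metric=%s n=%d", attr(grid, "metric"), attr(grid, "n"))
  con <- file(path, "w")
  writeLines(attr_line, con)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname grid_io
#' @export
read_grid_csv <- function(path) {
  header <- readLines(path, n = 1)
  metric <- sub(".*metric=(\\S+).*", "\\1", header)
  n <- as.integer(sub(".*n=(\\d+).*", "\\1", header))
  df <- utils::read.csv(path, skip = 1)
  cutoffs <- sort(unique(df$cutoff_a))
  v <- matrix(NA_real_, length(cutoffs), length(cutoffs),
              dimnames = list(cutoff_a = cutoffs, cutoff_b = cutoffs))
  v[cbind(match(df$cutoff_a, cutoffs), match(df$cutoff_b, cutoffs))] <- df$value
  structure(v, metric = metric, cutoffs = cutoffs, n = n,
            class = c("concordance_grid", "matrix"))
}

# --- analysis of one image ---------------------------------------------------

#' Run the image-analysis scoring chain on one RGB field
#'
#' Deconvolution, nucleus segmentation, membrane-ring feature extraction,
#' tumor/immune classification and sample scoring, all driven by one
#' configuration list.
#'
#' @param image H x W x 3 array (0-255) or a path readable by
#'   [read_image()].
#' @param config a [default_config()]-style list.
#' @param sample_id,assay identifiers for the score row.
#' @param region_mask optional comparable-region mask; only cells whose
#'   nucleus centroid falls inside it are scored.
#' @return list with `cells` (a `cell_objects` object), `score` (one-row
#'   score data frame) and `stains`.
#' @export
score_slide_image <- function(image, config = default_config(),
                              sample_id = NA_character_, assay = NA_character_,
                              region_mask = NULL) {
  if (is.character(image)) image <- read_image(image)
  seg <- config$segmentation
  stains <- deconvolve_stains(image)
  labels <- segment_nuclei(stains, segmentation_params(
    smooth_sigma = seg$smooth_sigma, threshold = seg$threshold,
    min_area = seg$min_area, watershed_tolerance = seg$watershed_tolerance))
  cells <- build_cell_objects(labels, stains, ring_offset = seg$ring_offset,
                              ring_width = seg$ring_width)
  cells <- classify_cells(cells, config$classification$area_cutoff,
                          config$classification$circularity_cutoff)
  scored_cells <- if (is.null(region_mask)) cells$cells
  else cells_in_region(cells, region_mask)
  th <- positivity_thresholds(config$thresholds$t_ratio,
                              config$thresholds$t_mem_dab)
  sc <- sample_score(scored_cells, th, min_cells = config$min_cells,
                     sample_id = sample_id, assay = assay, rater = "IA")
  list(cells = cells, score = sc, stains = stains)
}

# --- full pipeline -----------------------------------------------------------

#' Run the full synthetic-cohort pipeline
#'
#' Stages, in dependency order: `simulate` (generate the cohort, write
#' images, planted truth and simulated pathologist reads), `analyze` (read
#' each image back from disk and run the image-analysis scoring chain;
#' failures exclude the sample with a recorded reason), `concord` (pairwise
#' correlation summaries and F1/OPA grids between assays and between image
#' analysis and the simulated reader). Stages communicate only through the
#' documented file formats under `out_dir`.
#'
#' @param config a [default_config()]-style list.
#' @param out_dir output directory (created if needed).
#' @param stages character subset of `c("simulate", "analyze", "concord")`;
#'   later stages re-read earlier stages' outputs from `out_dir`.
#' @return list of class `pipeline_run`: `manifest` (per sample x assay:
#'   status and reason), `score_table`, `paths`, `config`.
#' @export
run_pipeline <- function(config = default_config(), out_dir,
                         stages = c("simulate", "analyze", "concord")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  img_dir <- file.path(out_dir, "images")
  paths <- list(
    config = file.path(out_dir, "config_resolved.yaml"),
    truth = file.path(out_dir, "truth.csv"),
    reads = file.path(out_dir, "reads.csv"),
    scores = file.path(out_dir, "scores.csv"),
    cells = file.path(out_dir, "cell_features.csv"),
    manifest = file.path(out_dir, "manifest.csv"),
    correlations = file.path(out_dir, "correlations.json")
  )
  write_config(config, paths$config)
  assay_names <- names(config$profiles)

  if ("simulate" %in% stages) {
    dir.create(img_dir, showWarnings = FALSE)
    cohort <- generate_cohort(
      n_samples = config$cohort$n_samples,
      profiles = config_profiles(config),
      readers = config_readers(config),
      n_cells = config$cohort$n_cells,
      immune_fraction = config$cohort$immune_fraction,
      field_size = config$cohort$field_size,
      tps = config$cohort$tps,
      seed = config$seed, render = TRUE)
    for (sid in names(cohort$images))
      for (an in names(cohort$images[[sid]]))
        write_image(cohort$images[[sid]][[an]],
                    file.path(img_dir, sprintf("%s_%s.png", sid, an)))
    utils::write.csv(cohort$truth, paths$truth, row.names = FALSE)
    write_score_table(cohort$reads, paths$reads)
  }

  truth <- utils::read.csv(paths$truth, stringsAsFactors = FALSE)
  reads <- read_score_table(paths$reads)
  sample_ids <- unique(truth$sample_id)

  manifest <- expand.grid(sample_id = sample_ids, assay = assay_names,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  manifest$status <- "evaluable"; manifest$reason <- ""
  ia_rows <- list(); cell_rows <- list()

  if ("analyze" %in% stages) {
    for (k in seq_len(nrow(manifest))) {
      sid <- manifest$sample_id[k]; an <- manifest$assay[k]
      img_path <- file.path(img_dir, sprintf("%s_%s.png", sid, an))
      res <- tryCatch(
        score_slide_image(img_path, config, sample_id = sid, assay = an),
        error = function(e) e)
      if (inherits(res, "error")) {
        manifest$status[k] <- "excluded"
        manifest$reason[k] <- if (inherits(res, "registration_failed"))
          "registration failed" else if (!file.exists(img_path))
            "missing image" else "unreadable image"
        next
      }
      ia_rows[[length(ia_rows) + 1]] <- res$score
      cf <- res$cells$cells
      cf$sample_id <- sid; cf$assay <- an
      cell_rows[[length(cell_rows) + 1]] <-
        cf[, c("sample_id", "assay", "cell_id", "x", "y", "class",
               "feat_mem_dab", "feat_cell_dab", "feat_ratio", "nucleus_area")]
    }
    ia <- do.call(rbind, ia_rows)
    score_table <- if (is.null(ia)) reads[, score_table_columns]
    else rbind(ia[, score_table_columns], reads[, score_table_columns])
    write_score_table(score_table, paths$scores)
    if (length(cell_rows))
      utils::write.csv(do.call(rbind, cell_rows), paths$cells, row.names = FALSE)
    utils::write.csv(manifest, paths$manifest, row.names = FALSE)
  }

  if ("concord" %in% stages && file.exists(paths$scores)) {
    score_table <- read_score_table(paths$scores)
    reader_name <- config$readers[[1]]$name
    summaries <- list()
    for (an in assay_names) {
      pr <- pair_scores(score_table, an, "IA", an, reader_name)
      if (nrow(pr) >= 3) {
        cc <- score_correlations(pr$score_a, pr$score_b)
        summaries[[paste0(an, ":IA_vs_", reader_name)]] <- unclass(cc)
        g <- concordance_grid(pr$score_a, pr$score_b, metric = "F1")
        write_grid_csv(g, file.path(out_dir, sprintf("f1_grid_%s_IA_vs_reader.csv", an)))
      }
    }
    ref <- assay_names[1]
    for (an in setdiff(assay_names, ref)) {
      pr <- pair_scores(score_table, ref, "IA", an, "IA")
      if (nrow(pr) >= 3) {
        summaries[[paste0(ref, "_vs_", an, ":IA")]] <-
          unclass(score_correlations(pr$score_a, pr$score_b))
        for (metric in c("F1", "OPA")) {
          g <- concordance_grid(pr$score_a, pr$score_b, metric = metric)
          write_grid_csv(g, file.path(out_dir, sprintf("%s_grid_%s_vs_%s.csv",
                                                       tolower(metric), ref, an)))
        }
      }
    }
    jsonlite::write_json(summaries, paths$correlations, auto_unbox = TRUE,
                         digits = NA)
  }

  score_table <- if (file.exists(paths$scores)) read_score_table(paths$scores) else NULL
  structure(list(manifest = manifest, score_table = score_table,
                 paths = paths, out_dir = out_dir, config = config),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> %s: %d evaluable, %d excluded of %d sample x assay\n",
              x$out_dir, sum(x$manifest$status == "evaluable"),
              sum(x$manifest$status == "excluded"), nrow(x$manifest)))
  invisible(x)
}
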