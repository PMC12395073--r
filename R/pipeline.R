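# File-level orchestration: the entry points behind the command-line
# interface (inst/cli/cyclesim.R). Each step writes plain-text artifacts plus
# a JSON manifest sufficient to reproduce the run.

#' Simulate a cohort and write its files
#'
#' Writes `daily_timeseries.csv`, `subjects.csv`, `cycles.csv` and
#' `run_manifest.json` into `out_dir`.
#'
#' @param config a [sim_config()] (or path handled by [read_config()]).
#' @param out_dir output directory (created if absent).
#' @return file paths, invisibly.
#' @export
run_simulate <- function(config = sim_config(), out_dir = ".") {
  if (is.character(config)) config <- read_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ds <- simulate_cohort(config)
  paths <- file.path(out_dir, c("daily_timeseries.csv", "subjects.csv",
                                "cycles.csv", "run_manifest.json"))
  write_dataset(ds, paths[1])
  utils::write.csv(ds$subjects, paths[2], row.names = FALSE, quote = FALSE)
  utils::write.csv(ds$cycles, paths[3], row.names = FALSE, quote = FALSE)
  manifest <- list(
    package = "cyclesim",
    version = as.character(utils::packageVersion("cyclesim")),
    master_seed = config$master_seed,
    config = config[c("n_eumenorrheic", "n_pcos", "cycles_per_subject",
                      "grid_points_per_cycle")],
    outputs = basename(paths[1:3]),
    summary = list(n_records = nrow(ds$daily),
                   n_subjects = nrow(ds$subjects),
                   n_cycles = nrow(ds$cycles),
                   clip_rate = ds$clip_rate,
                   surge_rate = ds$surge_rate))
  jsonlite::write_json(manifest, paths[4], auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  message(sprintf(
    "simulated %d records (%d subjects, %d cycles); clip rate %.3f%%, EUM surge rate %.1f%%",
    nrow(ds$daily), nrow(ds$subjects), nrow(ds$cycles),
    100 * ds$clip_rate, 100 * ds$surge_rate))
  invisible(paths)
}

#' Aggregate a daily dataset file into per-subject features
#'
#' @param dataset_path path to a `daily_timeseries.csv`.
#' @param out_path output `features.csv` path.
#' @return the output path, invisibly.
#' @export
run_features <- function(dataset_path, out_path = "features.csv") {
  d <- read_dataset(dataset_path)
  ft <- feature_table(d)
  write_features(ft, out_path)
  message(sprintf("wrote %d feature rows to %s", nrow(ft), out_path))
  invisible(out_path)
}

#' Run the discrimination analysis on a features file
#'
#' Writes `analysis_report.json` and `pca_scores.csv` to `out_dir`.
#'
#' @param features_path path to `features.csv`.
#' @param out_dir output directory.
#' @param preset feature preset (`"pca6"` or `"full"`).
#' @param seed integer seed.
#' @return the `phenotype_analysis` object, invisibly.
#' @export
run_analyze <- function(features_path, out_dir = ".", preset = "pca6",
                        seed = 1) {
  ft <- utils::read.csv(features_path, stringsAsFactors = FALSE)
  if (length(unique(ft$phenotype)) < 2)
    stop("features file contains a single class; analysis needs both")
  class(ft) <- c("feature_table", class(ft))
  an <- analyze_features(ft, preset = preset, seed = seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  evr <- an$pca$explained_variance_ratio
  report <- list(
    preset = preset, seed = seed,
    pca_explained_variance_ratio = evr,
    pca_pc1_pc2 = sum(evr[1:2]),
    kmeans_k = an$k, kmeans_agreement = an$kmeans$agreement,
    accuracy = an$classification$accuracy,
    sensitivity = an$classification$sensitivity,
    specificity = an$classification$specificity,
    auc = an$classification$auc,
    confusion = as.list(an$classification$confusion),
    n_train = an$classification$n_train,
    n_test = an$classification$n_test)
  jsonlite::write_json(report, file.path(out_dir, "analysis_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  sc <- data.frame(subject_id = ft$subject_id, phenotype = ft$phenotype,
                   PC1 = an$pca$scores[, 1], PC2 = an$pca$scores[, 2])
  utils::write.csv(sc, file.path(out_dir, "pca_scores.csv"),
                   row.names = FALSE, quote = FALSE)
  message(sprintf(
    "PC1+PC2 = %.1f%%; k-means agreement %.3f; accuracy %.3f, AUC %.3f",
    100 * sum(evr[1:2]), an$kmeans$agreement,
    an$classification$accuracy, an$classification$auc))
  invisible(an)
}

#' Full simulate -> features -> analyze chain
#'
#' @param config a [sim_config()].
#' @param out_dir output directory for all artifacts.
#' @param preset feature preset.
#' @param seed analysis seed (split, k-means).
#' @return the `phenotype_analysis`, invisibly.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = ".",
                         preset = "pca6", seed = 1) {
  run_simulate(config, out_dir)
  run_features(file.path(out_dir, "daily_timeseries.csv"),
               file.path(out_dir, "features.csv"))
  run_analyze(file.path(out_dir, "features.csv"), out_dir,
              preset = preset, seed = seed)
}
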