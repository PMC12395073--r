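# Subject-level feature aggregation: reduce each subject's daily records to
# the per-subject summary vector used for phenotype discrimination.

feature_hormones <- function() c(
  e2 = "Estradiol_pg_mL", e1 = "Estrone_pg_mL", fsh = "FSH_mIU_mL",
  lh = "LH_mIU_mL", amh = "AMH_ng_mL", t = "Testosterone_ng_mL",
  gnrh = "GnRH_AU")

#' Aggregate one subject's records into a feature vector
#'
#' Computes, over the concatenation of all that subject's cycles: per-hormone
#' mean, sample sd (n-1) and daily maximum; the LH/FSH and E1/E2 ratios of
#' means; phase-day proportions; and cycle-length mean and sd. With a single
#' cycle the length sd is reported as 0 (with a warning) so the feature
#' matrix stays complete.
#'
#' @param records daily records (rows of the long table) of one subject.
#' @return one-row `data.frame`.
#' @export
subject_features <- function(records) {
  if (!nrow(records)) stop("subject_features() needs at least one record")
  if (length(unique(records$subject_id)) != 1)
    stop("records must belong to a single subject")
  hs <- feature_hormones()
  out <- data.frame(subject_id = records$subject_id[1],
                    phenotype = records$phenotype[1],
                    stringsAsFactors = FALSE)
  for (nm in names(hs)) {
    v <- records[[hs[nm]]]
    out[[paste0(nm, "_mean")]] <- mean(v)
    out[[paste0(nm, "_sd")]] <- stats::sd(v)
    out[[paste0(nm, "_max")]] <- max(v)
  }
  out$lh_fsh_ratio <- out$lh_mean / out$fsh_mean
  out$e1_e2_ratio <- out$e1_mean / out$e2_mean
  for (ph in c("follicular", "peri-ovulatory", "luteal", "anovulatory")) {
    nm <- paste0("prop_", sub("-", "_", ph))
    out[[nm]] <- mean(records$phase == ph)
  }
  lens <- tapply(records$cycle_length_days, records$cycle_index,
                 function(v) v[1])
  out$cycle_length_mean <- mean(lens)
  if (length(lens) < 2) {
    warning("single cycle: cycle_length_sd reported as 0")
    out$cycle_length_sd <- 0
  } else out$cycle_length_sd <- stats::sd(lens)
  out
}

#' Build the per-subject feature table
#'
#' One [subject_features()] row per subject, ordered by subject id. Subjects
#' whose cycles differ in grid size are rejected (schema error).
#'
#' @param dataset a `cycle_dataset` or conforming daily data.frame.
#' @return `data.frame` of class `feature_table`: one row per subject, with
#'   a `phenotype` label column kept separate from the numeric features.
#' @export
feature_table <- function(dataset) {
  d <- if (inherits(dataset, "cycle_dataset")) dataset$daily else dataset
  if (!nrow(d)) stop("empty dataset")
  per_cycle <- tapply(d$day_index,
                      interaction(d$subject_id, d$cycle_index, drop = TRUE),
                      length)
  if (length(unique(per_cycle)) != 1)
    stop("schema error: cycles differ in grid size (",
         paste(unique(per_cycle), collapse = ", "), " records per cycle)")
  ids <- sort(unique(d$subject_id))
  rows <- lapply(ids, function(id)
    suppressWarnings(subject_features(d[d$subject_id == id, ])))
  ft <- do.call(rbind, rows)
  rownames(ft) <- NULL
  class(ft) <- c("feature_table", class(ft))
  ft
}

#' Select a feature preset
#'
#' `"pca6"` is the six mean hormone levels (E2, FSH, LH, AMH, testosterone,
#' GnRH) fed to PCA/k-means/classification; `"full"` is every numeric
#' aggregate (sds, maxima, ratios, phase proportions, cycle-length stats
#' included).
#'
#' @param features a [feature_table()].
#' @param preset `"pca6"` or `"full"`.
#' @return numeric matrix (rownames = subject ids).
#' @export
feature_matrix <- function(features, preset = c("pca6", "full")) {
  preset <- match.arg(preset)
  cols <- if (preset == "pca6") {
    c("e2_mean", "fsh_mean", "lh_mean", "amh_mean", "t_mean", "gnrh_mean")
  } else {
    setdiff(names(features)[vapply(features, is.numeric, logical(1))],
            character(0))
  }
  m <- as.matrix(features[, cols, drop = FALSE])
  rownames(m) <- features$subject_id
  m
}

#' Write the feature table as CSV
#'
#' @param features a [feature_table()].
#' @param path output CSV path.
#' @export
write_features <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
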