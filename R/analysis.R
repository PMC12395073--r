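# Phenotype-discrimination pipeline: standardization, PCA, k-means, and the
# stratified 70/30 logistic-regression evaluation.

#' Standardize a feature matrix
#'
#' Centers each column to mean 0 and scales to sample sd 1, returning the
#' transform parameters so they can be reused on held-out data (fit on train,
#' apply to test — never refit). Constant columns are an explicit error.
#'
#' @param x numeric matrix (subjects x features).
#' @param center,scale optional precomputed parameters (apply mode).
#' @return list with `x` (standardized matrix), `center`, `scale`.
#' @export
standardize <- function(x, center = NULL, scale = NULL) {
  x <- as.matrix(x)
  if (is.null(center)) {
    center <- colMeans(x)
    scale <- apply(x, 2, stats::sd)
    zero <- scale == 0 | is.na(scale)
    if (any(zero))
      stop("constant column(s) cannot be standardized: ",
           paste(colnames(x)[zero], collapse = ", "))
  }
  list(x = sweep(sweep(x, 2, center), 2, scale, "/"),
       center = center, scale = scale)
}

#' Principal component analysis of a standardized feature matrix
#'
#' Plain PCA via singular value decomposition of the (already standardized)
#' matrix. Component signs are fixed by making the largest-magnitude loading
#' of each component positive, so scores are reproducible across platforms.
#'
#' @param x standardized numeric matrix.
#' @param n_components number of components to keep in `scores`/`loadings`.
#' @return object of class `pca_result`: `scores` (subjects x components),
#'   `explained_variance_ratio` (all components), `loadings`
#'   (features x components), `n_components`.
#' @export
pca_project <- function(x, n_components = 2) {
  x <- as.matrix(x)
  if (n_components > ncol(x)) stop("n_components exceeds feature count")
  if (nrow(x) < n_components) stop("fewer subjects than components")
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  rot <- pc$rotation
  flip <- apply(rot, 2, function(v) sign(v[which.max(abs(v))]))
  rot <- sweep(rot, 2, flip, "*")
  scores <- x %*% rot
  structure(list(scores = scores[, seq_len(n_components), drop = FALSE],
                 explained_variance_ratio = evr,
                 loadings = rot[, seq_len(n_components), drop = FALSE],
                 rotation = rot, n_components = n_components),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  evr <- x$explained_variance_ratio
  cat(sprintf("PCA: %d components kept; explained variance: %s (PC1+PC2 = %.1f%%)\n",
              x$n_components,
              paste(sprintf("%.1f%%", 100 * evr[seq_len(x$n_components)]),
                    collapse = ", "),
              100 * sum(evr[1:min(2, length(evr))])))
  invisible(x)
}

#' k-means clustering with label-agreement score
#'
#' Seeded k-means with `nstart` restarts (best within-cluster sum of squares
#' kept). If true phenotype labels are supplied, reports the agreement: the
#' maximum, over assignments of clusters to classes, of the fraction of
#' subjects whose cluster maps to their true class (reporting only — the
#' clustering itself never sees labels).
#'
#' @param x standardized numeric matrix.
#' @param k number of clusters (>= 2).
#' @param seed integer seed.
#' @param labels optional true class labels (length nrow(x)).
#' @param nstart random restarts (default 10).
#' @return list with `cluster` (integer assignments), `agreement` (or `NA`),
#'   `kmeans` (the `stats::kmeans` fit).
#' @export
kmeans_cluster <- function(x, k = 2, seed = 1, labels = NULL, nstart = 10) {
  x <- as.matrix(x)
  if (k < 2) stop("k must be >= 2")
  if (k > nrow(x)) stop("k exceeds the number of subjects")
  km <- with_seed(seed, stats::kmeans(x, centers = k, nstart = nstart))
  agreement <- NA_real_
  if (!is.null(labels)) {
    stopifnot(length(labels) == nrow(x))
    classes <- unique(labels)
    # every mapping cluster -> class (k small; exhaustive)
    maps <- expand.grid(rep(list(classes), k), stringsAsFactors = FALSE)
    agreement <- max(apply(maps, 1, function(mp)
      mean(mp[km$cluster] == labels)))
  }
  list(cluster = km$cluster, agreement = agreement, kmeans = km)
}

auc_score <- function(scores, labels, positive) {
  # rank-based (Mann-Whitney) AUC; invariant to monotone score transforms
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  r <- rank(c(pos, neg))[seq_along(pos)]
  (sum(r) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Stratified train/test logistic-regression evaluation
#'
#' Splits subjects 70/30 stratified by phenotype, standardizes features on
#' the training subset only, fits a weakly L2-regularized logistic model
#' (ridge at a small fixed penalty — the unregularized MLE diverges on
#' perfectly separable synthetic classes; the reported metrics, not the
#' coefficients, are the contract), and evaluates on the held-out test set.
#' PCOS is the positive class for sensitivity/specificity.
#'
#' @param features numeric matrix (subjects x features), unstandardized.
#' @param labels phenotype labels (`"EUM"`/`"PCOS"`), length nrow(features).
#' @param train_fraction training share (default 0.7).
#' @param seed integer seed for the split.
#' @param positive positive class (default `"PCOS"`).
#' @param lambda ridge penalty (default 1e-3).
#' @return object of class `classification_report` with accuracy,
#'   sensitivity, specificity, auc, confusion counts, split sizes and seed.
#' @export
train_eval_logistic <- function(features, labels, train_fraction = 0.7,
                                seed = 1, positive = "PCOS", lambda = 1e-3) {
  x <- as.matrix(features)
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(x))
  classes <- unique(labels)
  if (length(classes) < 2) stop("both classes must be present")
  idx_train <- with_seed(seed, {
    unlist(lapply(classes, function(cl) {
      ix <- which(labels == cl)
      sample(ix, round(train_fraction * length(ix)))
    }))
  })
  idx_test <- setdiff(seq_len(nrow(x)), idx_train)
  if (length(unique(labels[idx_train])) < 2 ||
      length(unique(labels[idx_test])) < 2)
    stop("a class is absent from the train or test split")
  st <- standardize(x[idx_train, , drop = FALSE])
  xtr <- st$x
  xte <- standardize(x[idx_test, , drop = FALSE], st$center, st$scale)$x
  ytr <- as.integer(labels[idx_train] == positive)
  fit <- glmnet::glmnet(xtr, factor(ytr, levels = c(0, 1)),
                        family = "binomial", alpha = 0, lambda = lambda,
                        standardize = FALSE)
  score <- as.numeric(stats::predict(fit, xte, type = "response"))
  yte <- as.integer(labels[idx_test] == positive)
  pred <- as.integer(score >= 0.5)
  tp <- sum(pred == 1 & yte == 1); tn <- sum(pred == 0 & yte == 0)
  fp <- sum(pred == 1 & yte == 0); fn <- sum(pred == 0 & yte == 1)
  roc <- suppressMessages(pROC::roc(yte, score, quiet = TRUE,
                                    direction = "<", levels = c(0, 1)))
  structure(list(
    accuracy = (tp + tn) / length(yte),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    auc = as.numeric(pROC::auc(roc)),
    confusion = c(tp = tp, fp = fp, tn = tn, fn = fn),
    n_train = length(idx_train), n_test = length(idx_test),
    positive = positive, seed = seed, lambda = lambda,
    test_scores = score, test_labels = yte,
    standardization = st[c("center", "scale")]
  ), class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("Stratified train/test logistic-regression evaluation\n")
  cat(sprintf("  train n = %d, test n = %d (positive class: %s)\n",
              x$n_train, x$n_test, x$positive))
  cat(sprintf("  accuracy = %.3f  sensitivity = %.3f  specificity = %.3f  AUC = %.3f\n",
              x$accuracy, x$sensitivity, x$specificity, x$auc))
  invisible(x)
}

#' Run the full phenotype-discrimination analysis
#'
#' Standardization + PCA + k-means + stratified logistic evaluation on a
#' feature table. With the `"full"` preset, zero-variance columns (e.g. the
#' AMH daily sd, which is exactly 0 because AMH is trait-like) are dropped
#' before standardization.
#'
#' @param features a [feature_table()].
#' @param preset feature preset (see [feature_matrix()]).
#' @param seed integer seed for k-means and the split.
#' @param k clusters for k-means.
#' @return object of class `phenotype_analysis`: `pca`, `kmeans`,
#'   `classification`, `preset`, `seed`, `dropped_columns`.
#' @export
analyze_features <- function(features, preset = "pca6", seed = 1, k = 2) {
  m <- feature_matrix(features, preset)
  sds <- apply(m, 2, stats::sd)
  dropped <- colnames(m)[sds == 0 | is.na(sds)]
  if (length(dropped)) m <- m[, !(colnames(m) %in% dropped), drop = FALSE]
  labels <- features$phenotype
  st <- standardize(m)
  pca <- pca_project(st$x, n_components = 2)
  km <- kmeans_cluster(st$x, k = k, seed = seed, labels = labels)
  clf <- train_eval_logistic(m, labels, seed = seed)
  structure(list(pca = pca, kmeans = km, classification = clf,
                 preset = preset, seed = seed, k = k,
                 dropped_columns = dropped, labels = labels),
            class = "phenotype_analysis")
}

#' @export
print.phenotype_analysis <- function(x, ...) {
  evr <- x$pca$explained_variance_ratio
  cat(sprintf("Phenotype discrimination (preset '%s', seed %d)\n",
              x$preset, x$seed))
  cat(sprintf("  PCA: PC1+PC2 explain %.1f%% of variance\n",
              100 * sum(evr[1:2])))
  cat(sprintf("  k-means (k = %d): label agreement %.3f\n",
              x$k, x$kmeans$agreement))
  print(x$classification)
  invisible(x)
}

#' PC1/PC2 scatter colored by phenotype
#'
#' @param x a `phenotype_analysis`.
#' @param ... passed to `plot()`.
#' @export
plot.phenotype_analysis <- function(x, ...) {
  sc <- x$pca$scores
  cols <- ifelse(x$labels == "PCOS", "darkorange", "steelblue")
  pch <- ifelse(x$labels == "PCOS", 4, 1)
  evr <- 100 * x$pca$explained_variance_ratio
  plot(sc[, 1], sc[, 2], col = cols, pch = pch,
       xlab = sprintf("PC1 (%.1f%%)", evr[1]),
       ylab = sprintf("PC2 (%.1f%%)", evr[2]),
       main = "PCA of per-subject mean hormone levels", ...)
  graphics::legend("topright", legend = c("EUM", "PCOS"),
                   col = c("steelblue", "darkorange"), pch = c(1, 4))
  invisible(x)
}
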