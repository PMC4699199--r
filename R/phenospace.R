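#' Kolmogorov-Smirnov distance between two nesting-ratio samples
#'
#' The two-sample Kolmogorov-Smirnov statistic
#' `D = sup_x |ECDF1(x) - ECDF2(x)|` between the empirical cumulative
#' distributions of two samples of nesting ratios. It quantifies
#' statistical (dis)similarity of the nested-loop topologies of two
#' networks irrespective of their sizes. `D` lies in [0, 1]; it is
#' symmetric and zero for identical samples, but is a statistic, not a
#' metric (the triangle inequality is not guaranteed).
#'
#' @param x,y nonempty numeric samples.
#' @return the KS statistic, a number in [0, 1].
#' @export
ks_distance <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("empty sample")
  grid <- sort(unique(c(x, y)))
  cdf <- function(s) {
    vapply(grid, function(g) mean(s <= g), numeric(1))
  }
  max(abs(cdf(x) - cdf(y)))
}

#' Nearest neighbors under the KS distance
#'
#' Ranks the other specimens by the KS distance between their
#' nesting-ratio samples and the target's, smallest first; distance ties
#' are broken by id order.
#'
#' @param target_id id of the query specimen (must be a name of
#'   `ratio_samples`).
#' @param ratio_samples named list of numeric nesting-ratio samples.
#' @param k number of neighbors to return.
#' @return data.frame with columns `id` and `D_KS`, `k` rows.
#' @export
nearest_neighbors <- function(target_id, ratio_samples, k = 2) {
  if (!target_id %in% names(ratio_samples)) stop("unknown target id")
  others <- setdiff(names(ratio_samples), target_id)
  if (length(others) < k) stop("fewer than k other specimens available")
  D <- vapply(others, function(id) {
    ks_distance(ratio_samples[[target_id]], ratio_samples[[id]])
  }, numeric(1))
  ord <- order(D, others)[seq_len(k)]
  data.frame(id = others[ord], D_KS = unname(D[ord]),
             stringsAsFactors = FALSE)
}

#' Read a fingerprint feature table
#'
#' Loads a specimen-by-metric table (CSV or TSV) with one row per
#' specimen or fragment. Required columns: `specimen_id`, `species`, and
#' the 8 fingerprint metrics `sigma`, `a`, `A`, `rho_A`, `d`, `L_top`,
#' `i_u`, `i_w`.
#'
#' @param path CSV/TSV file.
#' @return a validated data.frame.
#' @export
read_fingerprint_table <- function(path) {
  if (!file.exists(path)) stop("fingerprint table not found: ", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("specimen_id", "species", fingerprint_metric_names())
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("fingerprint table lacks columns: ", paste(missing, collapse = ", "))
  if (anyNA(tab[, fingerprint_metric_names()]))
    stop("missing values in metric columns")
  tab
}

feature_columns <- function(feature_set = c("geometry+topology", "geometry")) {
  feature_set <- match.arg(feature_set)
  geo <- c("sigma", "a", "A", "rho_A", "d")
  if (feature_set == "geometry") geo else c(geo, "L_top", "i_u", "i_w")
}

#' Principal component analysis of a fingerprint table
#'
#' Standardizes each metric to zero mean and unit variance (the metrics
#' have incommensurate units) and performs PCA, i.e. an
#' eigendecomposition of the correlation matrix.
#'
#' @param table data.frame containing the 8 metric columns (see
#'   [read_fingerprint_table()]).
#' @return list with `explained` (fractions of total variance per
#'   component, summing to 1) and `loadings` (metrics x components
#'   orthonormal matrix).
#' @export
pca_fingerprints <- function(table) {
  cols <- fingerprint_metric_names()
  stopifnot(all(cols %in% names(table)))
  X <- as.matrix(table[, cols])
  if (nrow(X) < length(cols) + 1)
    stop("need more rows than metrics for a stable PCA")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("constant metric column(s): ", paste(cols[sds == 0], collapse = ", "))
  p <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  list(explained = p$sdev^2 / sum(p$sdev^2), loadings = p$rotation)
}

# Seeded stratified fold assignment: within each class, shuffle rows and
# deal them round-robin into folds.
stratified_folds <- function(labels, folds, seed) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
    fold
  })
}

#' Cross-validated linear discriminant classification
#'
#' Fits a linear discriminant classifier to identify specimens (or
#' species) from fingerprint rows, scoring it with seeded stratified
#' k-fold cross-validation. Features are standardized with the training
#' folds' statistics only, so no information leaks from the held-out
#' fold. Classes with fewer rows than folds are dropped with a warning.
#'
#' @param table a fingerprint feature table.
#' @param label label column: `"specimen_id"` or `"species"`.
#' @param feature_set `"geometry"` (sigma, a, A, rho_A, d) or
#'   `"geometry+topology"` (adds L_top, i_u, i_w).
#' @param folds number of cross-validation folds.
#' @param seed integer seed for the fold assignment.
#' @return numeric vector of the `folds` held-out accuracies (fraction of
#'   correctly identified rows).
#' @export
lda_cv <- function(table, label = c("specimen_id", "species"),
                   feature_set = c("geometry+topology", "geometry"),
                   folds = 10, seed = 0) {
  label <- match.arg(label)
  cols <- feature_columns(match.arg(feature_set))
  y <- as.character(table[[label]])
  counts <- table(y)
  small <- names(counts)[counts < folds]
  if (length(small)) {
    warning(sprintf("dropping %d class(es) with fewer than %d rows",
                    length(small), folds))
    keep <- !(y %in% small)
    table <- table[keep, , drop = FALSE]
    y <- y[keep]
  }
  if (length(unique(y)) < 2) stop("need at least 2 classes with enough rows")
  X <- as.matrix(table[, cols])
  fold <- stratified_folds(y, folds, seed)
  vapply(seq_len(folds), function(f) {
    tr <- fold != f
    mu <- colMeans(X[tr, , drop = FALSE])
    sd_ <- apply(X[tr, , drop = FALSE], 2, stats::sd)
    sd_[sd_ == 0] <- 1
    Xs <- sweep(sweep(X, 2, mu), 2, sd_, "/")
    fit <- MASS::lda(Xs[tr, , drop = FALSE], grouping = factor(y[tr]))
    pred <- stats::predict(fit, Xs[!tr, , drop = FALSE])$class
    mean(as.character(pred) == y[!tr])
  }, numeric(1))
}

#' Mean pairwise classification accuracy
#'
#' Runs [lda_cv()] restricted to every unordered pair of classes and
#' averages the mean fold accuracies — the probability of correctly
#' assigning a row to one of two candidate specimens.
#'
#' @inheritParams lda_cv
#' @return the mean over class pairs of the mean cross-validated accuracy.
#' @export
pairwise_lda <- function(table, label = c("specimen_id", "species"),
                         feature_set = c("geometry+topology", "geometry"),
                         folds = 10, seed = 0) {
  label <- match.arg(label)
  feature_set <- match.arg(feature_set)
  y <- as.character(table[[label]])
  counts <- table(y)
  classes <- names(counts)[counts >= folds]
  if (length(classes) < 2) stop("need at least 2 classes with enough rows")
  pairs <- utils::combn(sort(classes), 2)
  acc <- apply(pairs, 2, function(pr) {
    sub <- table[y %in% pr, , drop = FALSE]
    mean(lda_cv(sub, label = label, feature_set = feature_set,
                folds = folds, seed = seed))
  })
  mean(acc)
}

#' Welch's unequal-variance t test
#'
#' Two-sided Welch t test with Welch-Satterthwaite degrees of freedom,
#' e.g. for comparing the fold-accuracy samples of two feature sets.
#'
#' @param a,b numeric samples of size >= 2.
#' @return list with elements `t`, `df`, `p`.
#' @export
welch_t <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (isTRUE(all.equal(mean(a), mean(b))))
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1))
    return(list(t = sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2, p = 0))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}
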