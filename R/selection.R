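#' @include AllClasses.R core_io.R
NULL

#' Between-class distance score of a feature
#'
#' `|m1 - m2| / sqrt(s1^2 + s2^2)`: the absolute class-mean difference over
#' the root-sum-square of the class standard deviations (sample sd). Larger
#' distance means a more significant feature.
#'
#' @param feature numeric vector.
#' @param labels binary vector (same length).
#' @return numeric(1) >= 0.
#' @export
classDistanceScore <- function(feature, labels) {
  stopifnot(length(feature) == length(labels))
  x0 <- feature[labels == 0]; x1 <- feature[labels == 1]
  if (length(x0) < 2L || length(x1) < 2L)
    stop("each class needs at least 2 members")
  s2 <- var(x0) + var(x1)
  if (s2 < .EPS) return(if (abs(mean(x0) - mean(x1)) < .EPS) 0 else 1 / .EPS)
  abs(mean(x0) - mean(x1)) / sqrt(s2)
}

#' Plug-in mutual information between a binned feature and the label
#'
#' The feature is discretized into `n_bins` equal-frequency bins; MI is the
#' plug-in estimate in bits. Features with `MI <= phi` are flagged as
#' separately inappropriate (irrelevant on their own).
#'
#' @inheritParams classDistanceScore
#' @param n_bins number of feature bins (default 8).
#' @return numeric(1) >= 0.
#' @export
miRelevance <- function(feature, labels, n_bins = 8L) {
  stopifnot(n_bins >= 2L, length(feature) == length(labels))
  qs <- unique(quantile(feature, probs = seq(0, 1, length.out = n_bins + 1L)))
  bx <- if (length(qs) < 2L) rep(1L, length(feature)) else
    cut(feature, qs, include.lowest = TRUE, labels = FALSE)
  joint <- table(bx, labels) / length(feature)
  px <- rowSums(joint); py <- colSums(joint)
  mi <- 0
  for (i in seq_along(px)) for (j in seq_along(py)) {
    p <- joint[i, j]
    if (p > 0) mi <- mi + p * log2(p / (px[i] * py[j]))
  }
  max(0, as.numeric(mi))
}

#' Principal component analysis with population covariance
#'
#' Centres the columns, forms the covariance with 1/l normalization
#' (population form), and eigendecomposes it. Eigenvector signs are fixed so
#' each component's largest-magnitude loading is positive; eigenvalues below
#' 1e-10 are clamped to 0.
#'
#' @param table numeric N x F matrix (or [featureValues()] of a
#'   \linkS4class{CarotidFeatureSet}).
#' @return list with `eigenvalues`, `eigenvectors` (F x F, columns =
#'   components), `scores` (N x F projections of the centred rows),
#'   `center` (column means).
#' @export
pcaFit <- function(table) {
  X <- as.matrix(table)
  stopifnot(nrow(X) >= 2L)
  mu <- colMeans(X)
  S <- sweep(X, 2L, mu)
  C <- crossprod(S) / nrow(S)              # 1/l normalization
  eg <- eigen(C, symmetric = TRUE)
  vals <- pmax(0, eg$values)
  vals[vals < 1e-10] <- 0
  vecs <- eg$vectors
  for (j in seq_len(ncol(vecs))) {
    k <- which.max(abs(vecs[, j]))
    if (vecs[k, j] < 0) vecs[, j] <- -vecs[, j]
  }
  rownames(vecs) <- colnames(X)
  list(eigenvalues = vals, eigenvectors = vecs, scores = S %*% vecs,
       center = mu)
}

#' Select the k most discriminant features
#'
#' Ranks features by the between-class distance criterion, then gates the
#' ranking by principal-component loadings: components are retained until
#' they explain `variance_keep` of the total variance, and a feature is
#' eligible if it appears in the top loading quartile (by |loading|) of any
#' retained component. The selection takes the top `k` eligible features by
#' distance rank, topping up with the best remaining features by pure
#' distance rank when fewer than `k` qualify. Ties break lexicographically
#' by feature name, so the result is invariant to column order.
#' `variance_keep = 0` recovers pure distance ranking. Optional mutual-
#' information screening (off by default) removes features with
#' `MI <= mi_threshold` before ranking.
#'
#' Because histogram/correlogram columns enter the table unnormalized, the
#' gating PCA is computed on standardized columns (correlation scale), so
#' eligibility reflects correlation structure rather than raw feature
#' scale; the reported `eigenvalues`/`eigenvectors`/`scores` are from this
#' gating decomposition. [pcaFit()] remains available for the plain
#' population-covariance decomposition of an arbitrary table.
#'
#' @param table N x F numeric matrix with column names, or a
#'   \linkS4class{CarotidFeatureSet}.
#' @param labels binary labels (taken from the dataset when omitted).
#' @param k number of features to select (default 22).
#' @param variance_keep PCA variance fraction to cover (default 0.95).
#' @param mi_threshold MI screening threshold phi in bits, or NULL to skip
#'   (default NULL; 0.01 is a reasonable value when enabled).
#' @return a \linkS4class{SelectionReport}
#' @export
selectFeatures <- function(table, labels = NULL, k = 22L,
                           variance_keep = 0.95, mi_threshold = NULL) {
  if (is(table, "CarotidFeatureSet")) {
    if (is.null(labels)) labels <- imageLabels(table)
    table <- featureValues(table)
  }
  X <- as.matrix(table)
  if (is.null(colnames(X))) colnames(X) <- sprintf("f%02d", seq_len(ncol(X)))
  if (k > ncol(X)) stop("k exceeds the number of features")
  feats <- colnames(X)
  dist_scores <- vapply(feats, function(f) classDistanceScore(X[, f], labels),
                        numeric(1L))
  mi_scores <- numeric(0)
  screened <- feats
  if (!is.null(mi_threshold)) {
    mi_scores <- vapply(feats, function(f) miRelevance(X[, f], labels),
                        numeric(1L))
    screened <- feats[mi_scores > mi_threshold]
    if (length(screened) < k) {
      extra <- setdiff(feats[order(-mi_scores, feats)], screened)
      screened <- c(screened, head(extra, k - length(screened)))
    }
  }
  sds <- apply(X, 2L, sd)
  sds[!is.finite(sds) | sds < .EPS] <- 1
  pca <- pcaFit(sweep(X, 2L, sds, "/"))
  # distance ranking with lexicographic tie-break
  ranked <- feats[order(-dist_scores, feats)]
  ranked <- ranked[ranked %in% screened]
  total_var <- sum(pca$eigenvalues)
  if (variance_keep > 0 && total_var > .EPS) {
    cum <- cumsum(pca$eigenvalues) / total_var
    n_keep <- which(cum >= variance_keep)[1L]
    eligible <- character(0)
    qn <- max(1L, ceiling(length(feats) / 4))
    for (j in seq_len(n_keep)) {
      lo <- abs(pca$eigenvectors[, j])
      eligible <- union(eligible, feats[order(-lo, feats)][seq_len(qn)])
    }
    sel <- ranked[ranked %in% eligible]
  } else {
    sel <- ranked
  }
  if (length(sel) >= k) {
    selected <- sel[seq_len(k)]
  } else {
    topup <- ranked[!ranked %in% sel]
    selected <- c(sel, head(topup, k - length(sel)))
  }
  new("SelectionReport",
      distance_scores = dist_scores, mi_scores = mi_scores,
      eigenvalues = pca$eigenvalues, eigenvectors = pca$eigenvectors,
      scores = pca$scores, selected = selected,
      params = list(k = k, variance_keep = variance_keep,
                    mi_threshold = mi_threshold))
}

#' @describeIn selectedFeatures method for SelectionReport
#' @export
setMethod("selectedFeatures", "SelectionReport", function(x) x@selected)

setMethod("show", "SelectionReport", function(object) {
  cat(sprintf("SelectionReport: %d features selected of %d\n",
              length(object@selected), length(object@distance_scores)))
  top <- head(object@selected, 10L)
  cat("  top by distance:", paste(top, collapse = ", "), "\n")
})

#' Serialize a SelectionReport to JSON
#'
#' @param report a \linkS4class{SelectionReport}.
#' @param path output path.
#' @return `path`, invisibly
#' @export
writeSelectionJSON <- function(report, path) {
  jsonlite::write_json(list(
    selected = report@selected,
    distance_scores = as.list(report@distance_scores),
    mi_scores = as.list(report@mi_scores),
    eigenvalues = report@eigenvalues,
    params = report@params), path, auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(path)
}
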