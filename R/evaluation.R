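#' @include AllClasses.R
NULL

#' Confusion matrix for binary plaque classification
#'
#' Positive class = plaque (1).
#'
#' @param predicted,actual binary vectors of equal length.
#' @return named integer vector of class `ConfusionMatrix` with cells `TP`,
#'   `FP`, `FN`, `TN` (summing to the number of samples).
#' @export
confusionMatrix <- function(predicted, actual) {
  if (length(predicted) != length(actual))
    stop("predicted and actual must have equal length")
  predicted <- as.integer(predicted); actual <- as.integer(actual)
  structure(c(TP = sum(predicted == 1L & actual == 1L),
              FP = sum(predicted == 1L & actual == 0L),
              FN = sum(predicted == 0L & actual == 1L),
              TN = sum(predicted == 0L & actual == 0L)),
            class = "ConfusionMatrix")
}

#' Classification metrics from a confusion matrix
#'
#' accuracy = (TP+TN)/N, precision = TP/(TP+FP), recall/sensitivity =
#' TP/(TP+FN), specificity = TN/(TN+FP), F = 2PR/(P+R), and the balanced-
#' accuracy AUC = (sensitivity + specificity)/2. All reported as
#' percentages; a metric whose denominator is zero is reported as NA
#' (undefined), never as 0.
#'
#' @param cm a [confusionMatrix()] result, or a named vector/list with
#'   `TP`, `FP`, `FN`, `TN`.
#' @return named numeric vector (percentages): `accuracy`, `precision`,
#'   `sensitivity`, `specificity`, `f_score`, `auc_balanced`.
#' @export
classificationMetrics <- function(cm) {
  tp <- cm[["TP"]]; fp <- cm[["FP"]]; fn <- cm[["FN"]]; tn <- cm[["TN"]]
  sdiv <- function(num, den) if (den > 0) num / den else NA_real_
  acc <- sdiv(tp + tn, tp + tn + fp + fn)
  prec <- sdiv(tp, tp + fp)
  sens <- sdiv(tp, tp + fn)
  spec <- sdiv(tn, tn + fp)
  f <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0)
    2 * prec * sens / (prec + sens) else NA_real_
  auc_b <- if (!is.na(sens) && !is.na(spec)) (sens + spec) / 2 else NA_real_
  100 * c(accuracy = acc, precision = prec, sensitivity = sens,
          specificity = spec, f_score = f, auc_balanced = auc_b)
}

#' Format a metric set the way clinical tables print it
#'
#' Truncates (not rounds) to 2 decimals; full precision stays available in
#' the unformatted vector.
#'
#' @param metrics output of [classificationMetrics()].
#' @return named character vector.
#' @export
formatMetrics <- function(metrics) {
  vapply(metrics, function(v) {
    if (is.na(v)) "undefined" else sprintf("%.2f", floor(v * 100) / 100)
  }, character(1L))
}

#' ROC curve and trapezoidal AUC
#'
#' TPR/FPR at every distinct score threshold (descending); tied scores
#' cross their threshold simultaneously, so the trapezoidal AUC equals the
#' Mann-Whitney statistic with midrank tie handling.
#'
#' @param scores numeric scores, larger = more plaque-like.
#' @param actual binary labels.
#' @return list with `points` (data.frame fpr/tpr/threshold) and `auc`.
#' @export
rocCurve <- function(scores, actual) {
  actual <- as.integer(actual)
  if (length(unique(actual)) < 2L)
    stop("both classes must be present")
  thr <- sort(unique(scores), decreasing = TRUE)
  npos <- sum(actual == 1L); nneg <- sum(actual == 0L)
  tpr <- c(0, vapply(thr, function(t) sum(scores >= t & actual == 1L),
                     numeric(1L)) / npos)
  fpr <- c(0, vapply(thr, function(t) sum(scores >= t & actual == 0L),
                     numeric(1L)) / nneg)
  auc <- sum(diff(fpr) * (head(tpr, -1L) + tail(tpr, -1L)) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr,
                           threshold = c(Inf, thr)),
       auc = auc)
}

#' Cumulative gain chart
#'
#' Samples sorted by descending score; the cumulative fraction of positives
#' captured within each population decile. The final point is always
#' (1, 1).
#'
#' @inheritParams rocCurve
#' @param n_deciles number of population bins (>= 2, default 10).
#' @return data.frame with `population_fraction` and `gain`.
#' @export
gainChart <- function(scores, actual, n_deciles = 10L) {
  stopifnot(n_deciles >= 2L)
  actual <- as.integer(actual)
  ord <- order(-scores)
  y <- actual[ord]
  n <- length(y)
  cuts <- round(seq_len(n_deciles) / n_deciles * n)
  gain <- vapply(cuts, function(k) sum(y[seq_len(k)]), numeric(1L)) /
    max(1L, sum(y))
  data.frame(population_fraction = cuts / n, gain = gain)
}

#' Box-Cox transform with profile-likelihood lambda selection
#'
#' Evaluates the profile log-likelihood of the power transform
#' `(x^lambda - 1)/lambda` (log x at lambda = 0) on a lambda grid and
#' returns the maximizing lambda and the transformed values.
#'
#' @param values positive numeric vector.
#' @param lambda_grid candidate lambdas (default seq(-2, 2, 0.01)).
#' @return list with `lambda`, `transformed`, `loglik` (data.frame over the
#'   grid).
#' @export
boxcoxTransform <- function(values, lambda_grid = seq(-2, 2, by = 0.01)) {
  if (any(values <= 0)) stop("Box-Cox requires strictly positive values")
  n <- length(values)
  slg <- sum(log(values))
  ll <- vapply(lambda_grid, function(lm) {
    y <- if (abs(lm) < 1e-12) log(values) else (values^lm - 1) / lm
    v <- var(y) * (n - 1) / n
    if (v < .EPS) return(Inf)
    -n / 2 * log(v) + (lm - 1) * slg
  }, numeric(1L))
  best <- lambda_grid[which.max(ll)]
  y <- if (abs(best) < 1e-12) log(values) else (values^best - 1) / best
  list(lambda = best, transformed = y,
       loglik = data.frame(lambda = lambda_grid, loglik = ll))
}

#' Evaluate a fitted classifier on labelled data
#'
#' @param model a fitted classifier.
#' @param x feature rows.
#' @param y binary labels.
#' @return list with `confusion`, `metrics`, `roc` (list with auc), `gain`.
#' @export
evaluateClassifier <- function(model, x, y) {
  lab <- predictLabels(model, x)
  sc <- predictScores(model, x)
  cm <- confusionMatrix(as.integer(lab), y)
  roc <- if (length(unique(y)) == 2L && length(unique(sc)) > 1L)
    rocCurve(sc, y) else NULL
  list(confusion = cm, metrics = classificationMetrics(cm),
       roc = roc, gain = gainChart(sc, y))
}
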