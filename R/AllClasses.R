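#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom stats fft sd var median quantile rgamma runif rnorm dnorm lm
#'   coef setNames
#' @importFrom utils head tail read.csv write.csv
#' @importFrom grDevices chull
NULL

# numerical guard used wherever a denominator can degenerate
.EPS <- 1e-9

#' GrayImage: an 8-bit grayscale B-mode image
#'
#' A 2-D intensity grid with integer values in \[0, 255\] and optional
#' physical pixel spacing. Rows index the axial (depth) direction, columns the
#' lateral direction; coordinates used throughout the package are 0-based
#' (row, col).
#'
#' @slot pixels numeric matrix, H x W, integer-valued in \[0, 255\].
#' @slot spacing numeric(1), physical size of a pixel in mm (default 1).
#' @export
setClass("GrayImage",
  representation(pixels = "matrix", spacing = "numeric"),
  prototype(spacing = 1))

setValidity("GrayImage", function(object) {
  p <- object@pixels
  if (!is.numeric(p)) return("pixels must be a numeric matrix")
  if (nrow(p) < 8L || ncol(p) < 8L) return("image must be at least 8 x 8")
  if (anyNA(p)) return("pixels contain NA")
  if (min(p) < 0 || max(p) > 255) return("pixel values must lie in [0, 255]")
  if (any(p != round(p))) return("pixel values must be integers")
  if (length(object@spacing) != 1L || object@spacing <= 0)
    return("spacing must be a positive scalar")
  TRUE
})

#' ROIMask: a binary region of interest
#'
#' A logical H x W grid marking the pixels on which features are computed.
#' Must contain at least 16 foreground pixels.
#'
#' @slot mask logical matrix.
#' @export
setClass("ROIMask", representation(mask = "matrix"))

setValidity("ROIMask", function(object) {
  m <- object@mask
  if (!is.logical(m)) return("mask must be a logical matrix")
  if (anyNA(m)) return("mask contains NA")
  if (sum(m) < 16L) return("ROI must contain at least 16 foreground pixels")
  TRUE
})

#' CarotidFeatureSet: images x features with labels and a split record
#'
#' Extends \linkS4class{SummarizedExperiment}: the `"features"` assay holds
#' the F x N feature matrix (features in rows, images in columns), `colData`
#' carries the binary plaque label (1 = plaque, 0 = normal) and, once
#' [splitDataset()] has been applied, a `role` column marking each image as
#' `"train"` or `"test"`.
#'
#' @export
setClass("CarotidFeatureSet", contains = "SummarizedExperiment")

setValidity("CarotidFeatureSet", function(object) {
  if (!"features" %in% SummarizedExperiment::assayNames(object))
    return("assay 'features' is required")
  a <- SummarizedExperiment::assay(object, "features")
  if (anyNA(a) || any(!is.finite(a))) return("feature values must be finite")
  if (anyDuplicated(rownames(a))) return("feature names must be unique")
  cd <- SummarizedExperiment::colData(object)
  if (!"label" %in% colnames(cd)) return("colData must contain 'label'")
  if (!all(cd$label %in% c(0L, 1L))) return("labels must be 0 or 1")
  if ("role" %in% colnames(cd)) {
    if (!all(cd$role %in% c("train", "test")))
      return("role must be 'train' or 'test'")
  }
  TRUE
})

#' GaussianNBModel: fitted Gaussian Naive Bayes classifier
#'
#' Per-class empirical priors and per-class per-feature means and variances
#' (variances floored at 1e-9). Class 1 is the plaque class.
#'
#' @slot priors named numeric(2), summing to 1 (names "0", "1").
#' @slot means 2 x F matrix of class-conditional feature means.
#' @slot variances 2 x F matrix of class-conditional feature variances.
#' @slot features character vector of feature names.
#' @slot kernel logical(1); TRUE for the kernel-density variant.
#' @slot training list; for the kernel variant, the per-class training rows
#'   and bandwidths.
#' @export
setClass("GaussianNBModel",
  representation(priors = "numeric", means = "matrix", variances = "matrix",
                 features = "character", kernel = "logical",
                 training = "list"),
  prototype(kernel = FALSE, training = list()))

setValidity("GaussianNBModel", function(object) {
  if (abs(sum(object@priors) - 1) > 1e-9) return("priors must sum to 1")
  if (any(object@variances < .EPS - 1e-15)) return("variances below floor")
  if (!identical(dim(object@means), dim(object@variances)))
    return("means/variances shape mismatch")
  TRUE
})

#' DLVQModel: dynamic learning vector quantization classifier
#'
#' A labelled prototype set trained by attract/repel updates with a
#' monotonically decreasing step size, frequency-sensitive winner selection,
#' and per-epoch prototype growth for classes whose training error stays
#' above a threshold.
#'
#' @slot prototypes P x F matrix of prototype weight vectors.
#' @slot proto_labels integer vector of prototype class labels (0/1).
#' @slot win_counts numeric vector of per-prototype win counts.
#' @slot features character vector of feature names.
#' @slot config list of training hyper-parameters.
#' @slot trace data.frame with per-epoch error and prototype count.
#' @export
setClass("DLVQModel",
  representation(prototypes = "matrix", proto_labels = "integer",
                 win_counts = "numeric", features = "character",
                 config = "list", trace = "data.frame"))

setValidity("DLVQModel", function(object) {
  if (nrow(object@prototypes) != length(object@proto_labels))
    return("one label per prototype required")
  if (!all(c(0L, 1L) %in% object@proto_labels))
    return("at least one prototype per class required")
  if (any(!is.finite(object@prototypes))) return("non-finite prototype")
  if (any(object@win_counts < 0)) return("win counts must be non-negative")
  TRUE
})

#' SelectionReport: output of the feature-selection stage
#'
#' @slot distance_scores named numeric; between-class distance per feature.
#' @slot mi_scores named numeric; plug-in mutual information per feature
#'   (length 0 when MI screening is off).
#' @slot eigenvalues numeric, descending, non-negative.
#' @slot eigenvectors F x F loadings matrix (columns = components).
#' @slot scores N x F projections of the centred rows.
#' @slot selected character; ordered selected feature names.
#' @slot params list of selection parameters used.
#' @export
setClass("SelectionReport",
  representation(distance_scores = "numeric", mi_scores = "numeric",
                 eigenvalues = "numeric", eigenvectors = "matrix",
                 scores = "matrix", selected = "character", params = "list"))

setValidity("SelectionReport", function(object) {
  ev <- object@eigenvalues
  if (any(ev < -1e-8)) return("eigenvalues must be non-negative")
  if (is.unsorted(rev(ev), strictly = FALSE)) # descending
    return("eigenvalues must be sorted in descending order")
  TRUE
})
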