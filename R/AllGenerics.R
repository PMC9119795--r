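#' @include AllClasses.R
NULL

#' Pixel matrix of a GrayImage
#' @param x a \linkS4class{GrayImage}
#' @return numeric H x W matrix
#' @export
setGeneric("pixelMatrix", function(x) standardGeneric("pixelMatrix"))

#' Pixel spacing (mm/pixel)
#' @param x a \linkS4class{GrayImage}
#' @return numeric(1)
#' @export
setGeneric("pixelSpacing", function(x) standardGeneric("pixelSpacing"))

#' Logical mask of an ROIMask
#' @param x an \linkS4class{ROIMask}
#' @return logical matrix
#' @export
setGeneric("maskMatrix", function(x) standardGeneric("maskMatrix"))

#' Feature values as an images x features matrix
#' @param x a \linkS4class{CarotidFeatureSet}
#' @return numeric N x F matrix (one row per image)
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' Binary plaque labels (1 = plaque)
#' @param x a \linkS4class{CarotidFeatureSet}
#' @return integer vector of length N
#' @export
setGeneric("imageLabels", function(x) standardGeneric("imageLabels"))

#' Indices of the training split
#' @param x a \linkS4class{CarotidFeatureSet}
#' @return integer vector (empty when no split has been recorded)
#' @export
setGeneric("trainIndex", function(x) standardGeneric("trainIndex"))

#' Indices of the test split
#' @param x a \linkS4class{CarotidFeatureSet}
#' @return integer vector (empty when no split has been recorded)
#' @export
setGeneric("testIndex", function(x) standardGeneric("testIndex"))

#' Selected feature names
#' @param x a \linkS4class{SelectionReport}
#' @return character vector
#' @export
setGeneric("selectedFeatures", function(x) standardGeneric("selectedFeatures"))

#' Predict class labels
#' @param object a fitted classifier model
#' @param newdata numeric matrix or data.frame of feature rows
#' @param ... further arguments passed to methods
#' @return integer labels (with score attributes where applicable)
#' @export
setGeneric("predictLabels",
  function(object, newdata, ...) standardGeneric("predictLabels"))

#' Continuous classification scores for ROC analysis
#'
#' Returns, for each row of `newdata`, a score in \[0, 1\] increasing with
#' evidence for the plaque class.
#' @inheritParams predictLabels
#' @return numeric vector
#' @export
setGeneric("predictScores",
  function(object, newdata, ...) standardGeneric("predictScores"))
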