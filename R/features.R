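#' @include texture.R shape.R histcorr.R morphology.R
NULL

#' Names of the 63 features, in table order
#'
#' 33 texture + 5 shape + 10 histogram/correlogram + 15 morphology.
#' @return character vector of length 63.
#' @export
carotexFeatureNames <- function() {
  c(paste0("glcm.", c("contrast", "correlation", "energy", "homogeneity",
                      "entropy", "inertia")),
    paste0("fos.", c("mean", "median", "kurtosis", "skewness")),
    paste0("glds.", c("mean", "entropy", "contrast", "asm", "homogeneity")),
    "fdta.fd", "fps.radial", "fps.angular",
    paste0("ngtdm.", c("coarseness", "contrast", "complexity", "strength")),
    paste0("sfm.", c("coarseness", "contrast", "periodicity", "roughness")),
    paste0("grad.", c("mean", "variance")),
    "lbp.entropy", "gabor.energy",
    paste0("rle.", c("sre", "lre", "rp")),
    paste0("shape.", c("sharpness", "complexity", "length_irregularity",
                       "aspect_ratio", "circularity")),
    c("hist.gsm", "hist.entropy", "hist.energy", "mrh.inner_outer_diff",
      "gld.mean", "gld.variance", "gld.entropy", "hog.mean", "hog.max",
      "corr.profile_slope"),
    paste0("morph.", c("pdf_mean", "cdf_mean", "power_low", "power_medium",
                       "power_high", "shape", "connectivity", "convexity",
                       "size", "volume", "lipid_core", "hemorrhage",
                       "lumen_roughness", "dark_fraction",
                       "bright_fraction")))
}

#' Extract the full 63-feature vector from one image
#'
#' Texture and histogram/correlogram features are computed on the analysis
#' ROI; shape features on the boundary of the echogenic candidate region
#' inside the ROI (falling back to the ROI itself when the candidate is
#' empty, e.g. a clean lumen); morphology features as described in
#' [morphologyFeatures()]. The ground-truth plaque mask of a phantom is
#' never consulted.
#'
#' @inheritParams glcm
#' @return named numeric vector of length 63, all finite.
#' @export
extractFeatures <- function(image, roi = NULL, levels = 32L) {
  px <- .px(image)
  mask <- .roi(roi, dim(px))
  tex <- textureFeatures(image, mask, levels = levels)
  cand <- .plaque_candidate(image, mask)
  shape_mask <- if (sum(cand) >= 16L) cand else mask
  # a speckled candidate region is routinely disconnected; the largest
  # component is the intended object, so the tracer's warning is expected
  shp <- suppressWarnings(shapeFeatures(shape_mask, tolerance_px = 1))
  hc <- histcorrFeatures(image, mask)
  mo <- morphologyFeatures(image, mask)
  out <- c(tex, shp, hc, mo)
  stopifnot(identical(names(out), carotexFeatureNames()))
  bad <- !is.finite(out)
  if (any(bad)) out[bad] <- 0
  out
}

#' Extract features for a list of images
#'
#' @param images list of \linkS4class{GrayImage} (or matrices).
#' @param rois list of ROIs (recycled if length 1, NULL for full frame).
#' @param labels optional binary labels; when given, a
#'   \linkS4class{CarotidFeatureSet} is returned instead of a matrix.
#' @param verbose print a progress line every 50 images.
#' @return N x 63 matrix, or a \linkS4class{CarotidFeatureSet}.
#' @export
extractFeatureTable <- function(images, rois = NULL, labels = NULL,
                                verbose = FALSE) {
  n <- length(images)
  out <- matrix(NA_real_, n, 63L,
                dimnames = list(NULL, carotexFeatureNames()))
  for (i in seq_len(n)) {
    roi <- if (is.null(rois)) NULL
      else if (length(rois) == 1L) rois[[1L]] else rois[[i]]
    out[i, ] <- extractFeatures(images[[i]], roi)
    if (verbose && i %% 50L == 0L)
      message(sprintf("extracted %d / %d images", i, n))
  }
  if (is.null(labels)) return(out)
  carotidFeatureSet(out, labels)
}
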