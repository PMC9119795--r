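#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Construct a GrayImage
#'
#' @param pixels numeric H x W matrix with values in \[0, 255\]. Values are
#'   rounded to integers.
#' @param spacing physical pixel size in mm (default 1).
#' @return a \linkS4class{GrayImage}
#' @examples
#' img <- grayImage(matrix(seq(0, 255, length.out = 64), 8, 8))
#' @export
grayImage <- function(pixels, spacing = 1) {
  new("GrayImage", pixels = round(pixels), spacing = as.numeric(spacing))
}

#' Construct an ROIMask
#'
#' @param mask logical (or 0/1) matrix.
#' @return an \linkS4class{ROIMask}
#' @export
roiMask <- function(mask) {
  if (!is.logical(mask)) mask <- mask > 0
  new("ROIMask", mask = mask)
}

#' @describeIn pixelMatrix method for GrayImage
#' @export
setMethod("pixelMatrix", "GrayImage", function(x) x@pixels)

#' @describeIn pixelSpacing method for GrayImage
#' @export
setMethod("pixelSpacing", "GrayImage", function(x) x@spacing)

#' @describeIn maskMatrix method for ROIMask
#' @export
setMethod("maskMatrix", "ROIMask", function(x) x@mask)

setMethod("show", "GrayImage", function(object) {
  p <- object@pixels
  cat(sprintf("GrayImage %d x %d, spacing %g mm/px, intensity [%d, %d]\n",
              nrow(p), ncol(p), object@spacing, min(p), max(p)))
})

setMethod("show", "ROIMask", function(object) {
  cat(sprintf("ROIMask %d x %d, %d foreground pixels\n",
              nrow(object@mask), ncol(object@mask), sum(object@mask)))
})

#' Read an 8-bit grayscale image from PNG or TIFF
#'
#' Multi-channel images are converted to luminance; higher bit depths are
#' rescaled linearly so the maximum representable value maps to 255.
#'
#' @param path file path to a PNG or TIFF image.
#' @param spacing physical pixel size in mm.
#' @return a \linkS4class{GrayImage}
#' @export
readGrayImage <- function(path, spacing = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- EBImage::readImage(path)          # values scaled to [0,1]
  if (length(dim(img)) == 3L) img <- EBImage::channel(img, "luminance")
  m <- EBImage::imageData(img)
  if (length(dim(m)) != 2L) m <- m[, , 1L]
  if (length(m) == 0L) stop("zero-size image: ", path)
  # EBImage stores x (width) first: transpose to rows = image rows
  grayImage(t(m) * 255, spacing = spacing)
}

#' Write a GrayImage as an 8-bit PNG
#'
#' Round-trips losslessly through [readGrayImage()].
#'
#' @param image a \linkS4class{GrayImage}
#' @param path output path ending in .png
#' @return `path`, invisibly
#' @export
writeGrayImage <- function(image, path) {
  m <- t(.px(image)) / 255
  EBImage::writeImage(EBImage::Image(m, colormode = "Grayscale"), path)
  invisible(path)
}

#' Z-score then min-max normalize a vector to \[0, 1\]
#'
#' Subtracts the mean, divides by the standard deviation, then rescales the
#' z-scores linearly onto \[0, 1\]. A constant vector maps to 0.5 everywhere
#' so degenerate features never abort a run. When reference statistics
#' (fitted on a training split) are supplied, they are used instead of the
#' vector's own, and the output is clipped to \[0, 1\].
#'
#' @param values numeric vector.
#' @param stats optional list with `mean`, `sd`, `zmin`, `zmax` as returned in
#'   the `stats` attribute of a previous call.
#' @return numeric vector in \[0, 1\] with attribute `stats`.
#' @examples
#' zscoreUnitNormalize(c(1, 2, 3))  # 0, 0.5, 1
#' @export
zscoreUnitNormalize <- function(values, stats = NULL) {
  stopifnot(length(values) >= 1L)
  if (is.null(stats)) {
    mu <- mean(values)
    s <- sd(values)
    if (!is.finite(s) || s < .EPS) {
      out <- rep(0.5, length(values))
      attr(out, "stats") <- list(mean = mu, sd = 0, zmin = 0, zmax = 0)
      return(out)
    }
    z <- (values - mu) / s
    stats <- list(mean = mu, sd = s, zmin = min(z), zmax = max(z))
  }
  if (stats$sd < .EPS || stats$zmax - stats$zmin < .EPS) {
    out <- rep(0.5, length(values))
  } else {
    z <- (values - stats$mean) / stats$sd
    out <- (z - stats$zmin) / (stats$zmax - stats$zmin)
    out <- pmin(1, pmax(0, out))
  }
  attr(out, "stats") <- stats
  out
}

#' Assemble a CarotidFeatureSet
#'
#' @param features numeric N x F matrix, one row per image, named columns.
#' @param labels binary vector (1 = plaque) of length N.
#' @param image_ids optional character ids (defaults to `img001`, ...).
#' @return a \linkS4class{CarotidFeatureSet}
#' @export
carotidFeatureSet <- function(features, labels, image_ids = NULL) {
  features <- as.matrix(features)
  if (is.null(image_ids))
    image_ids <- sprintf("img%03d", seq_len(nrow(features)))
  stopifnot(length(labels) == nrow(features))
  assay <- t(features)
  colnames(assay) <- image_ids
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = assay),
    colData = S4Vectors::DataFrame(label = as.integer(labels),
                                   row.names = image_ids))
  new("CarotidFeatureSet", se)
}

#' @describeIn featureValues method for CarotidFeatureSet
#' @export
setMethod("featureValues", "CarotidFeatureSet", function(x)
  t(SummarizedExperiment::assay(x, "features")))

#' @describeIn imageLabels method for CarotidFeatureSet
#' @export
setMethod("imageLabels", "CarotidFeatureSet", function(x)
  as.integer(SummarizedExperiment::colData(x)$label))

#' @describeIn trainIndex method for CarotidFeatureSet
#' @export
setMethod("trainIndex", "CarotidFeatureSet", function(x) {
  cd <- SummarizedExperiment::colData(x)
  if (!"role" %in% colnames(cd)) return(integer(0))
  which(cd$role == "train")
})

#' @describeIn testIndex method for CarotidFeatureSet
#' @export
setMethod("testIndex", "CarotidFeatureSet", function(x) {
  cd <- SummarizedExperiment::colData(x)
  if (!"role" %in% colnames(cd)) return(integer(0))
  which(cd$role == "test")
})

setMethod("show", "CarotidFeatureSet", function(object) {
  n <- ncol(object)
  lab <- imageLabels(object)
  cat(sprintf("CarotidFeatureSet: %d images x %d features (%d plaque, %d normal)\n",
              n, nrow(object), sum(lab == 1L), sum(lab == 0L)))
  tr <- trainIndex(object)
  if (length(tr))
    cat(sprintf("  split: %d train / %d test\n", length(tr), n - length(tr)))
})

#' Stratified train/test split
#'
#' Splits the images into train and test sets, stratified by label, with
#' per-class sizes rounded so that the total training size is
#' `round(train_fraction * N)`. Reproducible for a given seed.
#'
#' @param dataset a \linkS4class{CarotidFeatureSet}.
#' @param train_fraction fraction of images used for training; the default
#'   270/361 reproduces a 270/91 split at N = 361.
#' @param seed integer seed.
#' @return the dataset with a `role` column added to its `colData`.
#' @export
splitDataset <- function(dataset, train_fraction = 270 / 361, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  labels <- imageLabels(dataset)
  counts <- table(labels)
  if (any(counts < 2L)) stop("each class needs at least 2 members")
  n <- length(labels)
  n_train <- round(train_fraction * n)
  classes <- sort(unique(labels))
  per_class <- round(train_fraction * as.numeric(counts[as.character(classes)]))
  # reconcile rounding so the totals match exactly
  excess <- sum(per_class) - n_train
  if (excess != 0) {
    j <- which.max(per_class)
    per_class[j] <- per_class[j] - excess
  }
  per_class <- pmin(pmax(per_class, 1L), as.numeric(counts) - 1L)
  role <- rep("test", n)
  withr::with_seed(as.integer(seed), {
    for (i in seq_along(classes)) {
      idx <- which(labels == classes[i])
      take <- sample(idx, per_class[i])
      role[take] <- "train"
    }
  })
  SummarizedExperiment::colData(dataset)$role <- role
  validObject(dataset)
  dataset
}

#' Normalize feature families using training-split statistics
#'
#' Texture, shape and morphology columns are passed through
#' [zscoreUnitNormalize()]; histogram/correlogram columns (prefixes `hist.`,
#' `mrh.`, `gld.`, `hog.`, `corr.`) are left unnormalized. Normalization
#' statistics are fitted on the training rows only (all rows when no split is
#' recorded) and applied to the remaining rows, preventing train/test leakage.
#'
#' @param dataset a \linkS4class{CarotidFeatureSet}.
#' @return the dataset with its `"features"` assay replaced; fitted statistics
#'   are stored in `metadata(dataset)$normalization`.
#' @export
normalizeFeatures <- function(dataset) {
  vals <- featureValues(dataset)
  tr <- trainIndex(dataset)
  if (length(tr) == 0L) tr <- seq_len(nrow(vals))
  skip <- grepl("^(hist|mrh|gld|hog|corr)\\.", colnames(vals))
  fitted <- vector("list", ncol(vals))
  names(fitted) <- colnames(vals)
  for (j in seq_len(ncol(vals))) {
    if (skip[j]) next
    ref <- zscoreUnitNormalize(vals[tr, j])
    st <- attr(ref, "stats")
    vals[, j] <- as.numeric(zscoreUnitNormalize(vals[, j], stats = st))
    fitted[[j]] <- st
  }
  a <- t(vals)
  colnames(a) <- colnames(SummarizedExperiment::assay(dataset, "features"))
  SummarizedExperiment::assay(dataset, "features") <- a
  S4Vectors::metadata(dataset)$normalization <- fitted
  dataset
}

#' Write a feature table to CSV
#'
#' Layout: first column `id`, then one column per feature, last column
#' `label` (plus `role` when a split is recorded).
#'
#' @param dataset a \linkS4class{CarotidFeatureSet}.
#' @param path output CSV path.
#' @return `path`, invisibly
#' @export
writeFeatureCSV <- function(dataset, path) {
  vals <- featureValues(dataset)
  df <- data.frame(id = rownames(vals), vals, check.names = FALSE)
  df$label <- imageLabels(dataset)
  cd <- SummarizedExperiment::colData(dataset)
  if ("role" %in% colnames(cd)) df$role <- cd$role
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [writeFeatureCSV()]
#'
#' @param path CSV path.
#' @return a \linkS4class{CarotidFeatureSet}
#' @export
readFeatureCSV <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  role <- if ("role" %in% names(df)) df$role else NULL
  feat_cols <- setdiff(names(df), c("id", "label", "role"))
  fs <- carotidFeatureSet(as.matrix(df[, feat_cols, drop = FALSE]),
                          labels = df$label, image_ids = df$id)
  if (!is.null(role)) SummarizedExperiment::colData(fs)$role <- role
  fs
}
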