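#' @include AllClasses.R utils.R
NULL

#' Gray-level histogram of the ROI
#'
#' Equal-width bins over \[0, 255\], normalized to sum to 1.
#'
#' @inheritParams glcm
#' @param bins number of bins (default 32).
#' @return numeric vector of bin masses.
#' @export
grayHistogram <- function(image, roi = NULL, bins = 32L) {
  px <- .px(image)
  v <- px[.roi(roi, dim(px))]
  if (length(v) == 0L) stop("empty ROI")
  idx <- pmin(bins, floor(v * bins / 256) + 1L)
  tabulate(idx, nbins = bins) / length(v)
}

#' Grayscale median and histogram entropy
#'
#' GSM is the median ROI intensity (the standard plaque echogenicity index);
#' entropy is the Shannon entropy in bits of the 32-bin gray histogram.
#'
#' @inheritParams grayHistogram
#' @return named numeric vector `gsm`, `entropy`.
#' @export
gsmEntropy <- function(image, roi = NULL, bins = 32L) {
  px <- .px(image)
  v <- px[.roi(roi, dim(px))]
  if (length(v) == 0L) stop("empty ROI")
  c(gsm = median(v), entropy = .entropy_bits(grayHistogram(image, roi, bins)))
}

#' Multiregion histogram over equidistant boundary bands
#'
#' Partitions the ROI into `n_rings` bands of equal depth measured inward
#' from the ROI boundary (band 1 = outermost) and computes a normalized
#' gray histogram per band. Bands with no pixels are flagged empty and emit
#' zeros.
#'
#' @inheritParams grayHistogram
#' @param n_rings number of bands (default 3).
#' @return list with `histograms` (n_rings x bins matrix), `band_means`
#'   (mean intensity per band, NA when empty), `empty` (logical).
#' @export
multiregionHistogram <- function(image, roi = NULL, n_rings = 3L,
                                 bins = 32L) {
  stopifnot(n_rings >= 1L)
  px <- .px(image)
  mask <- .roi(roi, dim(px))
  dm <- EBImage::distmap(1 * mask)            # distance to background
  dmax <- max(dm)
  band <- matrix(0L, nrow(px), ncol(px))
  band[mask] <- pmin(n_rings, floor((dm[mask] - .EPS) / dmax * n_rings) + 1L)
  hs <- matrix(0, n_rings, bins)
  means <- rep(NA_real_, n_rings)
  empty <- rep(TRUE, n_rings)
  for (k in seq_len(n_rings)) {
    v <- px[band == k]
    if (length(v) == 0L) next
    empty[k] <- FALSE
    idx <- pmin(bins, floor(v * bins / 256) + 1L)
    hs[k, ] <- tabulate(idx, nbins = bins) / length(v)
    means[k] <- mean(v)
  }
  list(histograms = hs, band_means = means, empty = empty)
}

#' Signed gray-level difference at an integer displacement
#'
#' `Yd(i, j) = I(i, j) - I(i + drow, j + dcol)` on the valid overlap, with
#' mean, variance and entropy (bits, 256-level histogram) of `|Yd|`.
#'
#' @inheritParams glcm
#' @param d integer displacement `c(drow, dcol)`.
#' @return list with `difference` (matrix), `mean`, `variance`, `entropy`.
#' @export
grayLevelDifference <- function(image, d = c(1L, 0L), roi = NULL) {
  px <- .px(image)
  if (any(abs(d) >= dim(px))) stop("offset exceeds the image size")
  mask <- .roi(roi, dim(px))
  win <- .pair_window(dim(px), d[1L], d[2L])
  if (is.null(win)) stop("offset exceeds the image size")
  a <- px[win$rows, win$cols, drop = FALSE]
  b <- px[win$rows + d[1L], win$cols + d[2L], drop = FALSE]
  yd <- a - b
  ok <- mask[win$rows, win$cols, drop = FALSE] &
    mask[win$rows + d[1L], win$cols + d[2L], drop = FALSE]
  v <- abs(yd[ok])
  p <- tabulate(v + 1L, nbins = 256L) / max(1L, length(v))
  list(difference = yd,
       mean = if (length(v)) mean(v) else 0,
       variance = if (length(v) > 1L) var(v) else 0,
       entropy = .entropy_bits(p))
}

#' Histogram of oriented gradients
#'
#' Central-difference gradients on the ROI bounding box; unsigned
#' orientations in \[0, 180) degrees; magnitude-weighted votes split
#' bilinearly between the two nearest orientation bins and among the four
#' nearest cell centres; per-cell histograms L2-normalized. The scalar
#' summaries used in the feature table are the mean and maximum descriptor
#' entry.
#'
#' @inheritParams glcm
#' @param cell_px cell size in pixels (>= 4, default 8).
#' @param n_orient_bins unsigned orientation bins (default 9).
#' @return list with `descriptor` (numeric vector), `cells` (dim of the cell
#'   grid), `mean`, `max`.
#' @export
hogFeatures <- function(image, roi = NULL, cell_px = 8L, n_orient_bins = 9L) {
  stopifnot(cell_px >= 4L)
  px <- .px(image)
  mask <- .roi(roi, dim(px))
  bb <- .bbox(mask)
  px <- px[bb$rows[1L]:bb$rows[2L], bb$cols[1L]:bb$cols[2L], drop = FALSE]
  sub <- mask[bb$rows[1L]:bb$rows[2L], bb$cols[1L]:bb$cols[2L], drop = FALSE]
  h <- nrow(px); w <- ncol(px)
  g <- .central_gradients(px, sub)
  mag <- sqrt(g$gx^2 + g$gy^2)
  mag[!g$valid] <- 0
  ori <- (atan2(g$gy, g$gx) * 180 / pi) %% 180      # unsigned
  ncr <- max(1L, floor(h / cell_px)); ncc <- max(1L, floor(w / cell_px))
  hist_arr <- array(0, c(ncr, ncc, n_orient_bins))
  # cell centres (1-based pixel coordinates)
  ctr_r <- (seq_len(ncr) - 0.5) * cell_px + 0.5
  ctr_c <- (seq_len(ncc) - 0.5) * cell_px + 0.5
  idx <- which(mag > 0, arr.ind = TRUE)
  if (nrow(idx)) {
    m <- mag[idx]; o <- ori[idx]
    # orientation interpolation
    bw <- 180 / n_orient_bins
    fb <- o / bw - 0.5
    b0 <- floor(fb)
    wb1 <- fb - b0
    b0 <- (b0 %% n_orient_bins) + 1L
    b1 <- (b0 %% n_orient_bins) + 1L
    # spatial interpolation over cell centres
    fr <- (idx[, 1L] - ctr_r[1L]) / cell_px
    fc <- (idx[, 2L] - ctr_c[1L]) / cell_px
    r0 <- floor(fr); c0 <- floor(fc)
    wr1 <- fr - r0; wc1 <- fc - c0
    for (dr in 0:1) for (dc in 0:1) {
      rr <- r0 + dr + 1L; cc <- c0 + dc + 1L
      wgt <- (if (dr == 0) 1 - wr1 else wr1) *
        (if (dc == 0) 1 - wc1 else wc1)
      ok <- rr >= 1L & rr <= ncr & cc >= 1L & cc <= ncc & wgt > 0
      if (!any(ok)) next
      for (ob in 1:2) {
        bb_ <- if (ob == 1L) b0 else b1
        wo <- if (ob == 1L) 1 - wb1 else wb1
        sel <- ok & wo > 0
        if (!any(sel)) next
        lin <- (bb_[sel] - 1L) * ncr * ncc + (cc[sel] - 1L) * ncr + rr[sel]
        add <- m[sel] * wgt[sel] * wo[sel]
        agg <- rowsum(add, lin)
        hist_arr[as.integer(rownames(agg))] <-
          hist_arr[as.integer(rownames(agg))] + agg[, 1L]
      }
    }
  }
  # per-cell L2 normalization
  for (i in seq_len(ncr)) for (j in seq_len(ncc)) {
    nrm <- sqrt(sum(hist_arr[i, j, ]^2))
    if (nrm > .EPS) hist_arr[i, j, ] <- hist_arr[i, j, ] / nrm
  }
  desc <- as.vector(hist_arr)
  list(descriptor = desc, cells = c(ncr, ncc),
       mean = mean(desc), max = if (length(desc)) max(desc) else 0)
}

#' Distance correlogram of the ROI
#'
#' Each ROI pixel's Euclidean distance from the ROI centroid is normalized
#' by the maximum distance and bucketed into `n_bands` equal-width bands;
#' per-band normalized gray histograms and mean intensities form the
#' correlogram. The scalar feature used in the feature table is the slope of
#' the band-mean intensity profile against normalized distance.
#'
#' @inheritParams grayHistogram
#' @param n_bands number of distance bands (>= 2, default 8).
#' @return list of class `DistanceCorrelogram` with `band_means`,
#'   `band_histograms`, `band_counts`, `normalizer` (max distance),
#'   `profile_slope`.
#' @export
correlogram <- function(image, roi = NULL, n_bands = 8L, bins = 32L) {
  stopifnot(n_bands >= 2L)
  px <- .px(image)
  mask <- .roi(roi, dim(px))
  idx <- which(mask, arr.ind = TRUE)
  ctr <- colMeans(idx)
  d <- sqrt((idx[, 1L] - ctr[1L])^2 + (idx[, 2L] - ctr[2L])^2)
  dmax <- max(d)
  band <- if (dmax < .EPS) rep(1L, length(d)) else
    pmin(n_bands, floor(d / dmax * n_bands) + 1L)
  v <- px[mask]
  means <- rep(NA_real_, n_bands)
  counts <- integer(n_bands)
  hs <- matrix(0, n_bands, bins)
  for (k in seq_len(n_bands)) {
    vk <- v[band == k]
    counts[k] <- length(vk)
    if (!length(vk)) next
    means[k] <- mean(vk)
    bidx <- pmin(bins, floor(vk * bins / 256) + 1L)
    hs[k, ] <- tabulate(bidx, nbins = bins) / length(vk)
  }
  mid <- (seq_len(n_bands) - 0.5) / n_bands
  okb <- !is.na(means)
  slope <- if (sum(okb) >= 2L && sd(means[okb]) > .EPS)
    unname(coef(lm(means[okb] ~ mid[okb]))[2L]) else 0
  structure(list(band_means = means, band_histograms = hs,
                 band_counts = counts, normalizer = dmax,
                 profile_slope = slope),
            class = "DistanceCorrelogram")
}

#' The 10 histogram and correlogram features
#'
#' GSM, 32-bin histogram entropy and energy; the inner-minus-outer band mean
#' of the multiregion histogram; mean, variance and entropy of the absolute
#' gray-level difference at unit displacement; HOG descriptor mean and max;
#' and the correlogram profile slope. These enter the feature table
#' unnormalized.
#'
#' @inheritParams glcm
#' @return named numeric vector of length 10.
#' @export
histcorrFeatures <- function(image, roi = NULL) {
  ge <- gsmEntropy(image, roi)
  hg <- grayHistogram(image, roi)
  mrh <- multiregionHistogram(image, roi, n_rings = 3L)
  bm <- mrh$band_means
  inner_outer <- if (!is.na(bm[3L]) && !is.na(bm[1L])) bm[3L] - bm[1L] else 0
  gld <- grayLevelDifference(image, d = c(1L, 0L), roi = roi)
  hog <- hogFeatures(image, roi)
  cg <- correlogram(image, roi)
  c(hist.gsm = unname(ge["gsm"]), hist.entropy = unname(ge["entropy"]),
    hist.energy = sum(hg^2),
    mrh.inner_outer_diff = inner_outer,
    gld.mean = gld$mean, gld.variance = gld$variance,
    gld.entropy = gld$entropy,
    hog.mean = hog$mean, hog.max = hog$max,
    corr.profile_slope = cg$profile_slope)
}
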