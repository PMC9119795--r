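#' @include AllClasses.R utils.R
NULL

# offset (drow, dcol) for a co-occurrence angle in degrees
.angle_offset <- function(theta, d) {
  switch(as.character(theta),
    "0"   = c(0L, d),
    "45"  = c(d, d),
    "90"  = c(d, 0L),
    "135" = c(d, -d),
    stop("theta must be one of 0, 45, 90, 135"))
}

#' Gray-level co-occurrence matrix
#'
#' Counts ordered pixel pairs `(p, p + offset)` whose two ends both lie in
#' the ROI, after quantizing the image to `levels` gray levels. The matrix is
#' left asymmetric (no transpose-symmetrization) and, when `normalize` is
#' TRUE (default), divided by the total pair count.
#'
#' @param image \linkS4class{GrayImage} or numeric matrix in \[0, 255\].
#' @param roi optional \linkS4class{ROIMask} or logical matrix.
#' @param levels number of gray levels (default 32).
#' @param d pair distance in pixels (default 1).
#' @param theta angle in degrees, one of 0, 45, 90, 135.
#' @param normalize divide counts by the total pair count.
#' @return a list of class `GLCMatrix` with elements `counts`, `levels`,
#'   `d`, `theta`, `normalized`.
#' @export
glcm <- function(image, roi = NULL, levels = 32L, d = 1L, theta = 0,
                 normalize = TRUE) {
  stopifnot(levels >= 2L, d >= 1L)
  px <- .px(image)
  mask <- .roi(roi, dim(px))
  q <- .quantize(px, levels)
  off <- .angle_offset(theta, as.integer(d))
  win <- .pair_window(dim(px), off[1L], off[2L])
  if (is.null(win)) stop("image too small for this offset")
  a <- q[win$rows, win$cols, drop = FALSE]
  b <- q[win$rows + off[1L], win$cols + off[2L], drop = FALSE]
  ok <- mask[win$rows, win$cols, drop = FALSE] &
    mask[win$rows + off[1L], win$cols + off[2L], drop = FALSE]
  if (!any(ok)) stop("ROI admits no pixel pair at this offset")
  idx <- a[ok] * levels + b[ok] + 1L     # row = first pixel, col = second
  cm <- matrix(tabulate(idx, nbins = levels^2), levels, levels, byrow = TRUE)
  if (normalize) cm <- cm / sum(cm)
  structure(list(counts = cm, levels = levels, d = d, theta = theta,
                 normalized = normalize), class = "GLCMatrix")
}

#' Haralick-style features of a normalized co-occurrence matrix
#'
#' contrast = sum (a-b)^2 p(a,b); correlation = sum p (a-mu_a)(b-mu_b) /
#' (sigma_a sigma_b); energy = sum p^2; homogeneity = sum p / (1+|a-b|);
#' entropy = -sum p log2 p; inertia is an alias of contrast (both name the
#' same second-moment difference form). Correlation of a matrix with a
#' degenerate marginal is reported as 0.
#'
#' @param cm a `GLCMatrix` (must be normalized) or a matrix summing to 1.
#' @return named numeric vector with elements `contrast`, `correlation`,
#'   `energy`, `homogeneity`, `entropy`, `inertia`.
#' @export
glcmFeatures <- function(cm) {
  p <- if (inherits(cm, "GLCMatrix")) cm$counts else cm
  if (abs(sum(p) - 1) > 1e-6) stop("co-occurrence matrix must be normalized")
  L <- nrow(p)
  lv <- seq_len(L) - 1
  A <- matrix(lv, L, L)          # row index = first pixel level
  B <- matrix(lv, L, L, byrow = TRUE)
  contrast <- sum((A - B)^2 * p)
  pa <- rowSums(p); pb <- colSums(p)
  mua <- sum(lv * pa); mub <- sum(lv * pb)
  sa <- sqrt(sum((lv - mua)^2 * pa)); sb <- sqrt(sum((lv - mub)^2 * pb))
  correlation <- if (sa < .EPS || sb < .EPS) 0 else
    sum(p * (A - mua) * (B - mub)) / (sa * sb)
  energy <- sum(p^2)
  homogeneity <- sum(p / (1 + abs(A - B)))
  entropy <- .entropy_bits(as.vector(p))
  c(contrast = contrast, correlation = correlation, energy = energy,
    homogeneity = homogeneity, entropy = entropy, inertia = contrast)
}

#' Co-occurrence features averaged over the four standard angles
#'
#' Computes [glcmFeatures()] at 0, 45, 90 and 135 degrees and returns their
#' mean. The 4-angle mean is invariant to 90-degree image rotation.
#'
#' @inheritParams glcm
#' @return named numeric vector as in [glcmFeatures()].
#' @export
glcmMeanFeatures <- function(image, roi = NULL, levels = 32L, d = 1L) {
  f <- vapply(c(0, 45, 90, 135),
              function(th) glcmFeatures(glcm(image, roi, levels, d, th)),
              numeric(6L))
  rowMeans(f)
}

#' First-order intensity statistics of the ROI
#'
#' Mean, median, excess kurtosis and skewness of the ROI intensity sample
#' (moment estimators; a near-constant sample reports skewness and kurtosis
#' of 0).
#'
#' @inheritParams glcm
#' @return named numeric vector `mean`, `median`, `kurtosis`, `skewness`.
#' @export
firstOrderStats <- function(image, roi = NULL) {
  px <- .px(image)
  v <- px[.roi(roi, dim(px))]
  if (length(v) == 0L) stop("empty ROI")
  if (var(v) < .EPS) {
    sk <- 0; ku <- 0
  } else {
    sk <- e1071::skewness(v, type = 1)
    ku <- e1071::kurtosis(v, type = 1)
  }
  c(mean = mean(v), median = median(v), kurtosis = ku, skewness = sk)
}

.UNIT_OFFSETS <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))

#' Gray-level difference statistics
#'
#' Statistics of the distribution of absolute intensity differences
#' `|I(p) - I(p + d)|`, averaged over the supplied offsets (by default the
#' four unit displacements).
#'
#' @inheritParams glcm
#' @param offsets list of integer `(drow, dcol)` displacement vectors.
#' @return named numeric vector `mean`, `entropy`, `contrast`, `asm`,
#'   `homogeneity`.
#' @export
gldsFeatures <- function(image, roi = NULL, offsets = .UNIT_OFFSETS) {
  px <- .px(image)
  mask <- .roi(roi, dim(px))
  per <- vapply(offsets, function(off) {
    d <- .pair_absdiff(px, mask, off[1L], off[2L])
    if (length(d) == 0L) return(rep(NA_real_, 5L))
    p <- tabulate(d + 1L, nbins = 256L) / length(d)
    c(mean(d), .entropy_bits(p), mean(d^2), sum(p^2),
      sum(p / (1 + 0:255)))
  }, numeric(5L))
  out <- rowMeans(per, na.rm = TRUE)
  names(out) <- c("mean", "entropy", "contrast", "asm", "homogeneity")
  out
}

#' Fractal dimension by differential box counting
#'
#' Treats the ROI bounding box of the intensity image as a surface and
#' estimates the fractal dimension as the least-squares slope of
#' `log N(s)` against `log(1/s)` over block sizes `s = 2 .. max_scale`,
#' where `N(s)` counts the gray-level boxes of height `s * 256 / M` spanned
#' within each `s x s` block (M = smaller image side). A flat image gives
#' a value near 2; rougher surfaces approach 3.
#'
#' @inheritParams glcm
#' @param max_scale largest block size (>= 3 so that at least two scales
#'   enter the fit; default 4).
#' @return numeric(1) fractal dimension estimate.
#' @export
fdtaFractalDimension <- function(image, roi = NULL, max_scale = 4L) {
  px <- .px(image)
  mask <- .roi(roi, dim(px))
  bb <- .bbox(mask)
  px <- px[bb$rows[1L]:bb$rows[2L], bb$cols[1L]:bb$cols[2L], drop = FALSE]
  scales <- 2:max_scale
  scales <- scales[scales <= min(dim(px))]
  if (length(scales) < 2L) stop("degenerate fit: need at least two scales")
  M <- min(dim(px))
  counts <- vapply(scales, function(s) {
    h <- s * 256 / M
    nbr <- floor(nrow(px) / s); nbc <- floor(ncol(px) / s)
    n <- 0
    for (i in seq_len(nbr)) for (j in seq_len(nbc)) {
      blk <- px[((i - 1L) * s + 1L):(i * s), ((j - 1L) * s + 1L):(j * s)]
      n <- n + (floor(max(blk) / h) - floor(min(blk) / h) + 1)
    }
    n
  }, numeric(1L))
  fit <- lm(log(counts) ~ log(1 / scales))
  unname(coef(fit)[2L])
}

#' Radial and angular sums of the Fourier power spectrum
#'
#' The power spectrum `|F|^2` of the ROI bounding box (non-ROI pixels
#' replaced by the ROI mean, DC excluded) is partitioned into `n_rings`
#' concentric rings and `n_wedges` unsigned-angle wedges about the spectrum
#' centre; each partition's power sum is normalized by the total power.
#' Scalar summaries `radial_centroid` and `angular_centroid` are the
#' power-weighted mean normalized radius and angle.
#'
#' @inheritParams glcm
#' @param n_rings,n_wedges partition sizes (default 4 each).
#' @return list with `ring_sums`, `wedge_sums`, `radial_centroid`,
#'   `angular_centroid`.
#' @export
fourierSpectrumSums <- function(image, roi = NULL, n_rings = 4L,
                                n_wedges = 4L) {
  stopifnot(n_rings >= 1L, n_wedges >= 1L)
  px <- .px(image)
  mask <- .roi(roi, dim(px))
  bb <- .bbox(mask)
  px <- px[bb$rows[1L]:bb$rows[2L], bb$cols[1L]:bb$cols[2L], drop = FALSE]
  sub <- mask[bb$rows[1L]:bb$rows[2L], bb$cols[1L]:bb$cols[2L], drop = FALSE]
  px[!sub] <- mean(px[sub])
  P <- Mod(fft(px))^2
  P[1L, 1L] <- 0                                   # exclude DC
  h <- nrow(px); w <- ncol(px)
  fr <- matrix(.freq_axis(h) / h, h, w)
  fc <- matrix(.freq_axis(w) / w, h, w, byrow = TRUE)
  rad <- sqrt(fr^2 + fc^2)
  rad_n <- rad / max(rad)
  ang <- atan2(fr, fc) %% pi                       # unsigned orientation
  total <- sum(P)
  if (total < .EPS) {
    return(list(ring_sums = rep(0, n_rings), wedge_sums = rep(0, n_wedges),
                radial_centroid = 0, angular_centroid = 0))
  }
  ring_idx <- pmin(n_rings, floor(rad_n * n_rings) + 1L)
  wedge_idx <- pmin(n_wedges, floor(ang / pi * n_wedges) + 1L)
  ring_sums <- vapply(seq_len(n_rings),
                      function(k) sum(P[ring_idx == k]), numeric(1L)) / total
  wedge_sums <- vapply(seq_len(n_wedges),
                       function(k) sum(P[wedge_idx == k]), numeric(1L)) / total
  list(ring_sums = ring_sums, wedge_sums = wedge_sums,
       radial_centroid = sum(P * rad_n) / total,
       angular_centroid = sum(P * ang) / total / pi)
}

#' Neighbourhood gray-tone difference matrix features
#'
#' Classical coarseness, contrast, complexity and strength computed from the
#' per-level sums `s(k)` of `|k - A|`, where `A` is the mean of the 8
#' neighbours, over pixels whose full 3x3 window lies inside the ROI.
#' Divisions are guarded by 1e-9; coarseness is capped at 1e9 for perfectly
#' smooth regions.
#'
#' @inheritParams glcm
#' @return named numeric vector `coarseness`, `contrast`, `complexity`,
#'   `strength`.
#' @export
ngtdmFeatures <- function(image, roi = NULL, levels = 32L) {
  px <- .px(image)
  mask <- .roi(roi, dim(px))
  q <- .quantize(px, levels)
  k8 <- matrix(1 / 8, 3L, 3L); k8[2L, 2L] <- 0
  fv <- .filter_valid(q, mask, k8)
  valid <- fv$valid & mask
  if (!any(valid)) stop("no 3x3 neighbourhood fits inside the ROI")
  i <- q[valid]
  dev <- abs(i - fv$response[valid])
  n <- length(i)
  ni <- tabulate(i + 1L, nbins = levels)
  si <- vapply(seq_len(levels) - 1L,
               function(k) sum(dev[i == k]), numeric(1L))
  pi_ <- ni / n
  present <- which(pi_ > 0)
  lv <- seq_len(levels) - 1
  coarseness <- min(1 / .EPS, 1 / (.EPS + sum(pi_ * si)))
  Ng <- length(present)
  if (Ng > 1L) {
    pp <- outer(pi_[present], pi_[present])
    dd2 <- outer(lv[present], lv[present], function(a, b) (a - b)^2)
    contrast <- sum(pp * dd2) / (Ng * (Ng - 1)) * sum(si) / n
    ps <- pi_[present] * si[present]
    num <- outer(ps, ps, "+")
    den <- outer(pi_[present], pi_[present], "+") * n
    dd1 <- outer(lv[present], lv[present], function(a, b) abs(a - b))
    complexity <- sum(dd1 * num / den)
    strength <- sum(outer(pi_[present], pi_[present], "+") * dd2) /
      (.EPS + sum(si))
  } else {
    contrast <- 0; complexity <- 0; strength <- 0
  }
  c(coarseness = coarseness, contrast = contrast, complexity = complexity,
    strength = strength)
}

#' Statistical feature matrix summaries
#'
#' Dissimilarity `DSS(d) = E|I(p) - I(p+d)|` and contrast
#' `CON(d) = E[(I(p) - I(p+d))^2]` are computed over a displacement set
#' (default the four unit displacements). Features: coarseness =
#' `1/(eps + mean DSS)` (capped at 1e9), contrast = `sqrt(mean CON)`,
#' periodicity = `(mean DSS - min DSS) / mean DSS`, roughness = the log2
#' ratio of the mean dissimilarity at distance 2 to that at distance 1 (a
#' Hurst-style increment slope; 0 for a flat image).
#'
#' @inheritParams gldsFeatures
#' @return named numeric vector `coarseness`, `contrast`, `periodicity`,
#'   `roughness`, with attribute `con` holding the raw per-offset contrasts.
#' @export
sfmFeatures <- function(image, roi = NULL, offsets = .UNIT_OFFSETS) {
  px <- .px(image)
  mask <- .roi(roi, dim(px))
  dss <- function(offs) vapply(offs, function(off) {
    d <- .pair_absdiff(px, mask, off[1L], off[2L])
    if (length(d) == 0L) NA_real_ else mean(d)
  }, numeric(1L))
  con <- vapply(offsets, function(off) {
    d <- .pair_absdiff(px, mask, off[1L], off[2L])
    if (length(d) == 0L) NA_real_ else mean(d^2)
  }, numeric(1L))
  d1 <- dss(offsets)
  offsets2 <- lapply(offsets, function(off) 2L * off)
  d2 <- dss(offsets2)
  m1 <- mean(d1, na.rm = TRUE)
  coarseness <- min(1 / .EPS, 1 / (.EPS + m1))
  contrast <- sqrt(mean(con, na.rm = TRUE))
  periodicity <- if (m1 < .EPS) 0 else (m1 - min(d1, na.rm = TRUE)) / m1
  m2 <- mean(d2, na.rm = TRUE)
  roughness <- log2((.EPS + m2) / (.EPS + m1))
  structure(c(coarseness = coarseness, contrast = contrast,
              periodicity = periodicity, roughness = roughness),
            con = con)
}

#' Absolute-gradient statistics
#'
#' Per-pixel gradient magnitude `sqrt(Gx^2 + Gy^2)` from central differences
#' (half-step denominators), over pixels whose 4 axial neighbours lie in the
#' ROI; reports the mean and variance of the magnitudes.
#'
#' @inheritParams glcm
#' @return named numeric vector `mean`, `variance`.
#' @export
absGradientFeatures <- function(image, roi = NULL) {
  g <- .central_gradients(.px(image), .roi(roi, dim(.px(image))))
  mag <- sqrt(g$gx[g$valid]^2 + g$gy[g$valid]^2)
  if (length(mag) == 0L) stop("ROI admits no central differences")
  c(mean = mean(mag),
    variance = if (length(mag) > 1L) var(mag) else 0)
}

# central differences on the interior; valid where the full cross lies in ROI
.central_gradients <- function(px, mask) {
  h <- nrow(px); w <- ncol(px)
  gx <- matrix(0, h, w); gy <- matrix(0, h, w)
  gx[, 2:(w - 1L)] <- (px[, 3:w] - px[, 1:(w - 2L)]) / 2
  gy[2:(h - 1L), ] <- (px[3:h, ] - px[1:(h - 2L), ]) / 2
  valid <- matrix(FALSE, h, w)
  valid[2:(h - 1L), 2:(w - 1L)] <-
    mask[2:(h - 1L), 2:(w - 1L)] &
    mask[1:(h - 2L), 2:(w - 1L)] & mask[3:h, 2:(w - 1L)] &
    mask[2:(h - 1L), 1:(w - 2L)] & mask[2:(h - 1L), 3:w]
  list(gx = gx, gy = gy, valid = valid)
}

#' Uniform rotation-invariant local binary pattern histogram
#'
#' 8-neighbour LBP codes with a `>=` comparison; patterns with at most two
#' 0/1 transitions around the ring map to bins 0..8 by their number of set
#' bits, all other patterns share bin 9. The histogram is normalized over
#' pixels whose 3x3 window lies in the ROI.
#'
#' @inheritParams glcm
#' @return numeric vector of 10 bin masses summing to 1 (names `u0`..`u8`,
#'   `nonuniform`).
#' @export
lbpHistogram <- function(image, roi = NULL) {
  px <- .px(image)
  mask <- .roi(roi, dim(px))
  h <- nrow(px); w <- ncol(px)
  ri <- 2:(h - 1L); ci <- 2:(w - 1L)
  centre <- px[ri, ci]
  # ring order: E, NE, N, NW, W, SW, S, SE
  shifts <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L),
                 c(0L, -1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))
  bits <- lapply(shifts, function(sh)
    px[ri + sh[1L], ci + sh[2L]] >= centre)
  ok <- mask[ri, ci]
  for (sh in shifts) ok <- ok & mask[ri + sh[1L], ci + sh[2L]]
  if (!any(ok)) stop("no 3x3 neighbourhood fits inside the ROI")
  nset <- Reduce(`+`, bits)
  trans <- Reduce(`+`, lapply(seq_along(bits), function(k) {
    nxt <- if (k == length(bits)) 1L else k + 1L
    bits[[k]] != bits[[nxt]]
  }))
  bin <- ifelse(trans <= 2L, nset, 9L)
  counts <- tabulate(bin[ok] + 1L, nbins = 10L)
  p <- counts / sum(counts)
  names(p) <- c(paste0("u", 0:8), "nonuniform")
  p
}

# complex Gabor kernel pair (even part zero-mean); orientation = direction of
# intensity variation in degrees (0 = variation along columns/x)
.gabor_kernel <- function(frequency, orientation, max_size = 31L) {
  sigma <- 0.56 / frequency
  r <- ceiling(2.5 * sigma)
  size <- min(2L * r + 1L, max_size)
  if (size %% 2L == 0L) size <- size - 1L
  half <- (size - 1L) / 2L
  y <- matrix(-half:half, size, size)          # row offsets
  x <- matrix(-half:half, size, size, byrow = TRUE)
  th <- orientation * pi / 180
  xr <- x * cos(th) + y * sin(th)
  env <- exp(-(x^2 + y^2) / (2 * sigma^2))
  even <- env * cos(2 * pi * frequency * xr)
  odd <- env * sin(2 * pi * frequency * xr)
  even <- even - mean(even)
  list(even = even, odd = odd)
}

#' Gabor filter-bank response statistics
#'
#' Convolves the image with a bank of complex Gabor filters (default 2
#' frequencies x 4 orientations, isotropic Gaussian envelope, zero-DC even
#' part) and reports the mean and standard deviation of the response
#' magnitude over ROI pixels with a fully valid filter footprint.
#'
#' @inheritParams glcm
#' @param frequencies carrier frequencies in cycles/pixel.
#' @param orientations directions of intensity variation in degrees.
#' @return data.frame with columns `frequency`, `orientation`, `mean`, `sd`.
#' @export
gaborFeatures <- function(image, roi = NULL,
                          frequencies = c(0.15, 0.3),
                          orientations = c(0, 45, 90, 135)) {
  stopifnot(length(frequencies) >= 1L, length(orientations) >= 1L)
  px <- .px(image)
  mask <- .roi(roi, dim(px))
  grid <- expand.grid(frequency = frequencies, orientation = orientations,
                      KEEP.OUT.ATTRS = FALSE)
  res <- t(apply(grid, 1L, function(g) {
    kk <- .gabor_kernel(g[["frequency"]], g[["orientation"]],
                        max_size = min(dim(px)) - (1 - min(dim(px)) %% 2L))
    fe <- .filter_valid(px, mask, kk$even)
    fo <- EBImage::filter2(px, kk$odd, boundary = 0)
    ok <- fe$valid & mask
    if (!any(ok)) return(c(NA_real_, NA_real_))
    mag <- sqrt(fe$response[ok]^2 + fo[ok]^2)
    c(mean(mag), if (length(mag) > 1L) sd(mag) else 0)
  }))
  data.frame(grid, mean = res[, 1L], sd = res[, 2L])
}

#' Gray-level run-length features
#'
#' Builds run-length matrices at 0, 45, 90 and 135 degrees (non-ROI pixels
#' break runs) on the image quantized to `levels` gray levels and averages
#' five classical emphasis statistics over the four directions: short- and
#' long-run emphasis, gray-level and run-length non-uniformity, and run
#' percentage.
#'
#' @inheritParams glcm
#' @param directions subset of c(0, 45, 90, 135) to average over.
#' @return named numeric vector `sre`, `lre`, `gln`, `rln`, `rp`.
#' @export
runLengthFeatures <- function(image, roi = NULL, levels = 32L,
                              directions = c(0, 45, 90, 135)) {
  stopifnot(levels >= 2L, all(directions %in% c(0, 45, 90, 135)))
  px <- .px(image)
  mask <- .roi(roi, dim(px))
  q <- .quantize(px, levels)
  q[!mask] <- -1L                               # breaks runs outside the ROI
  h <- nrow(q); w <- ncol(q)
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  lines_by <- list(
    "0" = split(as.vector(t(q)), as.vector(t(rows))),      # along each row
    "90" = split(as.vector(q), as.vector(cols)),           # along each column
    "45" = split(as.vector(q), as.vector(rows + cols)),    # anti-diagonals
    "135" = split(as.vector(q), as.vector(rows - cols)))   # diagonals
  lines_by <- lines_by[as.character(directions)]
  np <- sum(mask)
  max_len <- max(h, w)
  stats <- vapply(lines_by, function(lines) {
    R <- matrix(0, levels, max_len)
    for (ln in lines) {
      r <- rle(ln)
      keep <- r$values >= 0L
      if (!any(keep)) next
      for (k in which(keep))
        R[r$values[k] + 1L, r$lengths[k]] <- R[r$values[k] + 1L, r$lengths[k]] + 1
    }
    nr <- sum(R)
    if (nr == 0) return(rep(NA_real_, 5L))
    lens <- seq_len(max_len)
    rl <- colSums(R)                 # runs per length
    gl <- rowSums(R)                 # runs per gray level
    c(sre = sum(rl / lens^2) / nr, lre = sum(rl * lens^2) / nr,
      gln = sum(gl^2) / nr, rln = sum(rl^2) / nr, rp = nr / np)
  }, numeric(5L))
  out <- rowMeans(stats, na.rm = TRUE)
  names(out) <- c("sre", "lre", "gln", "rln", "rp")
  attr(out, "matrices") <- NULL
  out
}

#' The 33 texture features
#'
#' Computes the full texture block of the feature table: co-occurrence
#' features (4-angle mean at distance 1, 32 levels, inertia = contrast
#' alias), first-order statistics, gray-level difference statistics, fractal
#' dimension, Fourier power-spectrum ring/wedge centroids, NGTDM, SFM,
#' absolute-gradient statistics, the entropy of the uniform-LBP histogram,
#' the Gabor-bank mean response energy, and three run-length emphases.
#'
#' @inheritParams glcm
#' @return named numeric vector of length 33.
#' @export
textureFeatures <- function(image, roi = NULL, levels = 32L) {
  g <- glcmMeanFeatures(image, roi, levels = levels)
  fos <- firstOrderStats(image, roi)
  glds <- gldsFeatures(image, roi)
  fd <- fdtaFractalDimension(image, roi)
  fps <- fourierSpectrumSums(image, roi)
  ng <- ngtdmFeatures(image, roi, levels = levels)
  sf <- sfmFeatures(image, roi)
  gr <- absGradientFeatures(image, roi)
  lbp <- lbpHistogram(image, roi)
  gb <- gaborFeatures(image, roi)
  rl <- runLengthFeatures(image, roi, levels = levels)
  c(setNames(g, paste0("glcm.", names(g))),
    setNames(fos, paste0("fos.", names(fos))),
    setNames(glds, paste0("glds.", names(glds))),
    fdta.fd = fd,
    fps.radial = fps$radial_centroid, fps.angular = fps$angular_centroid,
    setNames(ng, paste0("ngtdm.", names(ng))),
    setNames(as.numeric(sf), paste0("sfm.", names(sf))),
    setNames(gr, paste0("grad.", names(gr))),
    lbp.entropy = .entropy_bits(lbp),
    gabor.energy = mean(gb$mean, na.rm = TRUE),
    rle.sre = unname(rl["sre"]), rle.lre = unname(rl["lre"]),
    rle.rp = unname(rl["rp"]))
}
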