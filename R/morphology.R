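#' @include AllClasses.R utils.R shape.R
NULL

#' Multilevel intensity decomposition
#'
#' Normalizes intensities to \[0, 1\] (division by 255) and thresholds the
#' ROI into low (`I < t1`), medium (`t1 <= I < t2`) and high (`I >= t2`)
#' binary maps. The three maps partition the ROI. Dark (low) components
#' mark echolucent, potentially unstable plaque; bright (high) components
#' mark calcified, stable plaque.
#'
#' @inheritParams glcm
#' @param t1,t2 thresholds in (0, 1) with `t1 < t2` (defaults 1/3, 2/3).
#' @return a list of class `MultilevelDecomposition` with logical maps
#'   `low`, `medium`, `high` and the thresholds.
#' @export
multilevelThreshold <- function(image, roi = NULL, t1 = 1 / 3, t2 = 2 / 3) {
  stopifnot(t1 > 0, t2 < 1, t1 < t2)
  px <- .px(image) / 255
  mask <- .roi(roi, dim(px))
  structure(list(low = mask & px < t1,
                 medium = mask & px >= t1 & px < t2,
                 high = mask & px >= t2,
                 t1 = t1, t2 = t2, roi = mask),
            class = "MultilevelDecomposition")
}

#' Power spectrum of a binary level map
#'
#' DFT power of the map with the DC term removed, normalized by the pixel
#' count of the map's frame; also a coarse 3-ring radial profile.
#'
#' @param level_map logical matrix (one map of a
#'   [multilevelThreshold()] decomposition).
#' @return list with `total_power` and `ring_profile` (length 3, summing to
#'   1 when power is present).
#' @export
levelPowerSpectrum <- function(level_map) {
  m <- 1 * level_map
  if (!any(level_map))
    return(list(total_power = 0, ring_profile = c(0, 0, 0)))
  P <- Mod(fft(m))^2
  P[1L, 1L] <- 0
  h <- nrow(m); w <- ncol(m)
  total <- sum(P) / length(m)
  if (sum(P) < .EPS)
    return(list(total_power = 0, ring_profile = c(0, 0, 0)))
  fr <- matrix(.freq_axis(h) / h, h, w)
  fc <- matrix(.freq_axis(w) / w, h, w, byrow = TRUE)
  rad <- sqrt(fr^2 + fc^2)
  rad <- rad / max(rad)
  ring <- pmin(3L, floor(rad * 3L) + 1L)
  prof <- vapply(1:3, function(k) sum(P[ring == k]), numeric(1L)) / sum(P)
  list(total_power = total, ring_profile = prof)
}

#' Morphological pattern spectrum (PDF and CDF)
#'
#' Opens the map with near-isotropic cross ('+', diamond) structuring
#' elements of increasing radius; the PDF is the fraction of the original
#' area removed at each scale (non-negative, sums to <= 1; mass can remain
#' in structures larger than the biggest element), the CDF its cumulative
#' sum.
#'
#' @param level_map logical matrix.
#' @param scales structuring-element radii in increasing order (default 1:4).
#' @return list with `pdf`, `cdf` (per scale), `mean_scale` (granulometric
#'   mean radius, counting surviving mass at the largest radius + 1) and
#'   `residual` (mass never removed).
#' @export
morphSetPdfCdf <- function(level_map, scales = 1:4) {
  stopifnot(length(scales) >= 1L, all(diff(scales) > 0))
  a0 <- sum(level_map)
  if (a0 == 0)
    return(list(pdf = rep(0, length(scales)), cdf = rep(0, length(scales)),
                mean_scale = 0, residual = 0))
  areas <- numeric(length(scales))
  m <- 1 * level_map
  for (k in seq_along(scales)) {
    brush <- EBImage::makeBrush(2L * scales[k] + 1L, shape = "diamond")
    areas[k] <- sum(EBImage::opening(m, brush))
  }
  pdf <- (c(a0, areas[-length(areas)]) - areas) / a0
  pdf <- pmax(0, pdf)
  cdf <- cumsum(pdf)
  residual <- 1 - sum(pdf)
  mean_scale <- sum(scales * pdf) + (max(scales) + 1) * residual
  list(pdf = pdf, cdf = cdf, mean_scale = mean_scale, residual = residual)
}

# ---- Krawtchouk moments ---------------------------------------------------

#' Krawtchouk polynomial table
#'
#' Values of the classical (unnormalized) Krawtchouk polynomials
#' `K_m(x; p, N)`, defined by the terminating hypergeometric series
#' `2F1(-m, -x; -N; 1/p)`, for orders `m = 0..max_order` at `x = 0..N`.
#' Computed by the stable three-term recurrence in the order index.
#'
#' @param N polynomial support size parameter (support `x = 0..N`).
#' @param p success probability in (0, 1).
#' @param max_order highest order (<= N).
#' @return (max_order + 1) x (N + 1) matrix; row m+1 holds `K_m(0..N)`.
#' @export
krawtchoukPolynomials <- function(N, p, max_order = N) {
  stopifnot(p > 0, p < 1, max_order <= N, N >= 1)
  x <- 0:N
  K <- matrix(0, max_order + 1L, N + 1L)
  K[1L, ] <- 1
  if (max_order >= 1L) K[2L, ] <- 1 - x / (p * N)
  if (max_order >= 2L) {
    # (N - m) p K_{m+1} = [Np - 2mp + m - x] K_m - m (1 - p) K_{m-1}
    for (m in 1:(max_order - 1L)) {
      K[m + 2L, ] <- ((N * p - 2 * m * p + m - x) * K[m + 1L, ] -
                        m * (1 - p) * K[m, ]) / ((N - m) * p)
    }
  }
  K
}

#' Krawtchouk moments of an image or map
#'
#' Projects the (ROI-masked) image onto the separable basis
#' `K_m(row) K_n(col)` for `m + n <= max_order`, with polynomials over the
#' ROI bounding box (support size = box extent - 1, shared `p`).
#'
#' @inheritParams glcm
#' @param p Krawtchouk parameter in (0, 1) (default 0.5; 0.5 centres the
#'   basis, making odd-order moments of symmetric maps vanish).
#' @param max_order include moments with `m + n <= max_order` (default 3).
#' @return named numeric vector `k<m><n>` of moments, normalized by the
#'   pixel count of the bounding box.
#' @export
krawtchoukMoments <- function(image, roi = NULL, p = 0.5, max_order = 3L) {
  px <- .px(image)
  mask <- .roi(roi, dim(px))
  bb <- .bbox(mask)
  px <- px[bb$rows[1L]:bb$rows[2L], bb$cols[1L]:bb$cols[2L], drop = FALSE]
  sub <- mask[bb$rows[1L]:bb$rows[2L], bb$cols[1L]:bb$cols[2L], drop = FALSE]
  px <- px * sub
  Nr <- nrow(px) - 1L; Nc <- ncol(px) - 1L
  if (Nr < 1L || Nc < 1L) stop("ROI bounding box too small")
  ord <- min(max_order, Nr, Nc)
  Kr <- krawtchoukPolynomials(Nr, p, ord)
  Kc <- krawtchoukPolynomials(Nc, p, ord)
  out <- numeric(0)
  for (m in 0:ord) for (n in 0:(ord - m)) {
    val <- drop(Kr[m + 1L, , drop = FALSE] %*% px %*% t(Kc[n + 1L, , drop = FALSE]))
    out[sprintf("k%d%d", m, n)] <- val / length(px)
  }
  out
}

#' Plaque geometry descriptors
#'
#' Size (pixel count x spacing^2), a 2-D volume surrogate (per-column
#' vertical extent integral x spacing^2), convexity (area / convex hull
#' area), connectivity (8-connected component count) and a shape class
#' (circularity of the largest component). An empty mask reports zeros.
#'
#' @param plaque_mask \linkS4class{ROIMask} or logical matrix (may be empty).
#' @param spacing mm per pixel.
#' @return named numeric vector `size`, `volume`, `convexity`,
#'   `connectivity`, `shape`.
#' @export
plaqueGeometry <- function(plaque_mask, spacing = 1) {
  mask <- if (is(plaque_mask, "ROIMask")) plaque_mask@mask else plaque_mask
  if (!any(mask))
    return(c(size = 0, volume = 0, convexity = 0, connectivity = 0,
             shape = 0))
  area <- sum(mask)
  cols <- which(colSums(mask) > 0)
  extent <- vapply(cols, function(j) {
    r <- which(mask[, j]); max(r) - min(r) + 1L
  }, integer(1L))
  volume <- sum(extent) * spacing^2
  idx <- which(mask, arr.ind = TRUE)
  hull_area <- if (nrow(idx) >= 3L) {
    ch <- chull(idx[, 2L], idx[, 1L])
    abs(.signed_area(idx[ch, , drop = FALSE]))
  } else 0
  convexity <- if (hull_area > 0) min(1, area / hull_area) else 1
  connectivity <- max(EBImage::bwlabel(mask))
  shape <- tryCatch(circularity(.largest_component(mask)), error = function(e) 0)
  c(size = area * spacing^2, volume = volume, convexity = convexity,
    connectivity = connectivity, shape = shape)
}

#' Lumen surface roughness
#'
#' Root-mean-square deviation of a lumen boundary profile from its
#' moving-average smoothed version (window 11), in pixels. A straight or
#' slowly varying surface scores ~0; short-wavelength irregularity of
#' amplitude `a` scores ~`a/sqrt(2)`.
#'
#' @param profile numeric vector of boundary coordinates (e.g. the surface
#'   row per column), at least 8 points.
#' @param window moving-average window (odd, default 11).
#' @return numeric(1) RMS roughness.
#' @export
lumenSurfaceRoughness <- function(profile, window = 11L) {
  stopifnot(length(profile) >= 8L, window %% 2L == 1L)
  n <- length(profile)
  half <- (window - 1L) / 2L
  sm <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(profile[lo:hi])
  }, numeric(1L))
  sqrt(mean((profile - sm)^2))
}

#' Echogenicity components of a multilevel decomposition
#'
#' Fractions of the analysed region falling in the low (dark) and high
#' (bright) maps, with rule-based flags for a dominant lipid core (largest
#' dark component above `lipid_frac` of the region) and intraplaque
#' haemorrhage (above `haem_frac`).
#'
#' @param decomp a [multilevelThreshold()] decomposition, restricted to the
#'   plaque (or candidate) region.
#' @param lipid_frac,haem_frac area-fraction thresholds (defaults 0.2 and
#'   0.35).
#' @return named numeric vector `dark_fraction`, `bright_fraction`,
#'   `lipid_core`, `hemorrhage`.
#' @export
echogenicityComponents <- function(decomp, lipid_frac = 0.2,
                                   haem_frac = 0.35) {
  n <- sum(decomp$roi)
  if (n == 0L)
    return(c(dark_fraction = 0, bright_fraction = 0, lipid_core = 0,
             hemorrhage = 0))
  dark <- sum(decomp$low) / n
  bright <- sum(decomp$high) / n
  largest_dark <- if (any(decomp$low)) sum(.largest_component(decomp$low)) / n else 0
  c(dark_fraction = dark, bright_fraction = bright,
    lipid_core = as.numeric(largest_dark > lipid_frac),
    hemorrhage = as.numeric(largest_dark > haem_frac))
}

# echogenic plaque-candidate mask: medium+high components inside the ROI,
# cleaned by a radius-1 opening to suppress isolated speckle spikes
.plaque_candidate <- function(image, roi, t1 = 1 / 3) {
  px <- .px(image) / 255
  mask <- .roi(roi, dim(px))
  cand <- mask & px >= t1
  opened <- EBImage::opening(1 * cand, EBImage::makeBrush(3L, "diamond")) > 0
  opened & mask
}

#' The 15 plaque-morphology features
#'
#' Computed on the echogenic candidate region inside the analysis ROI
#' (intensity >= t1 after \[0,1\] normalization, opened with a radius-1
#' cross): granulometric mean PDF scale and mean CDF of the dark and bright
#' morphological sets; power of the three intensity-level maps; candidate
#' shape, connectivity and convexity; size and 2-D volume surrogate; lipid
#' core and haemorrhage flags; lumen surface roughness; and dark/bright
#' echogenic fractions.
#'
#' @inheritParams glcm
#' @param spacing mm per pixel (taken from the image when a
#'   \linkS4class{GrayImage} is given).
#' @param t1,t2 multilevel thresholds.
#' @return named numeric vector of length 15 (prefix `morph.`).
#' @export
morphologyFeatures <- function(image, roi = NULL, spacing = NULL,
                               t1 = 1 / 3, t2 = 2 / 3) {
  if (is.null(spacing))
    spacing <- if (is(image, "GrayImage")) image@spacing else 1
  px <- .px(image)
  mask <- .roi(roi, dim(px))
  cand <- .plaque_candidate(image, mask, t1)
  decomp <- multilevelThreshold(image, mask, t1, t2)
  ps_low <- levelPowerSpectrum(decomp$low)
  ps_med <- levelPowerSpectrum(decomp$medium)
  ps_high <- levelPowerSpectrum(decomp$high)
  gran_dark <- morphSetPdfCdf(decomp$low)
  gran_bright <- morphSetPdfCdf(decomp$high)
  pdf_mean <- (gran_dark$mean_scale + gran_bright$mean_scale) / 2
  cdf_mean <- (mean(gran_dark$cdf) + mean(gran_bright$cdf)) / 2
  geom <- plaqueGeometry(cand, spacing)
  # lumen surface: per column inside the ROI, the deepest candidate row
  # (the tissue/lumen interface an operator would trace)
  cols <- which(colSums(mask) > 0)
  surface <- vapply(cols, function(j) {
    rr <- which(cand[, j])
    if (length(rr)) max(rr) else min(which(mask[, j]))
  }, numeric(1L))
  rough <- if (length(surface) >= 8L) lumenSurfaceRoughness(surface) else 0
  # echogenic composition of the candidate *with its interior filled*, so
  # dark cores inside a bright plaque are counted as lipid/haemorrhage
  echo <- if (any(cand)) {
    filled <- EBImage::fillHull(1 * cand) > 0
    echogenicityComponents(multilevelThreshold(image, filled, t1, t2))
  } else
    c(dark_fraction = 0, bright_fraction = 0, lipid_core = 0, hemorrhage = 0)
  c(morph.pdf_mean = pdf_mean, morph.cdf_mean = cdf_mean,
    morph.power_low = ps_low$total_power,
    morph.power_medium = ps_med$total_power,
    morph.power_high = ps_high$total_power,
    morph.shape = unname(geom["shape"]),
    morph.connectivity = unname(geom["connectivity"]),
    morph.convexity = unname(geom["convexity"]),
    morph.size = unname(geom["size"]),
    morph.volume = unname(geom["volume"]),
    morph.lipid_core = unname(echo["lipid_core"]),
    morph.hemorrhage = unname(echo["hemorrhage"]),
    morph.lumen_roughness = rough,
    morph.dark_fraction = unname(echo["dark_fraction"]),
    morph.bright_fraction = unname(echo["bright_fraction"]))
}
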