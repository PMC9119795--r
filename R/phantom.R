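#' @include AllClasses.R core_io.R
NULL

#' Parameters for the layered artery phantom
#'
#' Describes a longitudinal B-mode-like view of a carotid artery: a bright
#' adventitia band at the top and bottom of the frame, an intima/media wall
#' band of thickness `imt_px` on each side, and a dark lumen core. An
#' echogenic (or echolucent) plaque can protrude from the near (upper) wall
#' into the lumen as a half-ellipse of height `plaque_height_px`. Fully
#' developed speckle is modelled as multiplicative unit-mean gamma noise with
#' shape `speckle_shape` (smaller shape = higher speckle contrast).
#'
#' @param height,width image size in pixels.
#' @param lumen_mean,wall_mean,adventitia_mean mean intensities (\[0, 255\])
#'   of the three tissue bands before speckle.
#' @param imt_px intima-media band thickness in pixels.
#' @param adventitia_px adventitia band thickness in pixels.
#' @param plaque_height_px half-ellipse plaque protrusion height; 0 = no
#'   plaque (a normal image).
#' @param plaque_width_px plaque base width (defaults to 3x its height).
#' @param plaque_echogenicity mean plaque intensity before speckle.
#' @param speckle_shape gamma shape of the multiplicative speckle (> 0).
#' @param attenuation linear intensity gain drop from top to bottom row
#'   (0 = off, default).
#' @param spacing mm per pixel.
#' @return a validated list of class `PhantomParams`.
#' @export
phantomParams <- function(height = 64L, width = 64L,
                          lumen_mean = 20, wall_mean = 120,
                          adventitia_mean = 180,
                          imt_px = 5L, adventitia_px = 8L,
                          plaque_height_px = 0L, plaque_width_px = NULL,
                          plaque_echogenicity = 150,
                          speckle_shape = 16, attenuation = 0,
                          spacing = 0.1) {
  if (is.null(plaque_width_px)) plaque_width_px <- 3L * plaque_height_px
  p <- list(height = as.integer(height), width = as.integer(width),
            lumen_mean = lumen_mean, wall_mean = wall_mean,
            adventitia_mean = adventitia_mean,
            imt_px = as.integer(imt_px),
            adventitia_px = as.integer(adventitia_px),
            plaque_height_px = as.integer(plaque_height_px),
            plaque_width_px = as.integer(plaque_width_px),
            plaque_echogenicity = plaque_echogenicity,
            speckle_shape = speckle_shape, attenuation = attenuation,
            spacing = spacing)
  if (p$lumen_mean >= p$wall_mean)
    stop("lumen must be darker than the wall band")
  if (p$plaque_height_px < 0L) stop("plaque_height_px must be >= 0")
  if (p$speckle_shape <= 0) stop("speckle_shape must be positive")
  lumen_rows <- p$height - 2L * (p$adventitia_px + p$imt_px)
  if (lumen_rows < 8L) stop("bands exceed the image height")
  if (p$plaque_height_px > lumen_rows - 2L)
    stop("plaque taller than the lumen")
  class(p) <- "PhantomParams"
  p
}

# noise-free tissue template + ground-truth plaque mask
.phantom_template <- function(p) {
  h <- p$height; w <- p$width
  img <- matrix(p$lumen_mean, h, w)
  adv <- p$adventitia_px; imt <- p$imt_px
  img[1:adv, ] <- p$adventitia_mean
  img[(h - adv + 1L):h, ] <- p$adventitia_mean
  img[(adv + 1L):(adv + imt), ] <- p$wall_mean
  img[(h - adv - imt + 1L):(h - adv), ] <- p$wall_mean
  mask <- matrix(FALSE, h, w)
  if (p$plaque_height_px > 0L) {
    # half-ellipse seated on the near-wall/lumen interface, opening downward
    a <- p$plaque_width_px / 2          # semi-axis along the wall
    b <- p$plaque_height_px             # protrusion depth into the lumen
    r0 <- adv + imt                      # last wall row (interface)
    c0 <- (w + 1) / 2
    rows <- matrix(seq_len(h), h, w)
    cols <- matrix(seq_len(w), h, w, byrow = TRUE)
    inside <- rows > r0 & ((cols - c0) / a)^2 + ((rows - r0) / b)^2 <= 1
    mask <- inside
    img[mask] <- p$plaque_echogenicity
  }
  list(image = img, mask = mask)
}

#' Generate one speckled artery phantom
#'
#' @param params a [phantomParams()] object.
#' @param seed integer seed; the same params + seed give a pixel-identical
#'   image.
#' @return list with `image` (\linkS4class{GrayImage}), `label` (1 iff a
#'   plaque was drawn), `plaque_mask` (ground truth, \linkS4class{ROIMask}
#'   when non-empty, else a logical matrix of `FALSE`), and `roi` (the
#'   analysis region: the lumen/wall-interface band an operator would
#'   delineate, \linkS4class{ROIMask}).
#' @export
generatePhantom <- function(params, seed = 1L) {
  tmpl <- .phantom_template(params)
  h <- params$height; w <- params$width
  img <- withr::with_seed(as.integer(seed), {
    speckle <- matrix(rgamma(h * w, shape = params$speckle_shape,
                             rate = params$speckle_shape), h, w)
    tmpl$image * speckle
  })
  if (params$attenuation > 0) {
    gain <- 1 - params$attenuation * (seq_len(h) - 1) / (h - 1)
    img <- img * gain
  }
  img <- matrix(pmin(255, pmax(0, round(img))), h, w)
  # analysis ROI: from the first lumen row (minus one wall row so the
  # interface is included) down to the far wall; what a reader would trace
  top <- params$adventitia_px + params$imt_px
  bottom <- h - params$adventitia_px - params$imt_px
  roi <- matrix(FALSE, h, w)
  roi[top:bottom, ] <- TRUE
  label <- as.integer(params$plaque_height_px > 0L)
  # very small plaques stay plain logical matrices (ROIMask requires the
  # 16-pixel minimum an analysis region needs)
  pm <- if (label == 1L && sum(tmpl$mask) >= 16L) roiMask(tmpl$mask) else
    tmpl$mask
  list(image = grayImage(img, spacing = params$spacing),
       label = label, plaque_mask = pm, roi = roiMask(roi))
}

#' Default per-image parameter ranges for phantom datasets
#'
#' Each entry is a `c(min, max)` range sampled uniformly per image. The
#' defaults emulate a routine B-mode study population: moderate wall/lumen
#' contrast variability, IMT 3-8 px, predominantly echogenic plaques 8-18 px
#' tall.
#' @return named list of ranges.
#' @export
phantomRanges <- function() {
  list(lumen_mean = c(15, 30), wall_mean = c(100, 140),
       adventitia_mean = c(160, 200), imt_px = c(3, 8),
       plaque_height_px = c(8, 18), plaque_echogenicity = c(130, 180),
       speckle_shape = c(10, 20))
}

#' Generate a labelled phantom dataset
#'
#' Per-image parameters are drawn uniformly from `ranges`; image `i` is
#' generated with seed `seed + i` so the dataset is reproducible and images
#' are independent.
#'
#' @param n_normal,n_plaque class sizes; the defaults mirror a 202 normal /
#'   159 plaque study population.
#' @param ranges named list of `c(min, max)` ranges as from [phantomRanges()].
#' @param seed integer seed.
#' @param height,width image size in pixels.
#' @return list with `images` (list of \linkS4class{GrayImage}), `labels`
#'   (integer vector), `masks` (ground-truth plaque masks), `rois` (analysis
#'   regions) and `params` (per-image [phantomParams()]).
#' @export
generateDataset <- function(n_normal = 202L, n_plaque = 159L,
                            ranges = phantomRanges(), seed = 1L,
                            height = 64L, width = 64L) {
  stopifnot(n_normal >= 1L || n_plaque >= 1L)
  for (r in ranges) if (length(r) != 2L || r[2] < r[1])
    stop("each range must be c(min, max) with max >= min")
  n <- n_normal + n_plaque
  labels <- rep(c(0L, 1L), c(n_normal, n_plaque))
  draw <- function(nm, u) {
    r <- ranges[[nm]]
    if (is.null(r)) stop("missing range: ", nm)
    r[1] + u * (r[2] - r[1])
  }
  u <- withr::with_seed(as.integer(seed),
                        matrix(runif(n * 7L), n, 7L))
  images <- vector("list", n); masks <- vector("list", n)
  rois <- vector("list", n); plist <- vector("list", n)
  for (i in seq_len(n)) {
    ph <- if (labels[i] == 1L) round(draw("plaque_height_px", u[i, 5])) else 0L
    p <- phantomParams(
      height = height, width = width,
      lumen_mean = draw("lumen_mean", u[i, 1]),
      wall_mean = draw("wall_mean", u[i, 2]),
      adventitia_mean = draw("adventitia_mean", u[i, 3]),
      imt_px = round(draw("imt_px", u[i, 4])),
      plaque_height_px = ph,
      plaque_echogenicity = draw("plaque_echogenicity", u[i, 6]),
      speckle_shape = draw("speckle_shape", u[i, 7]))
    out <- generatePhantom(p, seed = as.integer(seed) + i)
    images[[i]] <- out$image; masks[[i]] <- out$plaque_mask
    rois[[i]] <- out$roi; plist[[i]] <- p
  }
  list(images = images, labels = labels, masks = masks, rois = rois,
       params = plist)
}
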