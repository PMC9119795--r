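#' @include AllClasses.R utils.R
NULL

# ---- contour polygon ------------------------------------------------------

# shoelace signed area; vertices n x 2 (row, col); positive = counter-
# clockwise in the (row, col) frame used throughout the package
.signed_area <- function(v) {
  x <- v[, 2L]; y <- v[, 1L]
  i2 <- c(2:nrow(v), 1L)
  sum(x * y[i2] - x[i2] * y) / 2
}

# Douglas-Peucker simplification of an open chain (keeps endpoints)
.dp_simplify <- function(pts, tol) {
  n <- nrow(pts)
  if (n <= 2L || tol <= 0) return(pts)
  a <- pts[1L, ]; b <- pts[n, ]
  ab <- b - a
  len <- sqrt(sum(ab^2))
  d <- if (len < .EPS) {
    sqrt(rowSums((pts - matrix(a, n, 2L, byrow = TRUE))^2))
  } else {
    abs((pts[, 1L] - a[1L]) * ab[2L] - (pts[, 2L] - a[2L]) * ab[1L]) / len
  }
  k <- which.max(d)
  if (d[k] <= tol) return(pts[c(1L, n), , drop = FALSE])
  left <- .dp_simplify(pts[1:k, , drop = FALSE], tol)
  right <- .dp_simplify(pts[k:n, , drop = FALSE], tol)
  rbind(left[-nrow(left), , drop = FALSE], right)
}

# ordered 0-based (row, col) boundary of the largest component of a mask
.trace_boundary <- function(mask) {
  comp <- .largest_component(mask)
  oc <- EBImage::ocontour(1 * comp)[[1L]]
  # EBImage indexes dim1 as x: column 1 is our row, column 2 our col (0-based)
  cbind(row = oc[, 1L], col = oc[, 2L])
}

#' Polygonal approximation of an ROI boundary
#'
#' Traces the 8-connected boundary of the (largest component of the) ROI and
#' simplifies it with a Douglas-Peucker tolerance. Vertices are returned as
#' 0-based (row, col) coordinates ordered counter-clockwise in the
#' (row, col) frame (positive shoelace area); the polygon is closed
#' implicitly (last vertex connects to the first).
#'
#' @param roi an \linkS4class{ROIMask} or logical matrix.
#' @param tolerance_px Douglas-Peucker tolerance in pixels (default 1).
#' @return a list of class `ContourPolygon` with `vertices` (n x 2 matrix),
#'   `n`, `segment_lengths` (L_i from vertex i to i+1, cyclic) and
#'   `angles` (interior discontinuity angle at each vertex, in (0, 2*pi)).
#' @export
polygonApproximation <- function(roi, tolerance_px = 1) {
  mask <- if (is(roi, "ROIMask")) roi@mask else roi
  lab <- EBImage::bwlabel(mask)
  if (max(lab) > 1L)
    warning("disconnected ROI: using the largest component")
  pts <- .trace_boundary(mask)
  if (nrow(pts) >= 3L && tolerance_px > 0) {
    # split the closed chain at the two mutually most distant of
    # {first vertex, farthest vertex}, simplify each half
    d0 <- rowSums((pts - matrix(pts[1L, ], nrow(pts), 2L, byrow = TRUE))^2)
    k <- which.max(d0)
    if (k > 2L && k < nrow(pts)) {
      h1 <- .dp_simplify(pts[1:k, , drop = FALSE], tolerance_px)
      h2 <- .dp_simplify(rbind(pts[k:nrow(pts), , drop = FALSE], pts[1L, ]),
                         tolerance_px)
      pts <- rbind(h1[-nrow(h1), , drop = FALSE],
                   h2[-nrow(h2), , drop = FALSE])
    }
  }
  pts <- unique(pts)
  if (nrow(pts) < 3L) {
    # simplification collapsed a thin region: fall back to the raw chain
    pts <- unique(.trace_boundary(mask))
    if (nrow(pts) < 3L)
      stop("boundary degenerated to fewer than 3 vertices")
  }
  if (.signed_area(pts) < 0) pts <- pts[nrow(pts):1L, , drop = FALSE]
  contourPolygon(pts)
}

#' Build a ContourPolygon from vertices
#'
#' @param vertices n x 2 matrix of (row, col) vertex coordinates, ordered,
#'   closed implicitly. Reversed internally if not counter-clockwise.
#' @return a `ContourPolygon` list (see [polygonApproximation()]).
#' @export
contourPolygon <- function(vertices) {
  vertices <- as.matrix(vertices)
  stopifnot(ncol(vertices) == 2L, nrow(vertices) >= 3L)
  if (.signed_area(vertices) < 0)
    vertices <- vertices[nrow(vertices):1L, , drop = FALSE]
  n <- nrow(vertices)
  nxt <- c(2:n, 1L)
  prv <- c(n, 1:(n - 1L))
  e_out <- vertices[nxt, , drop = FALSE] - vertices
  seg <- sqrt(rowSums(e_out^2))
  e_in <- vertices - vertices[prv, , drop = FALSE]
  # interior angle = pi - signed turn; total turn of a CCW simple polygon
  # is +2*pi, so interior angles lie in (0, 2*pi)
  cross <- e_in[, 2L] * e_out[, 1L] - e_in[, 1L] * e_out[, 2L]
  dot <- rowSums(e_in * e_out)
  turn <- atan2(cross, dot)
  angles <- pi - turn
  structure(list(vertices = vertices, n = n, segment_lengths = seg,
                 angles = angles), class = "ContourPolygon")
}

#' Contour sharpness
#'
#' `sum_i max(0, 1 - |2*theta_i - pi| / pi)^2 / n` over the interior
#' discontinuity angles; 1 when every corner is a right angle, 0 for a
#' straight (angle pi) boundary. The absolute value keeps the per-vertex
#' term in \[0, 1\] for reflex angles.
#'
#' @param poly a `ContourPolygon`.
#' @return numeric(1) in \[0, 1\].
#' @export
sharpness <- function(poly) {
  th <- poly$angles
  mean(pmax(0, 1 - abs(2 * th - pi) / pi)^2)
}

#' Contour complexity
#'
#' Vertex count scaled by 1e-3 (monotone in the number of polygon sides).
#'
#' @param poly a `ContourPolygon`.
#' @return numeric(1)
#' @export
shapeComplexity <- function(poly) 1e-3 * poly$n

#' Length irregularity
#'
#' Cyclic sum of absolute consecutive segment-length differences divided by
#' K, where K = 2P for n > 3 and K = P for n = 3 (P = perimeter). Zero for
#' equilateral polygons.
#'
#' @param poly a `ContourPolygon`.
#' @return numeric(1)
#' @export
lengthIrregularity <- function(poly) {
  L <- poly$segment_lengths
  P <- sum(L)
  K <- if (poly$n > 3L) 2 * P else P
  sum(abs(L - L[c(2:poly$n, 1L)])) / K
}

#' Aspect ratio
#'
#' `(p1 + p2) / C`, where p1 and p2 are the largest perpendicular distances
#' from the principal axis of the vertices to the boundary on either side,
#' and C is the chord length of the shape along the principal axis. A circle
#' scores 1; elongated shapes score < 1. Scale-invariant.
#'
#' @param poly a `ContourPolygon`.
#' @return numeric(1)
#' @export
aspectRatio <- function(poly) {
  v <- poly$vertices
  ctr <- colMeans(v)
  vc <- sweep(v, 2L, ctr)
  cv <- crossprod(vc) / nrow(vc)
  eg <- eigen(cv, symmetric = TRUE)
  axis <- eg$vectors[, 1L]
  proj <- vc %*% axis
  perp <- vc %*% eg$vectors[, 2L]
  C <- max(proj) - min(proj)
  if (C < .EPS) stop("degenerate polygon: no principal extent")
  p1 <- max(c(perp, 0)); p2 <- -min(c(perp, 0))
  if (p1 + p2 < .EPS) stop("degenerate (collinear) polygon")
  (p1 + p2) / C
}

#' Circularity
#'
#' `4*pi*A / P^2`: 1 for an ideal circle, smaller for elongated shapes. For
#' a `ContourPolygon`, A and P are the shoelace area and polygon perimeter.
#' For a mask, the boundary is traced and simplified with a 1-pixel
#' tolerance first, so that digital staircase steps do not inflate the
#' perimeter; values may exceed 1 by a small discretization slack.
#'
#' @param x a `ContourPolygon`, \linkS4class{ROIMask} or logical matrix.
#' @return numeric(1)
#' @export
circularity <- function(x) {
  poly <- if (inherits(x, "ContourPolygon")) x else polygonApproximation(x, 1)
  A <- abs(.signed_area(poly$vertices))
  P <- sum(poly$segment_lengths)
  if (A <= 0 || P <= 0) stop("area and perimeter must be positive")
  4 * pi * A / P^2
}

#' Region properties of an ROI
#'
#' Pixel-count area, crack-boundary perimeter (count of exposed pixel edges,
#' so a 10 x 10 square has perimeter 40), perimeter^2/area, and the 0-based
#' centroid (x = column, y = row).
#'
#' @param roi an \linkS4class{ROIMask} or logical matrix.
#' @return named numeric vector `centroid_x`, `centroid_y`, `area`,
#'   `perimeter`, `perimeter_sq_over_area`.
#' @export
regionProps <- function(roi) {
  mask <- if (is(roi, "ROIMask")) roi@mask else roi
  if (!any(mask)) stop("empty ROI")
  area <- sum(mask)
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- mask
  inner <- pad[2:(h + 1L), 2:(w + 1L)]
  exposed <- (inner & !pad[1:h, 2:(w + 1L)]) + (inner & !pad[3:(h + 2L), 2:(w + 1L)]) +
    (inner & !pad[2:(h + 1L), 1:w]) + (inner & !pad[2:(h + 1L), 3:(w + 2L)])
  perim <- sum(exposed)
  idx <- which(mask, arr.ind = TRUE)
  c(centroid_x = mean(idx[, 2L]) - 1, centroid_y = mean(idx[, 1L]) - 1,
    area = area, perimeter = perim,
    perimeter_sq_over_area = perim^2 / area)
}

#' The 5 contour shape features
#'
#' Sharpness, complexity, length irregularity, aspect ratio and circularity
#' of the polygonal boundary approximation of a region.
#'
#' @inheritParams polygonApproximation
#' @return named numeric vector of length 5 (prefix `shape.`).
#' @export
shapeFeatures <- function(roi, tolerance_px = 1) {
  poly <- polygonApproximation(roi, tolerance_px)
  c(shape.sharpness = sharpness(poly),
    shape.complexity = shapeComplexity(poly),
    shape.length_irregularity = lengthIrregularity(poly),
    shape.aspect_ratio = aspectRatio(poly),
    shape.circularity = circularity(poly))
}
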