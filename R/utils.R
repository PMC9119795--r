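#' @include AllClasses.R
NULL

# ---- internal helpers shared across feature families ----------------------

# coerce GrayImage | matrix -> plain numeric matrix
.px <- function(image) {
  if (is(image, "GrayImage")) return(image@pixels)
  if (is.matrix(image)) return(image)
  stop("expected a GrayImage or a numeric matrix")
}

# coerce ROIMask | logical matrix | NULL -> logical matrix matching `dims`
.roi <- function(roi, dims) {
  if (is.null(roi)) return(matrix(TRUE, dims[1L], dims[2L]))
  m <- if (is(roi, "ROIMask")) roi@mask else roi
  if (!is.logical(m)) m <- m > 0
  if (!identical(dim(m), as.integer(dims)))
    stop("ROI dimensions do not match the image")
  m
}

# quantize [0,255] intensities to integer levels 0..levels-1
.quantize <- function(pixels, levels) {
  q <- floor(pixels * levels / 256)
  q[q > levels - 1L] <- levels - 1L
  q
}

# Shannon entropy in bits of a probability vector; 0 log 0 := 0
.entropy_bits <- function(p) {
  p <- p[p > 0]
  if (length(p) == 0L) return(0)
  -sum(p * log2(p))
}

# valid pixel-pair index grids for an integer offset (dr, dc) inside dims;
# returns NULL when no pair fits
.pair_window <- function(dims, dr, dc) {
  h <- dims[1L]; w <- dims[2L]
  r0 <- max(1L, 1L - dr); r1 <- min(h, h - dr)
  c0 <- max(1L, 1L - dc); c1 <- min(w, w - dc)
  if (r0 > r1 || c0 > c1) return(NULL)
  list(rows = r0:r1, cols = c0:c1, dr = dr, dc = dc)
}

# absolute-difference sample |I(p) - I(p+d)| over pairs with both ends in ROI
.pair_absdiff <- function(pixels, mask, dr, dc) {
  win <- .pair_window(dim(pixels), dr, dc)
  if (is.null(win)) return(numeric(0))
  a <- pixels[win$rows, win$cols, drop = FALSE]
  b <- pixels[win$rows + dr, win$cols + dc, drop = FALSE]
  ok <- mask[win$rows, win$cols, drop = FALSE] &
    mask[win$rows + dr, win$cols + dc, drop = FALSE]
  abs(a[ok] - b[ok])
}

# 2-D linear convolution/correlation restricted to fully-valid windows:
# returns the filter response and a validity mask (TRUE where every pixel of
# the kernel footprint lies inside the ROI). Kernel must have odd dims.
.filter_valid <- function(pixels, mask, kernel) {
  resp <- EBImage::filter2(pixels, kernel, boundary = 0)
  cover <- EBImage::filter2(matrix(1, nrow(pixels), ncol(pixels)),
                            abs(kernel) > 0, boundary = 0)
  inroi <- EBImage::filter2(1 * mask, abs(kernel) > 0, boundary = 0)
  need <- sum(abs(kernel) > 0)
  valid <- abs(cover - need) < 0.5 & abs(inroi - need) < 0.5
  list(response = resp, valid = valid)
}

# fftshift-style centred frequency index for length n: 0 at position
# floor(n/2)+1 after shifting
.freq_axis <- function(n) {
  k <- seq_len(n) - 1L
  k[k >= ceiling(n / 2)] <- k[k >= ceiling(n / 2)] - n
  k
}

# bounding-box crop of a mask; returns row/col ranges
.bbox <- function(mask) {
  rows <- which(rowSums(mask) > 0)
  cols <- which(colSums(mask) > 0)
  list(rows = range(rows), cols = range(cols))
}

# largest connected component (8-connectivity) of a logical mask
.largest_component <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  if (max(lab) < 1) return(mask & FALSE)
  sizes <- tabulate(lab[lab > 0])
  lab == which.max(sizes)
}

.check_flag <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(what, " must be a finite scalar")
  x
}
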