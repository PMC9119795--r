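# Brute-force oracles and fixture builders shared across the suite.
# Every oracle is written independently of the package's implementation:
# explicit per-pixel loops and series sums, frozen conventions.

rot90cw <- function(m) t(m)[, nrow(m):1, drop = FALSE]

random_image <- function(h, w, seed) {
  withr::with_seed(seed, matrix(sample(0:255, h * w, replace = TRUE), h, w))
}

disk_mask <- function(n, r, cx = (n + 1) / 2, cy = (n + 1) / 2) {
  outer(1:n, 1:n, function(i, j) (i - cy)^2 + (j - cx)^2 <= r^2)
}

# co-occurrence by explicit pair enumeration
oracle_glcm <- function(px, levels, dr, dc) {
  q <- floor(px * levels / 256); q[q > levels - 1] <- levels - 1
  cm <- matrix(0, levels, levels)
  for (i in seq_len(nrow(px))) for (j in seq_len(ncol(px))) {
    i2 <- i + dr; j2 <- j + dc
    if (i2 >= 1 && i2 <= nrow(px) && j2 >= 1 && j2 <= ncol(px))
      cm[q[i, j] + 1, q[i2, j2] + 1] <- cm[q[i, j] + 1, q[i2, j2] + 1] + 1
  }
  cm / sum(cm)
}

# NGTDM by a per-pixel loop (classical coarseness/contrast/complexity/
# strength with the same 1e-9 guards)
oracle_ngtdm <- function(px, levels) {
  q <- floor(px * levels / 256); q[q > levels - 1] <- levels - 1
  h <- nrow(px); w <- ncol(px)
  si <- rep(0, levels); ni <- rep(0, levels); n <- 0
  for (i in 2:(h - 1)) for (j in 2:(w - 1)) {
    A <- (sum(q[(i - 1):(i + 1), (j - 1):(j + 1)]) - q[i, j]) / 8
    k <- q[i, j]
    si[k + 1] <- si[k + 1] + abs(k - A)
    ni[k + 1] <- ni[k + 1] + 1
    n <- n + 1
  }
  p <- ni / n; lv <- 0:(levels - 1); pres <- which(p > 0)
  coarse <- min(1e9, 1 / (1e-9 + sum(p * si)))
  Ng <- length(pres)
  if (Ng > 1) {
    dd2 <- outer(lv[pres], lv[pres], function(a, b) (a - b)^2)
    con <- sum(outer(p[pres], p[pres]) * dd2) / (Ng * (Ng - 1)) * sum(si) / n
    comp <- sum(outer(lv[pres], lv[pres], function(a, b) abs(a - b)) *
                  outer(p[pres] * si[pres], p[pres] * si[pres], "+") /
                  (n * outer(p[pres], p[pres], "+")))
    stre <- sum(outer(p[pres], p[pres], "+") * dd2) / (1e-9 + sum(si))
  } else {
    con <- 0; comp <- 0; stre <- 0
  }
  c(coarseness = coarse, contrast = con, complexity = comp, strength = stre)
}

# uniform rotation-invariant LBP histogram, bit by bit
oracle_lbp <- function(px) {
  h <- nrow(px); w <- ncol(px); bins <- rep(0, 10)
  sh <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1),
             c(0, -1), c(1, -1), c(1, 0), c(1, 1))
  for (i in 2:(h - 1)) for (j in 2:(w - 1)) {
    b <- vapply(sh, function(s) px[i + s[1], j + s[2]] >= px[i, j], logical(1))
    u <- sum(b != b[c(2:8, 1)])
    k <- if (u <= 2) sum(b) else 9
    bins[k + 1] <- bins[k + 1] + 1
  }
  bins / sum(bins)
}

# run-length statistics at 0 degrees by row-wise run enumeration
oracle_runlength0 <- function(px, levels) {
  q <- floor(px * levels / 256); q[q > levels - 1] <- levels - 1
  maxl <- max(dim(px))
  R <- matrix(0, levels, maxl)
  for (i in seq_len(nrow(q))) {
    r <- rle(q[i, ])
    for (k in seq_along(r$values))
      R[r$values[k] + 1, r$lengths[k]] <- R[r$values[k] + 1, r$lengths[k]] + 1
  }
  nr <- sum(R); lens <- seq_len(maxl)
  c(sre = sum(colSums(R) / lens^2) / nr,
    lre = sum(colSums(R) * lens^2) / nr,
    gln = sum(rowSums(R)^2) / nr,
    rln = sum(colSums(R)^2) / nr,
    rp = nr / length(px))
}

# Krawtchouk polynomial value by the terminating hypergeometric sum
# 2F1(-m, -x; -N; 1/p) = sum_k (-m)_k (-x)_k / (-N)_k / k! (1/p)^k
oracle_krawtchouk <- function(m, x, p, N) {
  poch <- function(a, k) if (k == 0) 1 else prod(a + 0:(k - 1))
  s <- 0
  for (k in 0:m)
    s <- s + poch(-m, k) * poch(-x, k) / poch(-N, k) / factorial(k) / p^k
  s
}

# feature table with a planted discriminative subset: `planted` columns get
# a between-class mean shift of `delta` standard deviations, the rest are
# pure noise with identical class distributions
planted_table <- function(n_per_class, n_features, planted, delta, seed) {
  withr::with_seed(seed, {
    y <- rep(0:1, each = n_per_class)
    X <- matrix(rnorm(2 * n_per_class * n_features), 2 * n_per_class)
    colnames(X) <- sprintf("f%02d", seq_len(n_features))
    X[y == 1, planted] <- X[y == 1, planted] + delta
    list(x = X, y = y)
  })
}

# two-feature dataset whose class structure lives only in the sign of the
# within-class correlation (identical marginals; Naive Bayes is blind to it)
correlated_classes <- function(n, seed, noise_sd = 0.25) {
  withr::with_seed(seed, {
    u <- rnorm(n); e <- rnorm(n, sd = noise_sd)
    y <- rep(0:1, length.out = n)
    x2 <- ifelse(y == 0, u, -u) + e
    list(x = cbind(f1 = u, f2 = x2), y = y)
  })
}
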