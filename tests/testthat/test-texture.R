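# -- co-occurrence ----------------------------------------------------------

test_that("co-occurrence counts match direct pair enumeration", {
  m <- rbind(c(0, 0), c(255, 255))
  g0 <- glcm(m, levels = 2, theta = 0)
  expect_equal(g0$counts, diag(c(0.5, 0.5)))
  g90 <- glcm(m, levels = 2, theta = 90)
  expect_equal(g90$counts[1, 2], 1)
  expect_equal(sum(g90$counts), 1)
  gc <- glcm(matrix(100, 4, 4), levels = 4, theta = 45)
  expect_equal(sum(diag(gc$counts)), 1)   # constant image: one diagonal cell
  # randomized oracle check over all four angles
  px <- random_image(8, 8, seed = 42)
  offs <- list("0" = c(0, 1), "45" = c(1, 1), "90" = c(1, 0),
               "135" = c(1, -1))
  for (th in names(offs)) {
    expect_equal(glcm(px, levels = 8, theta = as.numeric(th))$counts,
                 oracle_glcm(px, 8, offs[[th]][1], offs[[th]][2]),
                 tolerance = 1e-12, info = paste("angle", th))
  }
})

test_that("co-occurrence features follow their closed forms", {
  idm <- diag(4) / 4
  expect_equal(unname(glcmFeatures(idm)["contrast"]), 0)
  f <- glcmFeatures(rbind(c(0, 1), c(0, 0)))
  expect_equal(unname(f["contrast"]), 1)
  expect_equal(unname(f["homogeneity"]), 0.5)
  expect_equal(unname(f["inertia"]), unname(f["contrast"]))
  fu <- glcmFeatures(matrix(0.25, 2, 2))
  expect_equal(unname(fu["energy"]), 0.25)
  expect_equal(unname(fu["entropy"]), 2)
  expect_error(glcmFeatures(matrix(1, 2, 2)), "normalized")
})

test_that("4-angle mean co-occurrence features are 90-degree rotation invariant", {
  px <- random_image(12, 12, seed = 11)
  expect_equal(glcmMeanFeatures(px, levels = 8),
               glcmMeanFeatures(rot90cw(px), levels = 8), tolerance = 1e-10)
})

# -- first-order ------------------------------------------------------------

test_that("first-order statistics use moment conventions with guards", {
  f <- firstOrderStats(matrix(c(1, 2, 3, 1, 2, 3, 1, 2, 3), 3))
  expect_equal(unname(f["skewness"]), 0)
  fc <- firstOrderStats(matrix(9, 8, 8))
  expect_equal(unname(fc[c("skewness", "kurtosis")]), c(0, 0))
  f2 <- firstOrderStats(matrix(c(0, 0, 0, 255), 2))
  expect_equal(unname(f2["mean"]), 63.75)
  expect_equal(unname(f2["median"]), 0)
})

# -- gray-level difference statistics --------------------------------------

test_that("difference statistics reduce correctly on designed patterns", {
  const <- gldsFeatures(matrix(7, 8, 8))
  expect_equal(unname(const), c(0, 0, 0, 1, 1),
               tolerance = 1e-12)  # mean, entropy, contrast, asm, homogeneity
  stripes <- matrix(rep(c(0, 255), 8), 8, 16, byrow = TRUE)
  g <- gldsFeatures(stripes, offsets = list(c(0, 1)))
  expect_equal(unname(g["mean"]), 255)
  checker <- 255 * outer(1:8, 1:8, function(i, j) (i + j) %% 2)
  expect_equal(gldsFeatures(checker, offsets = list(c(0, 1))),
               gldsFeatures(checker, offsets = list(c(1, 0))))
})

# -- fractal dimension ------------------------------------------------------

test_that("box-counting dimension is ~2 for flat surfaces and fits the log-log slope", {
  expect_equal(fdtaFractalDimension(matrix(128, 32, 32)), 2,
               tolerance = 0.05)
  # independent closed-form slope oracle on the same counts
  px <- random_image(24, 24, seed = 13)
  scales <- 2:4
  counts <- vapply(scales, function(s) {
    h <- s * 256 / 24; n <- 0
    for (i in seq_len(24 %/% s)) for (j in seq_len(24 %/% s)) {
      blk <- px[((i - 1) * s + 1):(i * s), ((j - 1) * s + 1):(j * s)]
      n <- n + (floor(max(blk) / h) - floor(min(blk) / h) + 1)
    }
    n
  }, numeric(1))
  x <- log(1 / scales); y <- log(counts)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(fdtaFractalDimension(px), slope, tolerance = 1e-9)
  expect_error(fdtaFractalDimension(px, max_scale = 2), "degenerate")
})

# -- Fourier power spectrum -------------------------------------------------

test_that("spectrum partitions are normalized and orientation-selective", {
  px <- random_image(16, 16, seed = 14)
  fs <- fourierSpectrumSums(px)
  expect_equal(sum(fs$ring_sums), 1, tolerance = 1e-9)
  expect_equal(sum(fs$wedge_sums), 1, tolerance = 1e-9)
  expect_equal(sum(fourierSpectrumSums(matrix(50, 16, 16))$ring_sums), 0)
  sin_h <- matrix(127 + 100 * sin(2 * pi * 0.25 * (1:32)), 32, 32,
                  byrow = TRUE)
  wedge <- fourierSpectrumSums(sin_h, n_wedges = 4)$wedge_sums
  expect_equal(which.max(wedge), 1)   # energy on the horizontal axis
})

# -- NGTDM ------------------------------------------------------------------

test_that("NGTDM features match a per-pixel loop oracle", {
  for (seed in c(21, 22, 23)) {
    px <- random_image(8, 8, seed = seed)
    expect_equal(ngtdmFeatures(px, levels = 8), oracle_ngtdm(px, 8),
                 tolerance = 1e-6, info = paste("seed", seed))
  }
  const <- ngtdmFeatures(matrix(4, 8, 8), levels = 8)
  expect_equal(unname(const["coarseness"]), 1e9)
  expect_equal(unname(const["contrast"]), 0)
})

test_that("coarse blocky texture scores coarser than a fine checkerboard", {
  blocky <- matrix(0, 16, 16); blocky[1:8, ] <- 200; blocky[9:16, 1:8] <- 100
  checker <- 255 * outer(1:16, 1:16, function(i, j) (i + j) %% 2)
  expect_gt(ngtdmFeatures(blocky, levels = 8)["coarseness"],
            ngtdmFeatures(checker, levels = 8)["coarseness"])
})

# -- SFM --------------------------------------------------------------------

test_that("statistical feature matrix summaries behave on designed textures", {
  expect_equal(unname(sfmFeatures(matrix(9, 16, 16))["contrast"]), 0)
  stripes <- matrix(rep(c(0, 255), 10), 20, 20)     # period 2 along rows
  noise <- random_image(20, 20, seed = 15)
  expect_gt(sfmFeatures(stripes)["periodicity"],
            sfmFeatures(noise)["periodicity"])
  # SFM contrast at a single displacement is the root of the GLDS contrast
  px <- random_image(20, 20, seed = 16)
  s <- sfmFeatures(px, offsets = list(c(0, 1)))
  g <- gldsFeatures(px, offsets = list(c(0, 1)))
  expect_equal(unname(s["contrast"])^2, unname(g["contrast"]),
               tolerance = 1e-9)
})

# -- absolute gradient ------------------------------------------------------

test_that("gradient magnitude statistics follow central differences", {
  expect_equal(unname(absGradientFeatures(matrix(3, 10, 10))), c(0, 0))
  ramp <- matrix(1:20, 20, 20, byrow = TRUE)
  g <- absGradientFeatures(ramp)
  expect_equal(unname(g["mean"]), 1)
  expect_lt(unname(g["variance"]), 1e-12)
  px <- random_image(14, 14, seed = 17)
  expect_equal(absGradientFeatures(px), absGradientFeatures(rot90cw(px)),
               tolerance = 1e-10)
})

# -- LBP --------------------------------------------------------------------

test_that("uniform LBP codes match a bit-by-bit oracle", {
  for (seed in c(31, 32)) {
    px <- random_image(8, 8, seed = seed)
    expect_equal(unname(lbpHistogram(px)), oracle_lbp(px),
                 tolerance = 1e-12, info = paste("seed", seed))
  }
  h <- lbpHistogram(random_image(10, 10, seed = 33))
  expect_equal(sum(h), 1, tolerance = 1e-12)
  expect_equal(unname(lbpHistogram(matrix(5, 8, 8))["u8"]), 1)
})

# -- Gabor ------------------------------------------------------------------

test_that("Gabor bank responses are zero on flat input and orientation tuned", {
  flat <- gaborFeatures(matrix(100, 24, 24))
  expect_lt(max(flat$mean), 1e-6)
  sg <- matrix(127 + 100 * sin(2 * pi * 0.3 * (1:32)), 32, 32, byrow = TRUE)
  gb <- gaborFeatures(sg, frequencies = 0.3)
  expect_gte(gb$mean[gb$orientation == 0], gb$mean[gb$orientation == 90])
  # rotating the image by 90 degrees permutes the orientation features
  gr <- gaborFeatures(rot90cw(sg), frequencies = 0.3)
  expect_equal(gr$mean[gr$orientation == 90], gb$mean[gb$orientation == 0],
               tolerance = 0.1 * max(gb$mean))
})

# -- run length -------------------------------------------------------------

test_that("run-length statistics match run enumeration", {
  px <- random_image(6, 6, seed = 41)
  expect_equal(runLengthFeatures(px, levels = 4, directions = 0),
               oracle_runlength0(px, 4), tolerance = 1e-9)
  checker <- 255 * outer(1:6, 1:6, function(i, j) (i + j) %% 2)
  expect_equal(unname(runLengthFeatures(checker, levels = 2,
                                        directions = c(0, 90))["sre"]), 1)
  const <- runLengthFeatures(matrix(80, 6, 6), levels = 4, directions = 0)
  expect_equal(unname(const["lre"]), 36)   # one run of length 6 per row
  expect_equal(unname(const["rp"]), 1 / 6)
})

# -- family-wide invariants -------------------------------------------------

test_that("normalized matrices sum to one and features stay in range", {
  for (seed in 51:53) {
    px <- random_image(16, 16, seed = seed)
    expect_equal(sum(glcm(px, levels = 8)$counts), 1, tolerance = 1e-9)
    expect_equal(sum(lbpHistogram(px)), 1, tolerance = 1e-9)
    f <- glcmFeatures(glcm(px, levels = 8)$counts)
    expect_true(f["energy"] > 0 && f["energy"] <= 1)
    expect_true(f["homogeneity"] > 0 && f["homogeneity"] <= 1)
    expect_gte(f["contrast"], 0)
    expect_true(f["entropy"] >= 0 && f["entropy"] <= 2 * log2(8))
  }
})

test_that("the texture block has its 33 named entries, all finite", {
  px <- random_image(32, 32, seed = 61)
  tf <- textureFeatures(px)
  expect_length(tf, 33)
  expect_true(all(is.finite(tf)))
  expect_identical(names(tf), carotexFeatureNames()[1:33])
})
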