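test_that("multilevel thresholding partitions the ROI", {
  de0 <- multilevelThreshold(matrix(0, 9, 9))
  expect_equal(sum(de0$low), 81)
  three <- matrix(c(0.1, 0.5, 0.9) * 255, 9, 9)
  de <- multilevelThreshold(three)
  expect_equal(sum(de$low), 27)
  expect_equal(sum(de$medium), 27)
  expect_equal(sum(de$high), 27)
  expect_true(all(de$low + de$medium + de$high == 1))
  expect_error(multilevelThreshold(three, t1 = 0.7, t2 = 0.3))
})

test_that("level-map power spectra separate compact from scattered sets", {
  expect_equal(levelPowerSpectrum(matrix(FALSE, 8, 8))$total_power, 0)
  expect_equal(levelPowerSpectrum(matrix(TRUE, 8, 8))$total_power, 0)
  blob <- matrix(FALSE, 32, 32); blob[14:19, 14:19] <- TRUE
  scat <- matrix(FALSE, 32, 32)
  scat[withr::with_seed(2, sample(1024, 36))] <- TRUE
  pb <- levelPowerSpectrum(blob); ps <- levelPowerSpectrum(scat)
  expect_gt(ps$ring_profile[3], pb$ring_profile[3])
  expect_equal(sum(pb$ring_profile), 1, tolerance = 1e-9)
})

test_that("the pattern spectrum localizes structure scale", {
  single <- matrix(FALSE, 16, 16)
  single[cbind(c(3, 8, 13), c(3, 8, 13))] <- TRUE
  g <- morphSetPdfCdf(single, 1:3)
  expect_equal(g$pdf[1], 1)              # single pixels vanish at radius 1
  expect_equal(g$cdf[3], 1)
  expect_true(all(g$pdf >= 0))
  expect_lte(sum(g$pdf), 1 + 1e-12)
  big <- matrix(FALSE, 24, 24); big[6:19, 6:19] <- TRUE
  gb <- morphSetPdfCdf(big, 1:3)
  expect_gt(gb$residual, 0.5)            # survives every element
  expect_equal(morphSetPdfCdf(matrix(FALSE, 8, 8))$mean_scale, 0)
})

test_that("Krawtchouk polynomials match the hypergeometric series", {
  K <- krawtchoukPolynomials(8, 0.3, 8)
  for (m in 0:8) for (x in 0:8)
    expect_equal(K[m + 1, x + 1], oracle_krawtchouk(m, x, 0.3, 8),
                 tolerance = 1e-8)
  expect_true(all(krawtchoukPolynomials(6, 0.5, 0)[1, ] == 1))
  # K_1(x; p, N) = 1 - x/(pN), zero at x = pN
  expect_equal(krawtchoukPolynomials(4, 0.5, 1)[2, 3], 0)
})

test_that("odd-order moments of a symmetric map vanish at p = 0.5", {
  symm <- matrix(0, 9, 9); symm[3:7, 3:7] <- 255
  km <- krawtchoukMoments(symm, p = 0.5, max_order = 3)
  expect_equal(unname(km[c("k10", "k01", "k30", "k03", "k12", "k21")]),
               rep(0, 6), tolerance = 1e-9)
  expect_gt(abs(km["k00"]), 0)
})

test_that("plaque geometry handles empty, convex and split masks", {
  expect_equal(unname(plaqueGeometry(matrix(FALSE, 8, 8))), rep(0, 5))
  blob <- matrix(FALSE, 20, 20); blob[5:14, 5:14] <- TRUE
  pg <- plaqueGeometry(blob, spacing = 0.5)
  expect_equal(unname(pg["size"]), 100 * 0.25)
  expect_equal(unname(pg["volume"]), 100 * 0.25)  # no holes: extent = count
  expect_gte(unname(pg["convexity"]), 0.98)
  two <- blob; two[17:19, 17:19] <- TRUE
  expect_equal(unname(plaqueGeometry(two)["connectivity"]), 2)
  expect_lt(unname(plaqueGeometry(two)["convexity"]), 1)
})

test_that("lumen roughness is the RMS of the short-wavelength residual", {
  expect_equal(lumenSurfaceRoughness(rep(5, 50)), 0)
  a <- 3
  srf <- 10 + a * sin(2 * pi * (1:200) / 4)
  expect_equal(lumenSurfaceRoughness(srf), a / sqrt(2), tolerance = 0.15 * a)
  r <- vapply(c(0.5, 1, 2, 4), function(amp)
    lumenSurfaceRoughness(10 + amp * sin(2 * pi * (1:200) / 4)), numeric(1))
  expect_true(all(diff(r) > 0))   # monotone in amplitude
})

test_that("echogenicity fractions and flags follow the decomposition", {
  bright <- echogenicityComponents(multilevelThreshold(matrix(250, 16, 16)))
  expect_equal(unname(bright), c(0, 1, 0, 0))
  half <- matrix(250, 16, 16); half[, 1:8] <- 20
  e <- echogenicityComponents(multilevelThreshold(half))
  expect_equal(unname(e["dark_fraction"]), 0.5)
  expect_equal(unname(e["lipid_core"]), 1)
  expect_equal(unname(e["hemorrhage"]), 1)     # one dark blob of half area
  expect_equal(unname(e["dark_fraction"] + e["bright_fraction"]), 1)
})

test_that("candidate size and volume track the generating plaque height", {
  heights <- seq(6, 17, by = 1)
  feats <- vapply(heights, function(hh) {
    out <- generatePhantom(phantomParams(plaque_height_px = hh), seed = 100 + hh)
    mo <- morphologyFeatures(out$image, maskMatrix(out$roi))
    mo[c("morph.size", "morph.volume")]
  }, numeric(2))
  expect_gt(cor(heights, feats[1, ], method = "spearman"), 0.9)
  expect_gt(cor(heights, feats[2, ], method = "spearman"), 0.9)
})

test_that("the morphology block has its 15 named entries", {
  out <- generatePhantom(phantomParams(plaque_height_px = 10), seed = 5)
  mo <- morphologyFeatures(out$image, maskMatrix(out$roi))
  expect_length(mo, 15)
  expect_true(all(is.finite(mo)))
  expect_identical(names(mo), carotexFeatureNames()[49:63])
})
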