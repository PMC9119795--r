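test_that("class distance matches hand-computed values", {
  # means 0 and 2, both sds exactly 1
  expect_equal(classDistanceScore(c(-1, 0, 1, 1, 2, 3),
                                  c(0, 0, 0, 1, 1, 1)), sqrt(2))
  expect_equal(classDistanceScore(c(5, 6, 7, 5, 6, 7),
                                  c(0, 0, 0, 1, 1, 1)), 0)
  expect_equal(classDistanceScore(c(0, 0, 1, 1, 2, 2, 3, 3),
                                  rep(0:1, each = 4)),
               2 / sqrt(2 / 3), tolerance = 1e-9)
  expect_error(classDistanceScore(c(1, 2, 3), c(0, 0, 1)), "at least 2")
})

test_that("mutual information is non-negative and consistent", {
  lab <- rep(0:1, each = 200)
  expect_equal(miRelevance(lab + 0, lab), 1, tolerance = 1e-9)  # H(label)
  noise <- withr::with_seed(1, rnorm(400))
  expect_lt(miRelevance(noise, lab), 0.05)
  for (seed in 2:4)
    expect_gte(miRelevance(withr::with_seed(seed, rnorm(400)), lab), 0)
})

test_that("population-covariance PCA has its spectral identities", {
  xy <- cbind(a = 1:10, b = 1:10)
  p <- pcaFit(xy)
  expect_equal(unname(abs(p$eigenvectors[, 1])), rep(1 / sqrt(2), 2),
               tolerance = 1e-9)
  expect_lt(p$eigenvalues[2], 1e-9)
  X <- withr::with_seed(5, matrix(rnorm(200), 20, 10))
  p2 <- pcaFit(X)
  C <- crossprod(scale(X, scale = FALSE)) / nrow(X)
  expect_equal(sum(p2$eigenvalues), sum(diag(C)), tolerance = 1e-9)
  # completeness: full reconstruction of the centred data
  expect_equal(p2$scores %*% t(p2$eigenvectors), scale(X, scale = FALSE),
               tolerance = 1e-9, ignore_attr = TRUE)
  # orthonormal loadings; cross-check the spectrum against prcomp
  expect_equal(crossprod(p2$eigenvectors), diag(10), tolerance = 1e-9)
  pr <- prcomp(X, center = TRUE, scale. = FALSE)
  expect_equal(p2$eigenvalues, pr$sdev^2 * (nrow(X) - 1) / nrow(X),
               tolerance = 1e-9)
})

test_that("selection returns exactly k names led by the best separator", {
  pt <- planted_table(40, 30, planted = 1:6, delta = 2, seed = 6)
  # plant one perfect separator
  pt$x[, "f07"] <- pt$y * 10
  rep22 <- selectFeatures(pt$x, pt$y, k = 22)
  expect_length(selectedFeatures(rep22), 22)
  expect_equal(selectedFeatures(rep22)[1], "f07")
  expect_error(selectFeatures(pt$x, pt$y, k = 31), "exceeds")
})

test_that("selection is invariant to column permutation", {
  pt <- planted_table(30, 12, planted = 1:3, delta = 1.5, seed = 7)
  perm <- withr::with_seed(8, sample(12))
  a <- selectedFeatures(selectFeatures(pt$x, pt$y, k = 5))
  b <- selectedFeatures(selectFeatures(pt$x[, perm], pt$y, k = 5))
  expect_identical(a, b)
})

test_that("duplicating a column never adds distinct originals", {
  pt <- planted_table(30, 10, planted = 1:4, delta = 1.5, seed = 9)
  base <- selectedFeatures(selectFeatures(pt$x, pt$y, k = 6))
  dup <- cbind(pt$x, f01dup = pt$x[, "f01"])
  with_dup <- selectedFeatures(selectFeatures(dup, pt$y, k = 6))
  originals <- unique(sub("dup$", "", with_dup))
  expect_lte(length(intersect(originals, colnames(pt$x))),
             length(intersect(base, colnames(pt$x))))
})

test_that("variance_keep = 0 recovers pure distance ranking", {
  pt <- planted_table(40, 15, planted = 1:5, delta = 1.5, seed = 10)
  rep0 <- selectFeatures(pt$x, pt$y, k = 5, variance_keep = 0)
  ds <- rep0@distance_scores
  expect_identical(selectedFeatures(rep0),
                   names(sort(-ds))[1:5])
})

test_that("MI screening drops label-independent features", {
  pt <- planted_table(60, 10, planted = 1:2, delta = 2.5, seed = 11)
  rep_mi <- selectFeatures(pt$x, pt$y, k = 4, mi_threshold = 0.01)
  expect_length(rep_mi@mi_scores, 10)
  expect_true(all(c("f01", "f02") %in% selectedFeatures(rep_mi)))
})

test_that("a planted discriminative subset is recovered with high recall", {
  planted <- c(3, 9, 17, 25, 33, 41, 49, 55, 60, 63)
  pt <- planted_table(60, 63, planted = planted, delta = 1.5, seed = 12)
  colnames(pt$x) <- carotexFeatureNames()
  rep22 <- selectFeatures(pt$x, pt$y, k = 22)
  recall <- mean(carotexFeatureNames()[planted] %in%
                   selectedFeatures(rep22))
  expect_gt(recall, 0.8)
})

test_that("selection reports serialize to JSON", {
  pt <- planted_table(20, 8, planted = 1:2, delta = 2, seed = 13)
  rep_ <- selectFeatures(pt$x, pt$y, k = 3)
  path <- withr::local_tempfile(fileext = ".json")
  writeSelectionJSON(rep_, path)
  back <- jsonlite::read_json(path)
  expect_identical(unlist(back$selected), selectedFeatures(rep_))
  expect_length(back$distance_scores, 8)
})
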