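test_that("GrayImage and ROIMask enforce their invariants", {
  expect_s4_class(grayImage(matrix(0, 8, 8)), "GrayImage")
  expect_error(grayImage(matrix(0, 4, 8)), "8 x 8")
  expect_error(grayImage(matrix(300, 8, 8)), "0, 255")
  expect_error(roiMask(matrix(FALSE, 8, 8)), "16 foreground")
  m <- matrix(FALSE, 8, 8); m[1:4, 1:4] <- TRUE
  expect_s4_class(roiMask(m), "ROIMask")
})

test_that("PNG write/read round-trip is lossless for 8-bit images", {
  px <- random_image(16, 24, seed = 1)
  path <- withr::local_tempfile(fileext = ".png")
  writeGrayImage(grayImage(px), path)
  back <- readGrayImage(path)
  expect_equal(pixelMatrix(back), px, tolerance = 0, ignore_attr = FALSE)
})

test_that("multi-channel input with equal channels reads as its gray values", {
  px <- random_image(12, 12, seed = 2)
  arr <- EBImage::Image(array(rep(t(px) / 255, 3), c(12, 12, 3)),
                        colormode = "Color")
  path <- withr::local_tempfile(fileext = ".png")
  EBImage::writeImage(arr, path)
  back <- readGrayImage(path)
  # luminance of an (r = g = b) pixel is that value
  expect_equal(pixelMatrix(back), px, tolerance = 1e-8)
})

test_that("16-bit TIFF input is rescaled so the maximum maps to 255", {
  m <- matrix(0, 8, 8); m[1, 1] <- 65535; m[8, 8] <- 32768
  path <- withr::local_tempfile(fileext = ".tif")
  EBImage::writeImage(EBImage::Image(t(m) / 65535), path,
                      bits.per.sample = 16L)
  back <- readGrayImage(path)
  expect_equal(max(pixelMatrix(back)), 255)
  expect_equal(pixelMatrix(back)[8, 8], 128)
})

test_that("z-score unit normalization matches its closed forms", {
  expect_equal(as.numeric(zscoreUnitNormalize(c(1, 2, 3))), c(0, 0.5, 1))
  expect_equal(as.numeric(zscoreUnitNormalize(c(7, 7, 7))), rep(0.5, 3))
  v <- withr::with_seed(3, rnorm(40))
  out <- as.numeric(zscoreUnitNormalize(v))
  expect_equal(min(out), 0)
  expect_equal(max(out), 1)
})

test_that("normalization is invariant under positive affine rescaling", {
  v <- withr::with_seed(4, runif(25, 10, 90))
  expect_equal(as.numeric(zscoreUnitNormalize(v)),
               as.numeric(zscoreUnitNormalize(3.7 * v - 12)),
               tolerance = 1e-10)
})

test_that("reference statistics apply a frozen normalization to new rows", {
  tr <- c(2, 4, 6, 8)
  st <- attr(zscoreUnitNormalize(tr), "stats")
  out <- as.numeric(zscoreUnitNormalize(c(2, 5, 8, 20), stats = st))
  expect_equal(out[1], 0)
  expect_equal(out[2], 0.5)
  expect_equal(out[4], 1)   # clipped to the training range
})

test_that("stratified split reproduces a 270/91 partition at N = 361", {
  feats <- matrix(withr::with_seed(5, rnorm(361 * 3)), 361,
                  dimnames = list(NULL, c("a", "b", "c")))
  labels <- rep(c(0L, 1L), c(202L, 159L))
  fs <- carotidFeatureSet(feats, labels)
  sp <- splitDataset(fs, 270 / 361, seed = 9)
  expect_length(trainIndex(sp), 270)
  expect_length(testIndex(sp), 91)
  # stratification: per-class proportions match the global fraction
  tr_lab <- imageLabels(sp)[trainIndex(sp)]
  expect_equal(sum(tr_lab == 0L), 151)
  expect_equal(sum(tr_lab == 1L), 119)
  # train and test partition the rows
  expect_length(intersect(trainIndex(sp), testIndex(sp)), 0)
  expect_setequal(c(trainIndex(sp), testIndex(sp)), seq_len(361))
})

test_that("splits are seed-deterministic and seed-sensitive", {
  feats <- matrix(withr::with_seed(6, rnorm(40)), 20,
                  dimnames = list(NULL, c("a", "b")))
  labels <- rep(0:1, each = 10)
  fs <- carotidFeatureSet(feats, labels)
  s1 <- trainIndex(splitDataset(fs, 0.5, seed = 1))
  s1b <- trainIndex(splitDataset(fs, 0.5, seed = 1))
  s2 <- trainIndex(splitDataset(fs, 0.5, seed = 2))
  expect_identical(s1, s1b)
  expect_false(identical(s1, s2))
  # tiny balanced case keeps one member of each class per side
  fs4 <- carotidFeatureSet(matrix(1:8, 4, dimnames = list(NULL, c("a", "b"))),
                           c(0, 0, 1, 1))
  sp4 <- splitDataset(fs4, 0.5, seed = 3)
  expect_equal(sort(imageLabels(sp4)[trainIndex(sp4)]), c(0L, 1L))
})

test_that("a class with fewer than 2 members cannot be split", {
  fs <- carotidFeatureSet(matrix(1:6, 3, dimnames = list(NULL, c("a", "b"))),
                          c(0, 0, 1))
  expect_error(splitDataset(fs, 0.5, seed = 1), "at least 2")
})

test_that("train-fitted normalization leaves no train/test leakage", {
  feats <- matrix(withr::with_seed(7, rnorm(60)), 30,
                  dimnames = list(NULL, c("glcm.a", "hist.gsm")))
  fs <- splitDataset(carotidFeatureSet(feats, rep(0:1, 15)), 0.5, seed = 1)
  nm <- normalizeFeatures(fs)
  v <- featureValues(nm)
  tr <- trainIndex(nm)
  # texture column: training rows span exactly [0, 1]
  expect_equal(range(v[tr, "glcm.a"]), c(0, 1))
  # histogram column passes through untouched
  expect_equal(unname(v[, "hist.gsm"]), unname(feats[, "hist.gsm"]))
  # test rows are clipped into [0, 1], not refitted
  expect_true(all(v[, "glcm.a"] >= 0 & v[, "glcm.a"] <= 1))
})

test_that("feature CSV round-trips the table, labels and split", {
  feats <- matrix(withr::with_seed(8, rnorm(24)), 12,
                  dimnames = list(NULL, c("f.a", "f.b")))
  fs <- splitDataset(carotidFeatureSet(feats, rep(0:1, 6)), 0.5, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  writeFeatureCSV(fs, path)
  back <- readFeatureCSV(path)
  expect_equal(featureValues(back), featureValues(fs), tolerance = 1e-12)
  expect_identical(imageLabels(back), imageLabels(fs))
  expect_identical(trainIndex(back), trainIndex(fs))
})
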