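test_that("Gaussian NB fits counting priors and class-conditional moments", {
  x <- cbind(f = c(0, 0.5, 1, 1.5, 10, 11))
  y <- c(0, 0, 0, 0, 1, 1)
  m <- nbFit(x, y)
  expect_equal(unname(m@priors), c(4 / 6, 2 / 6))
  expect_equal(unname(m@means[, 1]), c(mean(x[1:4, 1]), mean(x[5:6, 1])))
  # constant feature: variance floored, posterior finite
  xc <- cbind(a = c(1, 1, 1, 1), b = c(0, 1, 4, 5))
  mc <- nbFit(xc, c(0, 0, 1, 1))
  expect_equal(mc@variances[1, "a"], 1e-9)
  expect_true(all(is.finite(nbPosterior(mc, c(1, 2)))))
  expect_error(nbFit(cbind(f = 1:4), c(0, 0, 0, 0)), "both classes")
})

test_that("NB posteriors follow the Gaussian likelihood-ratio closed form", {
  # classes N(0,1) and N(2,1) from exact-moment samples
  m <- nbFit(cbind(f = c(0, -1, 1, 2, 1, 3)), c(0, 0, 0, 1, 1, 1))
  po <- nbPosterior(m, 0)
  expect_equal(unname(po[1, "0"]), exp(2) / (1 + exp(2)), tolerance = 1e-9)
  expect_equal(rowSums(nbPosterior(m, c(-3, 0, 1, 5))), rep(1, 4))
  # symmetric midpoint with equal priors
  expect_equal(unname(nbPosterior(m, 1)[1, ]), c(0.5, 0.5), tolerance = 1e-9)
})

test_that("NB posteriors agree with an independent reference fit", {
  d <- planted_table(40, 4, planted = 1:2, delta = 1.5, seed = 21)
  m <- nbFit(d$x, d$y)
  ref <- e1071::naiveBayes(d$x, factor(d$y))
  pref <- predict(ref, d$x, type = "raw")
  expect_equal(nbPosterior(m, d$x)[, "1"], unname(pref[, "1"]),
               tolerance = 1e-6)
})

test_that("kernel-density NB flattens to the priors and agrees on Gaussian data", {
  x <- cbind(f = c(0, -1, 1, 2, 1, 3)); y <- c(0, 0, 0, 1, 1, 1)
  mk <- nbKdeFit(x, y, bandwidth = 1e6)
  expect_equal(unname(nbPosterior(mk, 0.3)[1, ]), c(0.5, 0.5),
               tolerance = 1e-3)
  d <- planted_table(150, 2, planted = 1, delta = 2, seed = 22)
  pg <- nbPosterior(nbFit(d$x, d$y), d$x)[, "1"]
  pk <- nbPosterior(nbKdeFit(d$x, d$y), d$x)[, "1"]
  expect_lt(mean(abs(pg - pk)), 0.05)
})

test_that("attract updates contract and repel updates expand", {
  expect_equal(lvqUpdate(0, 1, 0.1, TRUE), 0.1)
  expect_equal(lvqUpdate(0, 1, 0.1, FALSE), -0.1)
  withr::with_seed(23, {
    for (i in 1:1000) {
      p <- rnorm(5); y <- rnorm(5); rho <- runif(1, 0.01, 0.99)
      d0 <- sqrt(sum((y - p)^2))
      expect_lt(sqrt(sum((y - lvqUpdate(p, y, rho, TRUE))^2)), d0)
      expect_gt(sqrt(sum((y - lvqUpdate(p, y, rho, FALSE))^2)), d0)
    }
  })
})

test_that("prototype initialization sits at class means and is reproducible", {
  d <- planted_table(20, 3, planted = 1, delta = 2, seed = 24)
  m <- dlvqInit(d$x, d$y)
  expect_equal(m@prototypes[1, ], colMeans(d$x[d$y == 0, ]))
  expect_equal(m@prototypes[2, ], colMeans(d$x[d$y == 1, ]))
  expect_setequal(unique(m@proto_labels), c(0L, 1L))
  m4a <- dlvqInit(d$x, d$y, per_class = 3, seed = 5)
  m4b <- dlvqInit(d$x, d$y, per_class = 3, seed = 5)
  expect_identical(m4a@prototypes, m4b@prototypes)
})

test_that("well-separated blobs train to zero error without growth", {
  d <- withr::with_seed(25, list(
    x = rbind(matrix(rnorm(100, 0, 0.3), 50), matrix(rnorm(100, 3, 0.3), 50)),
    y = rep(0:1, each = 50)))
  m <- dlvqTrain(d$x, d$y, epochs = 10, seed = 25)
  expect_equal(tail(m@trace$error, 1), 0)
  expect_equal(nrow(m@prototypes), 2)   # no growth triggered
  expect_equal(nrow(m@trace), 10)
})

test_that("dynamic growth adds prototypes for hard classes", {
  d <- correlated_classes(200, seed = 26)
  m <- dlvqTrain(d$x, d$y, epochs = 30, per_class = 2, seed = 26)
  expect_gt(nrow(m@prototypes), 4)
  expect_lte(sum(m@proto_labels == 0), 10)   # per-class budget respected
  off <- dlvqTrain(d$x, d$y, epochs = 5, grow = FALSE, seed = 26)
  expect_equal(nrow(off@prototypes), 2)
})

test_that("DLVQ prediction is nearest-prototype with a bounded score", {
  d <- planted_table(30, 2, planted = 1, delta = 3, seed = 27)
  m <- dlvqTrain(d$x, d$y, epochs = 5, seed = 27)
  # a query equal to a prototype takes that prototype's label
  for (k in seq_along(m@proto_labels)) {
    lab <- predictLabels(m, m@prototypes[k, ])
    expect_equal(as.integer(lab), m@proto_labels[k])
  }
  sc <- predictScores(m, d$x)
  expect_true(all(sc >= 0 & sc <= 1))
  # equidistant query scores 0.5
  mid <- (m@prototypes[m@proto_labels == 0, , drop = FALSE][1, ] +
            m@prototypes[m@proto_labels == 1, , drop = FALSE][1, ]) / 2
  m2 <- m
  expect_equal(unname(predictScores(
    new("DLVQModel", prototypes = m@prototypes[1:2, ],
        proto_labels = c(0L, 1L), win_counts = c(0, 0),
        features = m@features, config = list(), trace = data.frame()),
    mid)), 0.5, tolerance = 1e-9)
})

test_that("classifiers on correlated planted structure: DLVQ >= NB", {
  tr <- correlated_classes(200, seed = 28)
  te <- correlated_classes(200, seed = 29)
  acc_nb <- mean(as.integer(predictLabels(nbFit(tr$x, tr$y), te$x)) == te$y)
  dl <- dlvqTrain(tr$x, tr$y, epochs = 40, per_class = 4, seed = 28)
  acc_dl <- mean(as.integer(predictLabels(dl, te$x)) == te$y)
  expect_gte(acc_dl, acc_nb)
  expect_gt(acc_dl, 0.8)    # the prototype net actually solves it
})

test_that("model serialization writes the fitted parameters", {
  d <- planted_table(20, 3, planted = 1, delta = 2, seed = 30)
  nb <- nbFit(d$x, d$y)
  path <- withr::local_tempfile(fileext = ".json")
  writeModelJSON(nb, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$type, "gaussian_nb")
  expect_equal(unlist(back$priors), c("0" = 0.5, "1" = 0.5))
  dl <- dlvqTrain(d$x, d$y, epochs = 2, seed = 30)
  writeModelJSON(dl, path)
  back2 <- jsonlite::read_json(path)
  expect_equal(back2$type, "dlvq")
  expect_length(back2$labels, nrow(dl@prototypes))
})
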