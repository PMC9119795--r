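#' @include AllClasses.R AllGenerics.R core_io.R
NULL

.as_xy <- function(train, labels) {
  if (is(train, "CarotidFeatureSet")) {
    idx <- trainIndex(train)
    if (length(idx) == 0L) idx <- seq_len(ncol(train))
    list(x = featureValues(train)[idx, , drop = FALSE],
         y = imageLabels(train)[idx])
  } else {
    stopifnot(!is.null(labels), nrow(train) == length(labels))
    list(x = as.matrix(train), y = as.integer(labels))
  }
}

#' Fit a Gaussian Naive Bayes classifier
#'
#' Empirical class priors and per-class per-feature means and variances
#' (sample variance, floored at 1e-9 so constant features never divide by
#' zero).
#'
#' @param train a \linkS4class{CarotidFeatureSet} (training rows are used
#'   when a split is recorded) or a numeric N x F matrix.
#' @param labels binary labels when `train` is a matrix.
#' @return a \linkS4class{GaussianNBModel}
#' @export
nbFit <- function(train, labels = NULL) {
  d <- .as_xy(train, labels)
  if (length(unique(d$y)) < 2L) stop("both classes must be present")
  cls <- c(0L, 1L)
  priors <- setNames(vapply(cls, function(c) mean(d$y == c), numeric(1L)),
                     cls)
  mu <- do.call(rbind, lapply(cls, function(c)
    colMeans(d$x[d$y == c, , drop = FALSE])))
  va <- do.call(rbind, lapply(cls, function(c)
    apply(d$x[d$y == c, , drop = FALSE], 2L, var)))
  va[!is.finite(va) | va < .EPS] <- .EPS
  rownames(mu) <- rownames(va) <- cls
  new("GaussianNBModel", priors = priors, means = mu, variances = va,
      features = colnames(d$x) %||% character(0), kernel = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a bare vector is one observation when its length matches the feature
# count, otherwise a column of single-feature observations
.feature_rows <- function(y, n_features) {
  if (!is.null(dim(y))) {
    x <- as.matrix(y)
  } else if (n_features == 1L) {
    x <- matrix(y, ncol = 1L)
  } else if (length(y) == n_features) {
    x <- matrix(y, nrow = 1L)
  } else {
    stop("feature vector length does not match the model")
  }
  if (ncol(x) != n_features)
    stop("feature count does not match the model")
  x
}

#' Fit a kernel-density Naive Bayes classifier
#'
#' Replaces the per-feature Gaussian class-conditionals with Gaussian-kernel
#' density estimates of the training sample; otherwise identical posterior
#' arithmetic. The default bandwidth is Silverman's rule per class and
#' feature; a scalar `bandwidth` overrides it everywhere.
#'
#' @inheritParams nbFit
#' @param bandwidth positive scalar bandwidth, or NULL for Silverman.
#' @return a \linkS4class{GaussianNBModel} with `kernel = TRUE`.
#' @export
nbKdeFit <- function(train, labels = NULL, bandwidth = NULL) {
  if (!is.null(bandwidth)) stopifnot(bandwidth > 0)
  d <- .as_xy(train, labels)
  if (length(unique(d$y)) < 2L) stop("both classes must be present")
  m <- nbFit(d$x, d$y)
  bw <- lapply(c(0L, 1L), function(c) {
    xs <- d$x[d$y == c, , drop = FALSE]
    apply(xs, 2L, function(v) {
      if (!is.null(bandwidth)) return(bandwidth)
      s <- sd(v)
      max(.EPS, 0.9 * min(s, IQR(v) / 1.34, na.rm = TRUE) *
            length(v)^(-1 / 5), na.rm = TRUE)
    })
  })
  m@kernel <- TRUE
  m@training <- list(x0 = d$x[d$y == 0L, , drop = FALSE],
                     x1 = d$x[d$y == 1L, , drop = FALSE],
                     bw0 = bw[[1L]], bw1 = bw[[2L]])
  m
}

#' @importFrom stats IQR
NULL

# per-class log-likelihood of feature rows under the model
.nb_loglik <- function(model, x) {
  x <- as.matrix(x)
  if (!model@kernel) {
    ll <- vapply(1:2, function(ci) {
      mu <- model@means[ci, ]; va <- model@variances[ci, ]
      rowSums(sweep(-sweep(x, 2L, mu)^2, 2L, 2 * va, "/") -
                matrix(0.5 * log(2 * pi * va), nrow(x), ncol(x), byrow = TRUE))
    }, numeric(nrow(x)))
  } else {
    kde_ll <- function(xs, bw) {
      # log mean_k dnorm(y; xs[k], bw) per feature, summed over features
      vapply(seq_len(nrow(x)), function(i) {
        sum(vapply(seq_len(ncol(x)), function(j) {
          z <- dnorm(x[i, j], mean = xs[, j], sd = bw[j])
          log(max(mean(z), 1e-300))
        }, numeric(1L)))
      }, numeric(1L))
    }
    ll <- cbind(kde_ll(model@training$x0, model@training$bw0),
                kde_ll(model@training$x1, model@training$bw1))
  }
  if (is.null(dim(ll))) ll <- matrix(ll, nrow = 1L)
  ll
}

#' Posterior class probabilities under a Naive Bayes model
#'
#' Accumulates per-feature log-densities plus log priors and normalizes by
#' log-sum-exp; the two posteriors always sum to 1.
#'
#' @param model a \linkS4class{GaussianNBModel}.
#' @param y one feature vector, or an N x F matrix of rows.
#' @return N x 2 matrix of posteriors, columns `0` (normal) and `1`
#'   (plaque).
#' @export
nbPosterior <- function(model, y) {
  x <- .feature_rows(y, ncol(model@means))
  ll <- .nb_loglik(model, x) +
    matrix(log(model@priors), nrow(x), 2L, byrow = TRUE)
  mx <- apply(ll, 1L, max)
  p <- exp(ll - mx)
  p <- p / rowSums(p)
  colnames(p) <- c("0", "1")
  p
}

#' @describeIn predictLabels Naive Bayes: argmax posterior
#' @export
setMethod("predictLabels", "GaussianNBModel", function(object, newdata, ...) {
  p <- nbPosterior(object, newdata)
  lab <- as.integer(p[, "1"] > p[, "0"])
  attr(lab, "scores") <- p[, "1"]
  lab
})

#' @describeIn predictScores Naive Bayes: posterior probability of plaque
#' @export
setMethod("predictScores", "GaussianNBModel", function(object, newdata, ...) {
  nbPosterior(object, newdata)[, "1"]
})

setMethod("show", "GaussianNBModel", function(object) {
  cat(sprintf("%s Naive Bayes: %d features, priors (%.3f, %.3f)\n",
              if (object@kernel) "Kernel-density" else "Gaussian",
              ncol(object@means), object@priors[1L], object@priors[2L]))
})

# ---- DLVQ -----------------------------------------------------------------

#' Initialize a DLVQ prototype set
#'
#' One prototype per class at the class-conditional mean when
#' `per_class = 1`; for more, the class mean plus seeded within-class
#' samples.
#'
#' @inheritParams nbFit
#' @param per_class initial prototypes per class (default 1).
#' @param seed integer seed (used when `per_class > 1`).
#' @return a \linkS4class{DLVQModel} (untrained).
#' @export
dlvqInit <- function(train, labels = NULL, per_class = 1L, seed = 1L) {
  stopifnot(per_class >= 1L)
  d <- .as_xy(train, labels)
  if (length(unique(d$y)) < 2L) stop("both classes must be present")
  protos <- NULL; plab <- integer(0)
  for (c in c(0L, 1L)) {
    xc <- d$x[d$y == c, , drop = FALSE]
    pc <- colMeans(xc)
    protos <- rbind(protos, pc)
    plab <- c(plab, c)
    if (per_class > 1L) {
      extra <- withr::with_seed(as.integer(seed) + c,
                                sample(nrow(xc), min(per_class - 1L, nrow(xc))))
      protos <- rbind(protos, xc[extra, , drop = FALSE])
      plab <- c(plab, rep(c, length(extra)))
    }
  }
  rownames(protos) <- NULL
  new("DLVQModel", prototypes = protos, proto_labels = plab,
      win_counts = rep(0, nrow(protos)),
      features = colnames(d$x) %||% character(0),
      config = list(), trace = data.frame())
}

# squared Euclidean distances from rows of x to rows of protos
.proto_dist2 <- function(x, protos) {
  outer(rowSums(x^2), rep(1, nrow(protos))) +
    outer(rep(1, nrow(x)), rowSums(protos^2)) - 2 * x %*% t(protos)
}

#' Train a DLVQ model
#'
#' Per sample, the winner is the prototype minimizing the win-count-scaled
#' distance `||y - n|| * (1 + count / sum(counts))` (frequency-sensitive
#' competitive learning; disable with `frequency_sensitive = FALSE` for
#' plain LVQ1). The winner moves toward a same-class sample and away from a
#' different-class sample by step `rho_t = rho0 * (1 - t/T)` (T = epochs x
#' N update steps). After each epoch, a class whose training error exceeds
#' `tau` and whose prototype count is below `max_per_class` receives one new
#' prototype at the centroid of its misclassified samples. The per-epoch
#' error and prototype count are recorded in the training trace.
#'
#' @inheritParams nbFit
#' @param epochs training epochs (default 50).
#' @param rho0 initial step size in (0, 1) (default 0.3).
#' @param tau per-class error threshold triggering growth (default 0.1).
#' @param max_per_class prototype budget per class (default 10).
#' @param per_class initial prototypes per class.
#' @param frequency_sensitive scale winner distances by win counts.
#' @param grow allow dynamic prototype growth.
#' @param seed integer seed controlling sample order shuffling.
#' @return a trained \linkS4class{DLVQModel}; slot `trace` holds the
#'   per-epoch record.
#' @export
dlvqTrain <- function(train, labels = NULL, epochs = 50L, rho0 = 0.3,
                      tau = 0.1, max_per_class = 10L, per_class = 1L,
                      frequency_sensitive = TRUE, grow = TRUE, seed = 1L) {
  stopifnot(rho0 > 0, rho0 < 1, epochs >= 1L)
  d <- .as_xy(train, labels)
  model <- dlvqInit(d$x, d$y, per_class = per_class, seed = seed)
  protos <- model@prototypes
  plab <- model@proto_labels
  wins <- model@win_counts
  n <- nrow(d$x)
  Tsteps <- epochs * n
  t <- 0L
  orders <- withr::with_seed(as.integer(seed),
    replicate(epochs, sample.int(n), simplify = FALSE))
  trace <- data.frame(epoch = integer(0), error = numeric(0),
                      prototypes = integer(0))
  for (ep in seq_len(epochs)) {
    for (i in orders[[ep]]) {
      y <- d$x[i, ]
      dst <- sqrt(pmax(.proto_dist2(matrix(y, 1L), protos)[1L, ], 0))
      if (frequency_sensitive) {
        tot <- sum(wins)
        if (tot > 0) dst <- dst * (1 + wins / tot)
      }
      w <- which.min(dst)
      rho <- rho0 * (1 - t / Tsteps)
      if (plab[w] == d$y[i]) {
        protos[w, ] <- protos[w, ] + rho * (y - protos[w, ])
      } else {
        protos[w, ] <- protos[w, ] - rho * (y - protos[w, ])
      }
      if (any(!is.finite(protos[w, ])))
        stop("DLVQ diverged: non-finite prototype at step ", t)
      wins[w] <- wins[w] + 1
      t <- t + 1L
    }
    # epoch-end evaluation and growth
    pred <- plab[apply(.proto_dist2(d$x, protos), 1L, which.min)]
    err <- mean(pred != d$y)
    for (c in c(0L, 1L)) {
      in_c <- d$y == c
      err_c <- mean(pred[in_c] != c)
      if (grow && err_c > tau && sum(plab == c) < max_per_class) {
        mis <- d$x[in_c & pred != d$y, , drop = FALSE]
        if (nrow(mis) > 0L) {
          protos <- rbind(protos, colMeans(mis))
          plab <- c(plab, c)
          wins <- c(wins, 0)
        }
      }
    }
    trace <- rbind(trace, data.frame(epoch = ep, error = err,
                                     prototypes = nrow(protos)))
  }
  new("DLVQModel", prototypes = protos, proto_labels = plab,
      win_counts = wins, features = model@features,
      config = list(epochs = epochs, rho0 = rho0, tau = tau,
                    max_per_class = max_per_class,
                    frequency_sensitive = frequency_sensitive,
                    grow = grow, seed = seed),
      trace = trace)
}

#' One LVQ attract/repel update
#'
#' Moves prototype `n` toward sample `y` by `rho * (y - n)` when the labels
#' match, away otherwise. Exposed for inspection and property testing: for
#' `rho` in (0, 1) an attract update strictly reduces `||y - n||` and a
#' repel update strictly increases it.
#'
#' @param proto numeric prototype vector.
#' @param y numeric sample vector.
#' @param rho step size in (0, 1).
#' @param attract TRUE when the prototype label matches the sample label.
#' @return updated prototype vector.
#' @export
lvqUpdate <- function(proto, y, rho, attract = TRUE) {
  stopifnot(rho > 0, rho < 1)
  if (attract) proto + rho * (y - proto) else proto - rho * (y - proto)
}

#' @describeIn predictLabels DLVQ: label of the nearest prototype (unscaled
#'   Euclidean distance; ties break toward the lower prototype index)
#' @export
setMethod("predictLabels", "DLVQModel", function(object, newdata, ...) {
  x <- .feature_rows(newdata, ncol(object@prototypes))
  d2 <- .proto_dist2(x, object@prototypes)
  lab <- object@proto_labels[apply(d2, 1L, which.min)]
  attr(lab, "scores") <- predictScores(object, x)
  lab
})

#' @describeIn predictScores DLVQ: `d- / (d+ + d-)` where d+ and d- are the
#'   distances to the nearest plaque and normal prototypes (0.5 when
#'   equidistant, saturating toward 1 near a plaque prototype)
#' @export
setMethod("predictScores", "DLVQModel", function(object, newdata, ...) {
  x <- .feature_rows(newdata, ncol(object@prototypes))
  d2 <- .proto_dist2(x, object@prototypes)
  dpos <- sqrt(pmax(0, apply(d2[, object@proto_labels == 1L, drop = FALSE],
                             1L, min)))
  dneg <- sqrt(pmax(0, apply(d2[, object@proto_labels == 0L, drop = FALSE],
                             1L, min)))
  ifelse(dpos + dneg < .EPS, 0.5, dneg / (dpos + dneg))
})

setMethod("show", "DLVQModel", function(object) {
  cat(sprintf("DLVQModel: %d prototypes (%d normal, %d plaque), %d features\n",
              nrow(object@prototypes), sum(object@proto_labels == 0L),
              sum(object@proto_labels == 1L), ncol(object@prototypes)))
  if (nrow(object@trace))
    cat(sprintf("  final training error %.3f after %d epochs\n",
                tail(object@trace$error, 1L), nrow(object@trace)))
})

#' Serialize a fitted classifier to JSON
#'
#' @param model a \linkS4class{GaussianNBModel} or \linkS4class{DLVQModel}.
#' @param path output path.
#' @return `path`, invisibly
#' @export
writeModelJSON <- function(model, path) {
  obj <- if (is(model, "GaussianNBModel")) {
    list(type = if (model@kernel) "kernel_nb" else "gaussian_nb",
         priors = as.list(model@priors),
         means = model@means, variances = model@variances,
         features = model@features)
  } else {
    list(type = "dlvq", prototypes = model@prototypes,
         labels = model@proto_labels, win_counts = model@win_counts,
         features = model@features, config = model@config)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", null = "null")
  invisible(path)
}
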