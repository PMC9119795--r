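#' @include features.R selection.R classifiers.R evaluation.R phantom.R
NULL

#' Default pipeline configuration
#'
#' All stage parameters with their defaults: phantom class sizes 202 normal
#' / 159 plaque, 32 quantization levels, multilevel thresholds 1/3 and 2/3,
#' a 270/361 training fraction, k = 22 selected features gated by 95% PCA
#' variance, and the classifier hyper-parameters.
#'
#' @param ... overrides for any listed element.
#' @return a validated named list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    n_normal = 202L, n_plaque = 159L,
    height = 64L, width = 64L,
    ranges = phantomRanges(),
    levels = 32L, t1 = 1 / 3, t2 = 2 / 3,
    train_fraction = 270 / 361,
    k = 22L, variance_keep = 0.95, mi_threshold = NULL,
    nb_kernel = FALSE,
    dlvq = list(epochs = 50L, rho0 = 0.3, tau = 0.1, max_per_class = 10L,
                per_class = 1L, frequency_sensitive = TRUE, grow = TRUE),
    seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config entries: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$k >= 1L, cfg$train_fraction > 0, cfg$train_fraction < 1,
            cfg$t1 < cfg$t2, cfg$levels >= 2L)
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Run the full phantom-to-metrics pipeline
#'
#' Simulate (or accept) images -> extract the 63 features -> split 75/25
#' stratified -> fit normalization on the training rows -> select k
#' features on the training rows -> train Gaussian Naive Bayes and DLVQ ->
#' evaluate both on the held-out test rows.
#'
#' @param config a [pipelineConfig()].
#' @param images,rois,labels optional pre-supplied data; when omitted a
#'   phantom dataset is generated from the config.
#' @param out_dir optional directory for the feature CSV, selection JSON,
#'   model JSONs and a metrics JSON.
#' @param verbose message stage progress.
#' @return list with `dataset` (a \linkS4class{CarotidFeatureSet}),
#'   `selection`, `models` (nb, dlvq), `evaluation` (per classifier:
#'   confusion, metrics, roc, gain) and `timings` (seconds per stage).
#' @export
runPipeline <- function(config = pipelineConfig(), images = NULL,
                        rois = NULL, labels = NULL, out_dir = NULL,
                        verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()
  if (is.null(images)) {
    say("simulating %d + %d phantoms", config$n_normal, config$n_plaque)
    sim <- generateDataset(config$n_normal, config$n_plaque,
                           ranges = config$ranges, seed = config$seed,
                           height = config$height, width = config$width)
    images <- sim$images; rois <- sim$rois; labels <- sim$labels
  }
  timings["simulate"] <- tic() - t0; t0 <- tic()
  say("extracting 63 features from %d images", length(images))
  fs <- extractFeatureTable(images, rois, labels, verbose = verbose)
  timings["extract"] <- tic() - t0; t0 <- tic()
  fs <- splitDataset(fs, config$train_fraction, seed = config$seed)
  fs <- normalizeFeatures(fs)
  timings["normalize_split"] <- tic() - t0; t0 <- tic()
  tr <- trainIndex(fs); te <- testIndex(fs)
  vals <- featureValues(fs); labs <- imageLabels(fs)
  if (config$k >= ncol(vals)) {
    say("k >= F: selection disabled, using all features")
    sel <- NULL
    keep <- colnames(vals)
  } else {
    sel <- selectFeatures(vals[tr, , drop = FALSE], labs[tr], k = config$k,
                          variance_keep = config$variance_keep,
                          mi_threshold = config$mi_threshold)
    keep <- selectedFeatures(sel)
  }
  timings["select"] <- tic() - t0; t0 <- tic()
  xtr <- vals[tr, keep, drop = FALSE]; ytr <- labs[tr]
  xte <- vals[te, keep, drop = FALSE]; yte <- labs[te]
  nb <- if (config$nb_kernel) nbKdeFit(xtr, ytr) else nbFit(xtr, ytr)
  dl <- do.call(dlvqTrain, c(list(train = xtr, labels = ytr,
                                  seed = config$seed), config$dlvq))
  timings["train"] <- tic() - t0; t0 <- tic()
  ev <- list(nb = evaluateClassifier(nb, xte, yte),
             dlvq = evaluateClassifier(dl, xte, yte))
  timings["evaluate"] <- tic() - t0
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    writeFeatureCSV(fs, file.path(out_dir, "features.csv"))
    if (!is.null(sel)) writeSelectionJSON(sel, file.path(out_dir, "selection.json"))
    writeModelJSON(nb, file.path(out_dir, "model_nb.json"))
    writeModelJSON(dl, file.path(out_dir, "model_dlvq.json"))
    jsonlite::write_json(
      list(nb = as.list(ev$nb$metrics), dlvq = as.list(ev$dlvq$metrics),
           nb_confusion = as.list(unclass(ev$nb$confusion)),
           dlvq_confusion = as.list(unclass(ev$dlvq$confusion)),
           selected = keep, timings = as.list(timings)),
      file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA,
      null = "null")
  }
  list(dataset = fs, selection = sel, models = list(nb = nb, dlvq = dl),
       evaluation = ev, selected = keep, timings = timings)
}
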