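## End-to-end orchestration: synthesize (or load) waveforms, optionally
## select the mode count, encode to images, split, train, evaluate; plus
## the confusion-matrix metrics and the color-count sweep.

#' Confusion-matrix metrics
#'
#' precision = tp/(tp+fp), recall = tp/(tp+fn),
#' f1 = 2 pr / (p + r), accuracy = (tp+tn)/total. Ratios with a zero
#' denominator are reported as NA with a warning, never as 0.
#'
#' @param tp,fp,fn,tn non-negative confusion counts (total > 0).
#' @return A [Metrics-class].
#' @examples
#' metricsTable(computeMetrics(3, 1, 2, 4))
#' @export
computeMetrics <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0)) stop("confusion counts must be non-negative")
  total <- sum(counts)
  if (total == 0) stop("confusion counts sum to zero")
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator); reported as NA")
      return(NA_real_)
    }
    num / den
  }
  precision <- ratio(tp, tp + fp, "precision")
  recall <- ratio(tp, tp + fn, "recall")
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall)
  else {
    warning("f1 undefined; reported as NA")
    NA_real_
  }
  new("Metrics", tp = as.integer(tp), fp = as.integer(fp),
      fn = as.integer(fn), tn = as.integer(tn), precision = precision,
      recall = recall, f1 = f1, accuracy = (tp + tn) / total)
}

#' Stratified train/test split
#'
#' Shuffles each class with a seeded RNG and assigns the first
#' \code{round(ratio * classSize)} (nearest integer, ties upward) to the
#' training set. Train and test are disjoint and exhaustive. At the study
#' scale (266 + 274 images, ratio 0.8) this gives 213 + 219 training and
#' 53 + 55 test images.
#'
#' @param images list of labeled images (or any objects; labels may be
#'   supplied separately).
#' @param ratio train fraction, strictly between 0 and 1.
#' @param seed shuffle seed.
#' @param labels optional label override.
#' @return List with \code{train}, \code{test} (sub-lists) and
#'   \code{trainIndex}, \code{testIndex} (indices into \code{images}).
#' @export
splitDataset <- function(images, ratio = 0.8, seed = 1, labels = NULL) {
  if (ratio <= 0 || ratio >= 1) stop("ratio must lie in (0, 1)")
  labs <- imageLabels(images, labels)
  if (anyNA(labs)) stop("all images must be labeled")
  classes <- sort(unique(labs))
  if (length(classes) < 2L) stop("both classes must be present")
  trainIdx <- integer(0)
  withSeed(deriveSeed(seed, 7), {
    for (cl in classes) {
      idx <- which(labs == cl)
      if (length(idx) < 2L)
        stop("class ", cl, " has fewer than 2 members")
      nTrain <- floor(ratio * length(idx) + 0.5)   # nearest, ties up
      idx <- idx[sample.int(length(idx))]
      trainIdx <- c(trainIdx, idx[seq_len(nTrain)])
    }
  })
  trainIdx <- sort(trainIdx)
  testIdx <- setdiff(seq_along(images), trainIdx)
  list(train = images[trainIdx], test = images[testIdx],
       trainIndex = trainIdx, testIndex = testIdx)
}

#' Run the full detection pipeline
#'
#' Synthesize the labeled dataset (or use \code{records}), optionally
#' select the mode count by minimum mean sample entropy, encode every
#' record into a color-cycled polyline image over the shared background,
#' split 80/20 stratified, train the MobileViT classifier, and evaluate on
#' the held-out images. All stage seeds derive from
#' \code{config@masterSeed}, making the run reproducible end to end.
#'
#' @param config a [RunConfig-class].
#' @param records optional list of labeled [UltrasoundRecord-class]
#'   objects to use instead of synthesizing.
#' @return List with \code{metrics} ([Metrics-class]), \code{history},
#'   \code{model}, \code{selectedM}, \code{nTrain}, \code{nTest}, and
#'   \code{seeds}. When \code{config@outputDir} is set, also writes
#'   \code{metrics.json}, \code{history.csv}, \code{background.png} and a
#'   resolved-config \code{run.json} there.
#' @export
runPipeline <- function(config = runConfig(), records = NULL) {
  validObject(config)
  seeds <- list(data = deriveSeed(config@masterSeed, 11),
                background = deriveSeed(config@masterSeed, 12),
                train = deriveSeed(config@masterSeed, 13))
  if (is.null(records))
    records <- generateDataset(config@nIntact, config@nCrack,
                               config@echoParams, seed = seeds$data)
  vmdCfg <- config@vmd
  selectedM <- vmdCfg@nModes
  if (config@autoSelectM) {
    selectedM <- selectM(records[[1]]@amplitudes, vmdCfg, config@sampEn)
    vmdCfg@nModes <- as.integer(selectedM)
  }
  enc <- encodeDataset(records, vmdCfg, config@encoder,
                       nBackgroundPerClass = config@nBackgroundPerClass,
                       seed = seeds$background,
                       outputSize = config@vit@inputSize)
  sp <- splitDataset(enc$images, config@splitRatio, config@splitSeed)
  vitCfg <- config@vit
  vitCfg@seed <- seeds$train
  model <- trainClassifier(sp$train, vitCfg)
  metrics <- evaluateClassifier(model, sp$test)
  report <- list(metrics = metrics, history = model@history, model = model,
                 selectedM = as.integer(selectedM),
                 nTrain = length(sp$train), nTest = length(sp$test),
                 seeds = seeds)
  if (length(config@outputDir)) {
    dir.create(config@outputDir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(c(as.list(metricsTable(metrics)),
                           list(n_train = report$nTrain,
                                n_test = report$nTest,
                                selected_M = report$selectedM)),
                         file.path(config@outputDir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(model@history,
                     file.path(config@outputDir, "history.csv"),
                     row.names = FALSE)
    if (!is.null(enc$background))
      writeImagePng(enc$background,
                    file.path(config@outputDir, "background.png"))
    jsonlite::write_json(list(master_seed = config@masterSeed,
                              seeds = seeds,
                              split_seed = config@splitSeed,
                              n_intact = config@nIntact,
                              n_crack = config@nCrack,
                              n_background_per_class =
                                config@nBackgroundPerClass,
                              split_ratio = config@splitRatio,
                              n_modes = vmdCfg@nModes,
                              n_colors = config@encoder@nColors,
                              input_size = config@vit@inputSize,
                              epochs = config@vit@epochs),
                         file.path(config@outputDir, "run.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

#' Sweep the number of encoding colors
#'
#' Re-encodes the same underlying signals with color cycles of each
#' requested length B (palettes are nested truncations of the 12-color
#' master set), retrains with the same split seed, and reports held-out
#' accuracy per B. Different B change only polyline colors, never
#' geometry.
#'
#' @param bValues integer vector of color counts (each <= 12).
#' @param config a [RunConfig-class].
#' @return data.frame with columns \code{B} and \code{accuracy}.
#' @export
sweepColors <- function(bValues, config = runConfig()) {
  if (max(bValues) > length(masterPalette(12)))
    stop("B exceeds the master palette size")
  seeds <- list(data = deriveSeed(config@masterSeed, 11))
  records <- generateDataset(config@nIntact, config@nCrack,
                             config@echoParams, seed = seeds$data)
  acc <- vapply(bValues, function(B) {
    cfg <- config
    cfg@encoder@nColors <- as.integer(B)
    cfg@encoder@palette <- masterPalette(B)
    rep <- runPipeline(cfg, records = records)
    rep$metrics@accuracy
  }, numeric(1))
  data.frame(B = as.integer(bValues), accuracy = acc)
}
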