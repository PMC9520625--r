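#' @import methods
NULL

## ---------------------------------------------------------------------------
## Core S4 containers. One seed's A-scan, the VMD result, the stacked mode
## matrix, the rendered raster, the classifier, and the evaluation metrics.
## ---------------------------------------------------------------------------

#' UltrasoundRecord: one seed's A-scan trace
#'
#' Holds a single air-coupled ultrasonic amplitude-versus-time trace (A-scan,
#' digitized voltage in arbitrary units) together with an optional binary
#' class label: 1 = intact kernel, 0 = kernel with a slight testa crack.
#'
#' @slot sampleId character scalar, typically the source file stem.
#' @slot amplitudes numeric vector of finite sample values (length L).
#' @slot label integer; \code{1L}, \code{0L}, or \code{NA_integer_} when no
#'   label is attached.
#'
#' @seealso [ultrasoundRecord()], [readSignalCsv()], [generateSignal()]
#' @exportClass UltrasoundRecord
setClass("UltrasoundRecord",
  representation(sampleId = "character", amplitudes = "numeric",
                 label = "integer"))

setValidity("UltrasoundRecord", function(object) {
  msg <- character(0)
  if (length(object@amplitudes) == 0L)
    msg <- c(msg, "amplitudes must have length > 0")
  if (anyNA(object@amplitudes) || any(!is.finite(object@amplitudes)))
    msg <- c(msg, "amplitudes must be finite")
  if (length(object@label) != 1L)
    msg <- c(msg, "label must be a single integer (NA for unlabeled)")
  else if (!is.na(object@label) && !object@label %in% c(0L, 1L))
    msg <- c(msg, "label must be 0, 1 or NA")
  if (length(object@sampleId) != 1L)
    msg <- c(msg, "sampleId must be a single string")
  if (length(msg)) msg else TRUE
})

#' Construct an UltrasoundRecord
#'
#' @param amplitudes numeric vector of finite sample values.
#' @param label 0, 1 or NA (default): 1 = intact, 0 = slight crack.
#' @param sampleId identifier string.
#' @return An [UltrasoundRecord-class] object.
#' @examples
#' rec <- ultrasoundRecord(sin(seq_len(100) / 5), label = 1)
#' rec
#' @export
ultrasoundRecord <- function(amplitudes, label = NA, sampleId = "record") {
  new("UltrasoundRecord", sampleId = as.character(sampleId),
      amplitudes = as.numeric(amplitudes), label = as.integer(label))
}

setMethod("show", "UltrasoundRecord", function(object) {
  lab <- if (is.na(object@label)) "unlabeled"
         else if (object@label == 1L) "1 (intact)" else "0 (slight crack)"
  cat("UltrasoundRecord '", object@sampleId, "': L = ",
      length(object@amplitudes), ", label ", lab, "\n", sep = "")
})

#' EchoModelParams: synthetic tone-burst echo model
#'
#' Parameters of the synthetic A-scan generator that stands in for the
#' instrument recordings. The model is a sum of Gaussian-windowed,
#' exponentially damped tone bursts (a direct through-transmission pulse
#' plus trailing multipath echoes) with additive Gaussian noise. A slight
#' crack lowers the carrier frequency, strengthens damping, and reduces
#' intensity; \code{separation} scales all three class deltas jointly and
#' \code{separation = 0} makes the two classes identically distributed.
#'
#' @slot sampleRate digitizer rate, Hz.
#' @slot nSamples record length L.
#' @slot carrierFreq transducer center frequency, Hz.
#' @slot burstCenters sample indices of the burst onsets.
#' @slot burstGains relative amplitude of each burst.
#' @slot burstWidth Gaussian envelope SD, samples.
#' @slot dampingRate per-sample exponential decay within each burst.
#' @slot crackFreqShift carrier downshift for the crack class, Hz.
#' @slot crackDampingMultiplier damping multiplier for the crack class.
#' @slot crackGainMultiplier gain multiplier for the crack class.
#' @slot separation scale in [0, 1] applied to the three crack deltas.
#' @slot noiseSd noise SD as a fraction of the noiseless peak amplitude.
#' @seealso [echoModelParams()], [generateSignal()]
#' @exportClass EchoModelParams
setClass("EchoModelParams",
  representation(sampleRate = "numeric", nSamples = "integer",
                 carrierFreq = "numeric", burstCenters = "numeric",
                 burstGains = "numeric", burstWidth = "numeric",
                 dampingRate = "numeric", crackFreqShift = "numeric",
                 crackDampingMultiplier = "numeric",
                 crackGainMultiplier = "numeric", separation = "numeric",
                 noiseSd = "numeric"))

setValidity("EchoModelParams", function(object) {
  msg <- character(0)
  if (object@carrierFreq >= object@sampleRate / 2)
    msg <- c(msg, "carrierFreq must be below the Nyquist frequency")
  if (object@nSamples < 2L) msg <- c(msg, "nSamples must be >= 2")
  if (length(object@burstGains) != length(object@burstCenters))
    msg <- c(msg, "burstGains and burstCenters must have equal length")
  if (any(object@burstGains <= 0) || object@burstWidth <= 0 ||
      object@dampingRate <= 0)
    msg <- c(msg, "gains, widths and rates must be strictly positive")
  if (object@separation < 0 || object@separation > 1)
    msg <- c(msg, "separation must lie in [0, 1]")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct echo model parameters
#'
#' Defaults describe a 400 kHz through-transmission geometry sampled at
#' 4 MHz over 450 samples (112.5 us): a direct pulse and two trailing
#' echoes. At 4 MHz the carrier completes exactly one cycle every 10
#' samples, matching the default 10-color encoding cycle, so intact
#' records draw phase-locked per-color polylines while the crack class's
#' downshifted carrier drifts through the color cycle (see the methods
#' vignette).
#'
#' @param sampleRate,nSamples,carrierFreq,burstCenters,burstGains,burstWidth
#'   see [EchoModelParams-class].
#' @param dampingRate,crackFreqShift,crackDampingMultiplier,crackGainMultiplier
#'   see [EchoModelParams-class].
#' @param separation,noiseSd see [EchoModelParams-class].
#' @return An [EchoModelParams-class] object.
#' @export
echoModelParams <- function(sampleRate = 4.0e6, nSamples = 450,
                            carrierFreq = 4.0e5,
                            burstCenters = c(80, 200, 320),
                            burstGains = c(1.0, 0.45, 0.2),
                            burstWidth = 18, dampingRate = 0.015,
                            crackFreqShift = 6.0e4,
                            crackDampingMultiplier = 1.6,
                            crackGainMultiplier = 0.7,
                            separation = 1.0, noiseSd = 0.05) {
  new("EchoModelParams", sampleRate = sampleRate,
      nSamples = as.integer(nSamples), carrierFreq = carrierFreq,
      burstCenters = burstCenters, burstGains = burstGains,
      burstWidth = burstWidth, dampingRate = dampingRate,
      crackFreqShift = crackFreqShift,
      crackDampingMultiplier = crackDampingMultiplier,
      crackGainMultiplier = crackGainMultiplier,
      separation = separation, noiseSd = noiseSd)
}

#' VMDConfig: variational mode decomposition settings
#'
#' @slot nModes number of intrinsic mode functions M.
#' @slot alpha bandwidth penalty (quadratic penalty factor).
#' @slot tau dual-ascent step; 0 disables the Lagrangian update (robust to
#'   noise).
#' @slot eps convergence tolerance on the summed relative squared spectral
#'   change between iterations.
#' @slot maxIter iteration cap.
#' @slot initOmega center-frequency initialization, "uniform" or "zero".
#' @seealso [vmdConfig()], [vmdDecompose()]
#' @exportClass VMDConfig
setClass("VMDConfig",
  representation(nModes = "integer", alpha = "numeric", tau = "numeric",
                 eps = "numeric", maxIter = "integer", initOmega = "character"))

setValidity("VMDConfig", function(object) {
  msg <- character(0)
  if (object@nModes < 1L) msg <- c(msg, "nModes must be >= 1")
  if (object@alpha <= 0) msg <- c(msg, "alpha must be > 0")
  if (object@tau < 0) msg <- c(msg, "tau must be >= 0")
  if (object@eps <= 0) msg <- c(msg, "eps must be > 0")
  if (object@maxIter < 1L) msg <- c(msg, "maxIter must be >= 1")
  if (!object@initOmega %in% c("uniform", "zero"))
    msg <- c(msg, "initOmega must be 'uniform' or 'zero'")
  if (length(msg)) msg else TRUE
})

#' Construct a VMD configuration
#'
#' @param nModes number of modes M (default 3).
#' @param alpha bandwidth penalty (default 2000).
#' @param tau dual ascent step (default 0).
#' @param eps convergence tolerance (default 1e-7).
#' @param maxIter iteration cap (default 500).
#' @param initOmega "uniform" (default) or "zero".
#' @return A [VMDConfig-class] object.
#' @export
vmdConfig <- function(nModes = 3, alpha = 2000, tau = 0, eps = 1e-7,
                      maxIter = 500, initOmega = "uniform") {
  new("VMDConfig", nModes = as.integer(nModes), alpha = alpha, tau = tau,
      eps = eps, maxIter = as.integer(maxIter), initOmega = initOmega)
}

#' VMDResult: band-limited intrinsic mode functions
#'
#' @slot modes M x L numeric matrix; row m is mode u_m, rows sorted by
#'   ascending center frequency.
#' @slot omegas normalized center frequencies, cycles/sample in [0, 0.5],
#'   ascending.
#' @slot iterations ADMM iterations actually run.
#' @slot converged TRUE if the relative-change criterion fell below eps.
#' @seealso [vmdDecompose()]
#' @exportClass VMDResult
setClass("VMDResult",
  representation(modes = "matrix", omegas = "numeric",
                 iterations = "integer", converged = "logical"))

setValidity("VMDResult", function(object) {
  msg <- character(0)
  if (nrow(object@modes) != length(object@omegas))
    msg <- c(msg, "one omega per mode required")
  if (any(object@omegas < 0 | object@omegas > 0.5))
    msg <- c(msg, "omegas must lie in [0, 0.5]")
  if (is.unsorted(object@omegas))
    msg <- c(msg, "omegas must be ascending")
  if (length(msg)) msg else TRUE
})

setMethod("show", "VMDResult", function(object) {
  cat("VMDResult: M =", nrow(object@modes), "modes, L =",
      ncol(object@modes), "\n  omegas:",
      paste(signif(object@omegas, 4), collapse = ", "),
      "\n  iterations:", object@iterations,
      if (object@converged) "(converged)" else "(max iterations)", "\n")
})

#' SampEnConfig: sample-entropy settings
#'
#' @slot embedDim template (embedding) dimension z.
#' @slot rMode "relative_sd" (tolerance = rValue * SD of the series) or
#'   "absolute".
#' @slot rValue tolerance factor or absolute tolerance.
#' @slot candidates candidate mode counts for [selectM()].
#' @seealso [sampleEntropy()], [selectM()]
#' @exportClass SampEnConfig
setClass("SampEnConfig",
  representation(embedDim = "integer", rMode = "character",
                 rValue = "numeric", candidates = "integer"))

setValidity("SampEnConfig", function(object) {
  msg <- character(0)
  if (object@embedDim < 1L) msg <- c(msg, "embedDim must be >= 1")
  if (object@rValue <= 0) msg <- c(msg, "rValue must be > 0")
  if (!object@rMode %in% c("relative_sd", "absolute"))
    msg <- c(msg, "rMode must be 'relative_sd' or 'absolute'")
  if (any(object@candidates < 1L)) msg <- c(msg, "candidates must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a sample-entropy configuration
#'
#' @param embedDim embedding dimension z (default 2).
#' @param rMode "relative_sd" (default) or "absolute".
#' @param rValue tolerance factor (default 0.2, i.e. 0.2 * SD).
#' @param candidates candidate M values for mode-count selection
#'   (default 2:6).
#' @return A [SampEnConfig-class] object.
#' @export
sampEnConfig <- function(embedDim = 2, rMode = "relative_sd", rValue = 0.2,
                         candidates = 2:6) {
  new("SampEnConfig", embedDim = as.integer(embedDim), rMode = rMode,
      rValue = rValue, candidates = as.integer(candidates))
}

#' ModeMatrix: stacked intrinsic mode functions of one signal
#'
#' The M x L matrix S whose rows are one signal's IMFs (ascending center
#' frequency) and whose columns s_l are the per-time-index vectors drawn as
#' polylines, together with its global extrema used for the per-signal
#' amplitude normalization.
#'
#' @slot S M x L numeric matrix.
#' @slot sMax,sMin true maximum and minimum entries of S.
#' @seealso [buildModeMatrix()], [mapCoordinates()]
#' @exportClass ModeMatrix
setClass("ModeMatrix",
  representation(S = "matrix", sMax = "numeric", sMin = "numeric"))

setValidity("ModeMatrix", function(object) {
  msg <- character(0)
  if (object@sMax < object@sMin) msg <- c(msg, "sMax must be >= sMin")
  if (length(object@S) &&
      (abs(object@sMax - max(object@S)) > 0 ||
       abs(object@sMin - min(object@S)) > 0))
    msg <- c(msg, "sMax/sMin must be the extrema of S")
  if (length(msg)) msg else TRUE
})

#' EncoderConfig: polyline image encoding settings
#'
#' Canvas geometry and color cycle for the sound-to-image encoding. The
#' defaults use an 1800 x 1200 canvas with drawing origin (288, 1010)
#' (y measured downward from the top-left pixel), a 1224 px drawing width,
#' a 190 px top bound, and a 10-color cycle.
#'
#' @slot nColors color-cycle length B.
#' @slot palette character vector of B distinct hex colors.
#' @slot imageWidth,imageHeight canvas size in pixels.
#' @slot originX,originY drawing origin (x_OS, y_OS), pixels.
#' @slot drawWidth horizontal drawing extent W_S, pixels.
#' @slot drawTop top drawing bound H_S, pixels (< originY).
#' @slot lineWidth polyline stroke width, pixels.
#' @seealso [encoderConfig()], [renderImage()]
#' @exportClass EncoderConfig
setClass("EncoderConfig",
  representation(nColors = "integer", palette = "character",
                 imageWidth = "integer", imageHeight = "integer",
                 originX = "integer", originY = "integer",
                 drawWidth = "integer", drawTop = "integer",
                 lineWidth = "integer"))

setValidity("EncoderConfig", function(object) {
  msg <- character(0)
  if (length(object@palette) != object@nColors)
    msg <- c(msg, "palette length must equal nColors")
  if (anyDuplicated(object@palette))
    msg <- c(msg, "palette entries must be pairwise distinct")
  if (object@originX + object@drawWidth > object@imageWidth)
    msg <- c(msg, "originX + drawWidth must be <= imageWidth")
  if (!(object@drawTop < object@originY &&
        object@originY <= object@imageHeight))
    msg <- c(msg, "need drawTop < originY <= imageHeight")
  if (object@lineWidth < 1L) msg <- c(msg, "lineWidth must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Master and default encoding palettes
#'
#' A fixed 12-color master set of visually distinct colors; the default
#' encoding uses its first 10 entries. Sweeps over the color-cycle length
#' truncate this same master set so that palettes are nested.
#'
#' @param n number of colors (<= 12).
#' @return Character vector of n hex colors.
#' @examples
#' masterPalette(10)
#' @export
masterPalette <- function(n = 12) {
  master <- c("#E6194B", "#3CB44B", "#FFE119", "#4363D8", "#F58231",
              "#911EB4", "#46F0F0", "#F032E6", "#008080", "#9A6324",
              "#800000", "#000075")
  if (n > length(master))
    stop("master palette has only ", length(master), " colors")
  master[seq_len(n)]
}

#' Construct an encoder configuration
#'
#' @param nColors color-cycle length B (default 10).
#' @param palette B distinct hex colors; defaults to the first B entries of
#'   [masterPalette()].
#' @param imageWidth,imageHeight canvas size (default 1800 x 1200).
#' @param originX,originY drawing origin (default 288, 1010).
#' @param drawWidth drawing width W_S (default 1224, symmetric margins).
#' @param drawTop top bound H_S (default 190).
#' @param lineWidth stroke width in pixels (default 2).
#' @return An [EncoderConfig-class] object.
#' @export
encoderConfig <- function(nColors = 10, palette = masterPalette(nColors),
                          imageWidth = 1800, imageHeight = 1200,
                          originX = 288, originY = 1010,
                          drawWidth = 1224, drawTop = 190, lineWidth = 2) {
  new("EncoderConfig", nColors = as.integer(nColors), palette = palette,
      imageWidth = as.integer(imageWidth),
      imageHeight = as.integer(imageHeight), originX = as.integer(originX),
      originY = as.integer(originY), drawWidth = as.integer(drawWidth),
      drawTop = as.integer(drawTop), lineWidth = as.integer(lineWidth))
}

#' EncodedImage: rendered RGB raster
#'
#' @slot pixels integer array height x width x 3, 8-bit channel values in
#'   0..255; row 1 is the top pixel row.
#' @slot label integer class label carried over from the source record
#'   (NA when not applicable, e.g. for a background canvas).
#' @seealso [renderImage()], [encodeDataset()], [writeImagePng()]
#' @exportClass EncodedImage
setClass("EncodedImage",
  representation(pixels = "array", label = "integer"))

setValidity("EncodedImage", function(object) {
  msg <- character(0)
  d <- dim(object@pixels)
  if (length(d) != 3L || d[3] != 3L)
    msg <- c(msg, "pixels must be a height x width x 3 array")
  if (min(object@pixels) < 0L || max(object@pixels) > 255L)
    msg <- c(msg, "channel values must lie in 0..255")
  if (length(object@label) != 1L)
    msg <- c(msg, "label must be a single integer (NA allowed)")
  if (length(msg)) msg else TRUE
})

setMethod("show", "EncodedImage", function(object) {
  d <- dim(object@pixels)
  lab <- if (is.na(object@label)) "unlabeled" else object@label
  cat("EncodedImage:", d[2], "x", d[1], "RGB, label", lab, "\n")
})

#' ViTConfig: MobileViT classifier settings
#'
#' Training hyperparameters follow the study protocol: 256 x 256 input,
#' 2 classes, batch size 16, learning rate 1e-3, 10 epochs. The channel
#' plan defaults to an XXS-scale layout; [mobileViTPlan()] also provides a
#' reduced "tiny" plan for fast CPU runs.
#'
#' @slot inputSize square input resolution in pixels.
#' @slot nClasses number of classes.
#' @slot batchSize minibatch size.
#' @slot learningRate Adam learning rate.
#' @slot epochs training epochs.
#' @slot patchH,patchW transformer patch size.
#' @slot channelPlan list describing stem width, stage layout and
#'   transformer dims (see [mobileViTPlan()]).
#' @slot weightDecay decoupled weight decay applied to weight matrices
#'   (never to biases or normalization parameters).
#' @slot seed RNG seed controlling init and shuffling.
#' @seealso [vitConfig()], [trainClassifier()]
#' @exportClass ViTConfig
setClass("ViTConfig",
  representation(inputSize = "integer", nClasses = "integer",
                 batchSize = "integer", learningRate = "numeric",
                 epochs = "integer", patchH = "integer", patchW = "integer",
                 channelPlan = "list", weightDecay = "numeric",
                 seed = "integer"))

setValidity("ViTConfig", function(object) {
  msg <- character(0)
  if (object@nClasses < 2L) msg <- c(msg, "nClasses must be >= 2")
  if (object@inputSize < 16L) msg <- c(msg, "inputSize must be >= 16")
  ## total downsampling = stem stride 2 x strided stages; the deepest
  ## feature map must still split into whole patchH x patchW patches
  strides <- vapply(object@channelPlan$stages, function(s)
    if (identical(s$type, "mv2")) as.integer(s$stride) else 1L, integer(1))
  down <- 2L * prod(strides) * max(object@patchH, object@patchW)
  if (object@inputSize %% down != 0L)
    msg <- c(msg, paste0("inputSize must be divisible by ", down))
  if (length(msg)) msg else TRUE
})

#' MobileViT channel plans
#'
#' \code{"xxs"} is the default plan (stem 16; inverted-residual stages
#' 16/24/48/64/80 with expansion 2; transformer dims 64/80/96 at depths
#' 2/4/3; classifier head 320). \code{"tiny"} is a reduced plan for
#' CPU-budget runs (stem 8; stages 8/16/24/32/40; transformer dims 48/64/80
#' at depth 1; head 160).
#'
#' @param scale "xxs" or "tiny".
#' @return A list with elements \code{stem}, \code{stages} (each stage a
#'   list with \code{type} "mv2" or "vit" and its sizes), \code{head},
#'   \code{heads} (attention heads), and \code{expansion}.
#' @export
mobileViTPlan <- function(scale = c("xxs", "tiny")) {
  scale <- match.arg(scale)
  if (scale == "xxs") {
    list(stem = 16L, expansion = 2L, heads = 2L, head = 320L,
         stages = list(
           list(type = "mv2", out = 16L, stride = 1L),
           list(type = "mv2", out = 24L, stride = 2L),
           list(type = "mv2", out = 24L, stride = 1L),
           list(type = "mv2", out = 48L, stride = 2L),
           list(type = "vit", tdim = 64L, depth = 2L, mlp = 128L),
           list(type = "mv2", out = 64L, stride = 2L),
           list(type = "vit", tdim = 80L, depth = 4L, mlp = 160L),
           list(type = "mv2", out = 80L, stride = 2L),
           list(type = "vit", tdim = 96L, depth = 3L, mlp = 192L)))
  } else {
    list(stem = 8L, expansion = 2L, heads = 2L, head = 160L,
         stages = list(
           list(type = "mv2", out = 8L, stride = 1L),
           list(type = "mv2", out = 16L, stride = 2L),
           list(type = "mv2", out = 24L, stride = 2L),
           list(type = "vit", tdim = 48L, depth = 1L, mlp = 96L),
           list(type = "mv2", out = 32L, stride = 2L),
           list(type = "vit", tdim = 64L, depth = 1L, mlp = 128L),
           list(type = "mv2", out = 40L, stride = 2L),
           list(type = "vit", tdim = 80L, depth = 1L, mlp = 160L)))
  }
}

#' Construct a classifier configuration
#'
#' @param inputSize square input resolution (default 256).
#' @param nClasses number of classes (default 2).
#' @param batchSize minibatch size (default 16).
#' @param learningRate Adam learning rate (default 1e-3).
#' @param epochs training epochs (default 10).
#' @param patchH,patchW transformer patch size (default 2 x 2).
#' @param channelPlan see [mobileViTPlan()].
#' @param weightDecay decoupled weight decay on weight matrices
#'   (default 1e-3).
#' @param seed RNG seed (default 1).
#' @return A [ViTConfig-class] object.
#' @export
vitConfig <- function(inputSize = 256, nClasses = 2, batchSize = 16,
                      learningRate = 1e-3, epochs = 10, patchH = 2,
                      patchW = 2, channelPlan = mobileViTPlan("xxs"),
                      weightDecay = 1e-3, seed = 1) {
  new("ViTConfig", inputSize = as.integer(inputSize),
      nClasses = as.integer(nClasses), batchSize = as.integer(batchSize),
      learningRate = learningRate, epochs = as.integer(epochs),
      patchH = as.integer(patchH), patchW = as.integer(patchW),
      channelPlan = channelPlan, weightDecay = weightDecay,
      seed = as.integer(seed))
}

#' MobileViTModel: a trained classifier
#'
#' @slot params nested list of parameter arrays.
#' @slot buffers nested list of non-trainable buffers (batch-norm running
#'   statistics).
#' @slot config the [ViTConfig-class] used for training.
#' @slot classLevels integer labels in output-unit order.
#' @slot history data.frame with per-epoch loss and training accuracy.
#' @seealso [trainClassifier()], [predictClassifier()]
#' @exportClass MobileViTModel
setClass("MobileViTModel",
  representation(params = "list", buffers = "list", config = "ViTConfig",
                 classLevels = "integer", history = "data.frame"))

setMethod("show", "MobileViTModel", function(object) {
  n <- sum(vapply(rapply(object@params, length, how = "unlist"),
                  identity, numeric(1)))
  cat("MobileViTModel:", length(object@classLevels), "classes,",
      format(n, big.mark = ","), "parameters,",
      nrow(object@history), "epochs trained\n")
})

#' Metrics: confusion counts and derived scores
#'
#' Positive class is the slight-crack class (label 0) unless flipped at
#' evaluation time. Ratios with a zero denominator are NA.
#'
#' @slot tp,fp,fn,tn confusion counts.
#' @slot precision,recall,f1,accuracy derived proportions in [0, 1] (NA
#'   when undefined).
#' @seealso [computeMetrics()]
#' @exportClass Metrics
setClass("Metrics",
  representation(tp = "integer", fp = "integer", fn = "integer",
                 tn = "integer", precision = "numeric", recall = "numeric",
                 f1 = "numeric", accuracy = "numeric"))

setMethod("show", "Metrics", function(object) {
  pc <- function(x) if (is.na(x)) "NA" else sprintf("%.1f%%", 100 * x)
  cat("Metrics (tp", object@tp, "fp", object@fp, "fn", object@fn,
      "tn", object@tn, ")\n  precision", pc(object@precision),
      " recall", pc(object@recall), " F1", pc(object@f1),
      " accuracy", pc(object@accuracy), "\n")
})

#' RunConfig: end-to-end pipeline settings
#'
#' @slot echoParams synthetic generator settings ([EchoModelParams-class]).
#' @slot vmd decomposition settings ([VMDConfig-class]).
#' @slot sampEn entropy settings ([SampEnConfig-class]).
#' @slot encoder encoding settings ([EncoderConfig-class]).
#' @slot vit classifier settings ([ViTConfig-class]).
#' @slot nIntact,nCrack synthetic class sizes.
#' @slot nBackgroundPerClass records per class reserved for the background.
#' @slot splitRatio train fraction (0.8 = 80/20 protocol).
#' @slot splitSeed seed of the stratified split.
#' @slot masterSeed master seed deriving all stage seeds.
#' @slot autoSelectM if TRUE, choose the mode count by minimum mean sample
#'   entropy before encoding.
#' @slot outputDir optional directory for reports and images (length 0 =
#'   in-memory only).
#' @seealso [runConfig()], [runPipeline()]
#' @exportClass RunConfig
setClass("RunConfig",
  representation(echoParams = "EchoModelParams", vmd = "VMDConfig",
                 sampEn = "SampEnConfig", encoder = "EncoderConfig",
                 vit = "ViTConfig", nIntact = "integer", nCrack = "integer",
                 nBackgroundPerClass = "integer", splitRatio = "numeric",
                 splitSeed = "integer", masterSeed = "integer",
                 autoSelectM = "logical", outputDir = "character"))

setValidity("RunConfig", function(object) {
  msg <- character(0)
  if (object@splitRatio <= 0 || object@splitRatio >= 1)
    msg <- c(msg, "splitRatio must lie strictly between 0 and 1")
  if (object@nIntact < 0L || object@nCrack < 0L)
    msg <- c(msg, "class sizes must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a pipeline run configuration
#'
#' Defaults emulate the full study conditions: 296 intact + 304 slight-crack
#' seeds, 30 + 30 background reservations, 80/20 stratified split.
#'
#' @param echoParams,vmd,sampEn,encoder,vit stage configurations.
#' @param nIntact,nCrack synthetic class sizes (defaults 296 and 304).
#' @param nBackgroundPerClass background reservations per class (default 30).
#' @param splitRatio train fraction (default 0.8).
#' @param splitSeed,masterSeed seeds.
#' @param autoSelectM select M by minimum mean sample entropy (default
#'   FALSE; the default vmd config already uses M = 3).
#' @param outputDir optional output directory.
#' @return A [RunConfig-class] object.
#' @export
runConfig <- function(echoParams = echoModelParams(), vmd = vmdConfig(),
                      sampEn = sampEnConfig(), encoder = encoderConfig(),
                      vit = vitConfig(), nIntact = 296, nCrack = 304,
                      nBackgroundPerClass = 30, splitRatio = 0.8,
                      splitSeed = 1, masterSeed = 1, autoSelectM = FALSE,
                      outputDir = character(0)) {
  new("RunConfig", echoParams = echoParams, vmd = vmd, sampEn = sampEn,
      encoder = encoder, vit = vit, nIntact = as.integer(nIntact),
      nCrack = as.integer(nCrack),
      nBackgroundPerClass = as.integer(nBackgroundPerClass),
      splitRatio = splitRatio, splitSeed = as.integer(splitSeed),
      masterSeed = as.integer(masterSeed), autoSelectM = autoSelectM,
      outputDir = outputDir)
}
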