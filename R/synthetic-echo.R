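## Synthetic A-scan generator. Emulates 400 kHz through-transmission
## tone-burst echoes: a direct pulse plus trailing multipath echoes, each a
## Gaussian-windowed, one-sidedly damped cosine at the carrier frequency,
## with additive Gaussian noise. A slight crack changes the structural
## strength and damping of the kernel, which shifts the carrier frequency
## downward, strengthens damping, and reduces intensity; the generator
## carries class identity through exactly those three cues (burst phases
## are random so phase carries no class information).

## Noiseless waveform for a class, given per-burst phases.
echoWaveform <- function(classLabel, params, phases) {
  n <- seq_len(params@nSamples) - 1
  sep <- if (classLabel == 0L) params@separation else 0
  f <- params@carrierFreq - sep * params@crackFreqShift
  beta <- params@dampingRate * (1 + (params@crackDampingMultiplier - 1) * sep)
  gains <- params@burstGains * (1 - (1 - params@crackGainMultiplier) * sep)
  fNorm <- f / params@sampleRate
  x <- numeric(params@nSamples)
  for (k in seq_along(params@burstCenters)) {
    nk <- params@burstCenters[k]
    env <- exp(-(n - nk)^2 / (2 * params@burstWidth^2)) *
      exp(-beta * pmax(0, n - nk))
    x <- x + gains[k] * env * cos(2 * pi * fNorm * n + phases[k])
  }
  x
}

#' Generate one synthetic A-scan
#'
#' Draws per-burst phases uniformly on [0, 2 pi), builds the class-dependent
#' noiseless waveform, and adds Gaussian noise with SD equal to
#' \code{noiseSd} times the peak absolute noiseless amplitude. The same
#' seed always yields the identical record, and at \code{separation = 0}
#' matched seeds yield identical records for both classes.
#'
#' @param classLabel 1 (intact) or 0 (slight crack).
#' @param params an [EchoModelParams-class].
#' @param seed integer RNG seed for this record.
#' @return An [UltrasoundRecord-class] with the requested label.
#' @examples
#' rec <- generateSignal(1, echoModelParams(), seed = 1)
#' rec
#' @export
generateSignal <- function(classLabel, params = echoModelParams(), seed = 1) {
  if (length(classLabel) != 1L || !classLabel %in% c(0, 1))
    stop("classLabel must be 0 or 1")
  validObject(params)
  classLabel <- as.integer(classLabel)
  withSeed(seed, {
    phases <- stats::runif(length(params@burstCenters), 0, 2 * pi)
    x <- echoWaveform(classLabel, params, phases)
    if (params@noiseSd > 0) {
      peak <- max(abs(x))
      x <- x + stats::rnorm(length(x), 0, params@noiseSd * peak)
    }
    ultrasoundRecord(x, label = classLabel,
                     sampleId = sprintf("synthetic_%d_%d", classLabel, seed))
  })
}

#' Generate a labeled synthetic dataset
#'
#' Produces \code{nIntact} label-1 records followed by \code{nCrack}
#' label-0 records. Each record uses a seed derived deterministically from
#' the master seed, so the whole dataset is reproducible element-wise.
#' The study-scale dataset is 296 intact + 304 slight-crack records.
#'
#' @param nIntact,nCrack class sizes (>= 0).
#' @param params an [EchoModelParams-class].
#' @param seed master seed.
#' @return List of [UltrasoundRecord-class] objects.
#' @examples
#' ds <- generateDataset(3, 2, seed = 1)
#' vapply(ds, recordLabel, integer(1))
#' @export
generateDataset <- function(nIntact, nCrack, params = echoModelParams(),
                            seed = 1) {
  if (nIntact < 0 || nCrack < 0) stop("counts must be >= 0")
  labels <- c(rep(1L, nIntact), rep(0L, nCrack))
  out <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    rec <- generateSignal(labels[i], params, seed = deriveSeed(seed, i))
    rec@sampleId <- sprintf("synthetic_%03d_label%d", i, labels[i])
    out[[i]] <- rec
  }
  out
}

#' Write a synthetic dataset to a directory
#'
#' Writes one CSV per record (see [writeSignalCsv()]) plus a
#' \code{manifest.json} recording the master seed and generator parameters,
#' from which the dataset can be regenerated exactly.
#'
#' @param records list of [UltrasoundRecord-class] objects.
#' @param directory output directory (created if needed).
#' @param params generator parameters to record in the manifest.
#' @param seed master seed to record in the manifest.
#' @return Invisibly, the directory path.
#' @export
writeDataset <- function(records, directory, params = NULL, seed = NULL) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(records)) {
    rec <- records[[i]]
    writeSignalCsv(rec, file.path(directory,
                                  sprintf("%s.csv", rec@sampleId)))
  }
  manifest <- list(n_records = length(records), seed = seed)
  if (!is.null(params))
    manifest$params <- list(
      sampleRate = params@sampleRate, nSamples = params@nSamples,
      carrierFreq = params@carrierFreq, burstCenters = params@burstCenters,
      burstGains = params@burstGains, burstWidth = params@burstWidth,
      dampingRate = params@dampingRate,
      crackFreqShift = params@crackFreqShift,
      crackDampingMultiplier = params@crackDampingMultiplier,
      crackGainMultiplier = params@crackGainMultiplier,
      separation = params@separation, noiseSd = params@noiseSd)
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(directory)
}
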