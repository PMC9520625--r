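## Sample entropy and mode-count selection. SampEn(z, r) = -ln(A/B), where
## B and A count ordered template pairs (i != j, i, j <= L - z) within
## Chebyshev tolerance r at embedding dimensions z and z + 1 (the canonical
## Richman-Moorman estimator: self-matches excluded, the same L - z
## templates counted at both dimensions). Lower values indicate a more
## regular, self-similar series. The VMD mode count M is chosen as the
## candidate whose modes have the smallest mean sample entropy.

## max over the k = 0..m-1 diagonal window of the pairwise |x_i - x_j|
## matrix: chebD(x, m)[i, j] = max_k |x[i+k] - x[j+k]|.
chebyshevDistances <- function(x, m) {
  n <- length(x)
  D <- abs(outer(x, x, "-"))
  Z <- n - m + 1L
  out <- D[seq_len(Z), seq_len(Z), drop = FALSE]
  k <- 1L
  while (k < m) {
    out <- pmax(out, D[k + seq_len(Z), k + seq_len(Z), drop = FALSE])
    k <- k + 1L
  }
  out
}

## resolve the tolerance for one series under the configured rule
resolveTolerance <- function(series, config) {
  if (config@rMode == "relative_sd") config@rValue * stats::sd(series)
  else config@rValue
}

#' Sample entropy of a series
#'
#' @param series numeric vector of length >= embedDim + 2.
#' @param config a [SampEnConfig-class]; under \code{rMode = "relative_sd"}
#'   the tolerance is \code{rValue * sd(series)}, making the value
#'   invariant to rescaling the series.
#' @return Non-negative sample entropy; \code{Inf} (with a warning) when no
#'   template pair matches at dimension z + 1. An error is raised when no
#'   pair matches even at dimension z.
#' @examples
#' sampleEntropy(rep(1, 100))                    # perfectly regular: 0
#' sampleEntropy(sin(seq_len(200) / 5))          # low
#' @export
sampleEntropy <- function(series, config = sampEnConfig()) {
  validObject(config)
  z <- config@embedDim
  L <- length(series)
  if (L < z + 2L) stop("series too short: need length >= embedDim + 2")
  r <- resolveTolerance(series, config)
  nz <- L - z                      # templates counted at both dimensions
  Dz <- chebyshevDistances(series, z)
  B <- sum(Dz[seq_len(nz), seq_len(nz)] <= r) - nz
  Dz1 <- chebyshevDistances(series, z + 1L)
  A <- sum(Dz1 <= r) - nz
  if (B == 0L)
    stop("sample entropy undefined: no template pairs match at dimension z")
  if (A == 0L) {
    warning("no template pairs match at dimension z + 1; returning Inf")
    return(Inf)
  }
  -log(A / B)
}

#' Mean sample entropy over the modes of a decomposition
#'
#' Arithmetic mean of [sampleEntropy()] over the M modes, each mode using
#' its own tolerance (r relative to that mode's SD under
#' \code{relative_sd}). An infinite single-mode entropy propagates to the
#' mean.
#'
#' @param result a [VMDResult-class] with >= 1 mode.
#' @param config a [SampEnConfig-class].
#' @return Mean sample entropy (possibly \code{Inf}).
#' @export
meanModeEntropy <- function(result, config = sampEnConfig()) {
  stopifnot(is(result, "VMDResult"))
  M <- nrow(result@modes)
  if (M < 1L) stop("result has no modes")
  vals <- vapply(seq_len(M),
                 function(m) sampleEntropy(result@modes[m, ], config),
                 numeric(1))
  mean(vals)
}

#' Select the mode count by minimum mean sample entropy
#'
#' Decomposes the signal once per candidate M, computes the mean sample
#' entropy of the resulting modes, and returns the candidate with the
#' smallest value (ties broken toward the smallest M).
#'
#' @param signal numeric waveform.
#' @param vmdConfigTemplate a [VMDConfig-class] whose \code{nModes} is
#'   overridden per candidate.
#' @param config a [SampEnConfig-class] carrying the candidate list.
#' @return The selected mode count (integer). The per-candidate entropies
#'   are attached as attribute \code{"entropies"} (named by candidate).
#' @examples
#' x <- amplitudes(generateSignal(1, seed = 1))
#' selectM(x, config = sampEnConfig(candidates = c(2, 3)))
#' @export
selectM <- function(signal, vmdConfigTemplate = vmdConfig(),
                    config = sampEnConfig()) {
  cands <- sort(unique(config@candidates))
  ent <- vapply(cands, function(M) {
    cfg <- vmdConfigTemplate
    cfg@nModes <- as.integer(M)
    meanModeEntropy(vmdDecompose(signal, cfg), config)
  }, numeric(1))
  if (all(!is.finite(ent)))
    stop("selection error: all candidates give infinite mean entropy")
  chosen <- cands[which.min(ent)]   # first minimum = smallest M on ties
  structure(as.integer(chosen), entropies = stats::setNames(ent, cands))
}
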