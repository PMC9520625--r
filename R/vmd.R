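## Variational mode decomposition. The signal is split into M band-limited
## intrinsic mode functions by minimizing the summed bandwidth of the
## analytic-signal spectra subject to the modes summing to the input,
## solved with ADMM: a Wiener-filter mode update, a power-centroid
## center-frequency update, and a dual-ascent step, iterated to a relative
## change tolerance. Updates operate on the non-negative half spectrum;
## negative frequencies follow by conjugate symmetry. The signal is
## mirror-extended by half its length at each end before the transform and
## cropped after inversion to suppress edge ringing.

#' Wiener-filter mode-spectrum update
#'
#' One ADMM mode update on the non-negative half spectrum: the residual of
#' the signal spectrum after removing the other modes (plus half the dual
#' variable) is attenuated by \code{1 / (1 + 2 alpha (omega_grid - omega)^2)}.
#' The gain is exactly 1 at the bin where the grid frequency equals the
#' mode's center frequency.
#'
#' @param signalSpectrum,otherModesSum,dualSpectrum complex half-spectra of
#'   equal length.
#' @param omega the mode's current center frequency (cycles/sample).
#' @param alpha bandwidth penalty.
#' @param freqGrid normalized frequencies of the half-spectrum bins;
#'   defaults to an even grid over [0, 0.5].
#' @return Updated complex half-spectrum.
#' @export
updateModeSpectrum <- function(signalSpectrum, otherModesSum, dualSpectrum,
                               omega, alpha,
                               freqGrid = seq(0, 0.5,
                                              length.out =
                                                length(signalSpectrum))) {
  n <- length(signalSpectrum)
  if (length(otherModesSum) != n || length(dualSpectrum) != n ||
      length(freqGrid) != n)
    stop("shape error: spectra and frequency grid must share one length")
  (signalSpectrum - otherModesSum + dualSpectrum / 2) /
    (1 + 2 * alpha * (freqGrid - omega)^2)
}

#' Power-centroid center-frequency update
#'
#' Returns the power-weighted mean frequency of a mode's half-spectrum.
#' A spectrum with zero power leaves the center frequency unchanged: the
#' documented fallback returns \code{previous}.
#'
#' @param modeSpectrum complex half-spectrum.
#' @param freqGrid normalized frequencies of the bins.
#' @param previous value returned when the spectrum has zero power.
#' @return Normalized center frequency (cycles/sample).
#' @export
updateCenterFrequency <- function(modeSpectrum, freqGrid,
                                  previous = NA_real_) {
  if (length(modeSpectrum) != length(freqGrid))
    stop("shape error: spectrum and frequency grid must share one length")
  p <- Mod(modeSpectrum)^2
  tot <- sum(p)
  if (tot == 0) return(previous)
  sum(freqGrid * p) / tot
}

#' ADMM convergence check
#'
#' TRUE iff the summed relative squared spectral change
#' \code{sum_m ||u_m(new) - u_m(old)||^2 / ||u_m(old)||^2} is below
#' \code{eps}. A mode whose previous spectrum has zero norm contributes 0
#' when unchanged; if it changed, the criterion is not met.
#'
#' @param prevModesSpec,newModesSpec lists of complex half-spectra.
#' @param eps tolerance.
#' @return Logical flag.
#' @export
checkConvergence <- function(prevModesSpec, newModesSpec, eps) {
  stopifnot(length(prevModesSpec) == length(newModesSpec))
  total <- 0
  for (m in seq_along(prevModesSpec)) {
    d <- newModesSpec[[m]] - prevModesSpec[[m]]
    if (length(d) != length(prevModesSpec[[m]]))
      stop("shape error: mismatched spectra")
    num <- sum(Mod(d)^2)
    den <- sum(Mod(prevModesSpec[[m]])^2)
    if (den == 0) {
      if (num > 0) return(FALSE)
    } else {
      total <- total + num / den
    }
  }
  total < eps
}

#' Variational mode decomposition of a waveform
#'
#' Decomposes a real signal into \code{config@nModes} band-limited modes.
#' Mode spectra are updated Gauss-Seidel style (each mode sees the already
#' updated spectra of the others within an iteration), center frequencies
#' by power centroid, and the dual variable by \code{tau} times the
#' reconstruction residual. Iteration stops when the summed relative
#' squared change falls below \code{config@eps} or at \code{maxIter}.
#' Returned modes are sorted by ascending center frequency and reconstruct
#' the input as their sum (exactly when converged with \code{tau > 0},
#' closely otherwise).
#'
#' @param signal finite numeric vector, length >= 4 * nModes.
#' @param config a [VMDConfig-class].
#' @return A [VMDResult-class].
#' @examples
#' x <- cos(2 * pi * 0.1 * (0:449))
#' res <- vmdDecompose(x, vmdConfig(nModes = 1))
#' centerFrequencies(res)
#' @export
vmdDecompose <- function(signal, config = vmdConfig()) {
  validObject(config)
  if (anyNA(signal) || any(!is.finite(signal)))
    stop("signal must be finite")
  L <- length(signal)
  M <- config@nModes
  if (L < 4L * M) stop("signal too short: need length >= 4 * nModes")

  ## mirror extension: half the signal reflected at each end
  half <- L %/% 2L
  ext <- c(rev(signal[seq_len(half)]), signal,
           rev(signal[seq(L - half + 1L, L)]))
  Tlen <- length(ext)
  K <- Tlen %/% 2L + 1L          # non-negative frequency bins
  if (M > K - 1L) stop("nModes exceeds the usable spectrum bins")
  fh <- stats::fft(ext)[seq_len(K)]
  freqs <- (seq_len(K) - 1) / Tlen

  omega <- switch(config@initOmega,
                  uniform = 0.5 * seq_len(M) / (M + 1),
                  zero = rep(0, M))
  U <- matrix(0 + 0i, nrow = K, ncol = M)
  lam <- complex(K)
  n <- 0L
  converged <- FALSE
  repeat {
    n <- n + 1L
    Uprev <- U
    for (m in seq_len(M)) {
      others <- if (M > 1L) rowSums(U[, -m, drop = FALSE]) else complex(K)
      U[, m] <- updateModeSpectrum(fh, others, lam, omega[m],
                                   config@alpha, freqs)
      omega[m] <- updateCenterFrequency(U[, m], freqs, previous = omega[m])
    }
    if (config@tau > 0)
      lam <- lam + config@tau * (fh - rowSums(U))
    if (checkConvergence(asplit(Uprev, 2), asplit(U, 2), config@eps)) {
      converged <- TRUE
      break
    }
    if (n >= config@maxIter) break
  }

  ord <- order(omega)
  modesOut <- matrix(0, nrow = M, ncol = L)
  for (m in seq_len(M)) {
    uh <- U[, ord[m]]
    full <- complex(Tlen)
    full[seq_len(K)] <- uh
    if (K > 2L) {
      idx <- 2:(K - 1L)
      full[Tlen - idx + 2L] <- Conj(uh[idx])
    }
    u <- Re(stats::fft(full, inverse = TRUE)) / Tlen
    modesOut[m, ] <- u[(half + 1L):(half + L)]
  }
  new("VMDResult", modes = modesOut,
      omegas = pmin(pmax(omega[ord], 0), 0.5),
      iterations = n, converged = converged)
}
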