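## Spike detection from raw traces: second-order Bessel high-pass (200 Hz),
## robust noise estimate, negative threshold at -4.5 sigma, one event per
## dead-time window with the timestamp at the trough sample.

#' Spike detection parameters
#'
#' @param filterOrder high-pass filter order; only 2 is supported (the
#'   acquisition chain's filter).
#' @param filterCutoffHz high-pass cutoff frequency, Hz (default 200).
#' @param thresholdFactor detection threshold in multiples of the noise
#'   s.d.; the threshold applied is \code{-thresholdFactor * sigma}
#'   (default 4.5).
#' @param deadTimeMs minimum separation between detected events, ms. The
#'   default (1 ms) is shorter than the 2 ms pairwise propagation-delay
#'   window, so dead time cannot suppress genuine propagation partners.
#' @param noiseWindowS minimum trace length for noise estimation, s.
#' @param zeroPhase logical; apply the filter forward-backward
#'   (zero-phase) instead of causal forward-only. Causal filtering matches
#'   an online acquisition chain and is the default because timestamps feed
#'   latency computations.
#' @return A validated list of class \code{"DetectionParams"}.
#' @export
detectionParams <- function(filterOrder = 2L, filterCutoffHz = 200,
                            thresholdFactor = 4.5, deadTimeMs = 1,
                            noiseWindowS = 0.1, zeroPhase = FALSE) {
  if (filterOrder != 2L)
    stop("invalid DetectionParams field 'filterOrder': only order 2 supported")
  if (filterCutoffHz <= 0)
    stop("invalid DetectionParams field 'filterCutoffHz': must be > 0")
  if (thresholdFactor <= 0)
    stop("invalid DetectionParams field 'thresholdFactor': must be > 0")
  if (deadTimeMs < 0)
    stop("invalid DetectionParams field 'deadTimeMs': must be >= 0")
  structure(list(filterOrder = 2L, filterCutoffHz = filterCutoffHz,
                 thresholdFactor = thresholdFactor, deadTimeMs = deadTimeMs,
                 noiseWindowS = noiseWindowS, zeroPhase = zeroPhase),
            class = "DetectionParams")
}

## order-2 Bessel polynomial s^2 + 3 s + 3; its low-pass -3 dB frequency is
## w with w^4 + 3 w^2 - 9 = 0, i.e. w = 1.3616541...; the magnitude-normalized
## high-pass at analog cutoff Wc is H(s) = s^2 / (s^2 + a1 s + a0) with
## a1 = wN * Wc, a0 = (wN * Wc)^2 / 3.
besselW3dB <- sqrt((-3 + sqrt(45)) / 2)

besselHighpassCoefficients <- function(cutoffHz, samplingRateHz) {
  if (cutoffHz >= samplingRateHz / 2)
    stop("cutoff (", cutoffHz, " Hz) must be below the Nyquist frequency (",
         samplingRateHz / 2, " Hz)")
  ## bilinear transform s = K (1 - z^-1)/(1 + z^-1), prewarped at the cutoff
  K <- 2 * samplingRateHz
  Wc <- K * tan(pi * cutoffHz / samplingRateHz)
  a1 <- besselW3dB * Wc
  a0 <- a1^2 / 3
  b <- K^2 * c(1, -2, 1)
  a <- c(K^2 + a1 * K + a0, -2 * K^2 + 2 * a0, K^2 - a1 * K + a0)
  list(b = b / a[1], a = a / a[1])
}

#' Analytic transfer magnitude of the second-order Bessel high-pass
#'
#' Magnitude response of the analog prototype used by
#' \code{\link{highpassFilter}}, for validation and documentation.
#'
#' @param freqHz frequencies at which to evaluate, Hz.
#' @param cutoffHz -3 dB cutoff frequency, Hz.
#' @return Numeric vector of gains in (0, 1].
#' @export
besselHighpassGain <- function(freqHz, cutoffHz) {
  w <- 2 * pi * freqHz
  a1 <- besselW3dB * 2 * pi * cutoffHz
  a0 <- a1^2 / 3
  w^2 / sqrt((a0 - w^2)^2 + (a1 * w)^2)
}

#' High-pass filter a voltage trace
#'
#' Applies the acquisition chain's second-order Bessel high-pass (default
#' cutoff 200 Hz), rejecting DC and low-frequency field potentials before
#' spike detection. Causal (forward-only) by default; set
#' \code{zeroPhase = TRUE} in the params for forward-backward filtering.
#'
#' @param trace numeric voltage samples, uV.
#' @param samplingRateHz sampling rate, Hz; must exceed twice the cutoff.
#' @param params a \code{\link{detectionParams}}.
#' @return Filtered trace of the same length.
#' @export
highpassFilter <- function(trace, samplingRateHz,
                           params = detectionParams()) {
  co <- besselHighpassCoefficients(params$filterCutoffHz, samplingRateHz)
  if (isTRUE(params$zeroPhase))
    as.numeric(signal::filtfilt(co$b, co$a, trace))
  else
    as.numeric(signal::filter(co$b, co$a, trace))
}

#' Robust noise estimate of a filtered trace
#'
#' Estimates the noise standard deviation from the median absolute
#' deviation (MAD, scaled for Gaussian consistency), which is insensitive to
#' the sparse large-amplitude spikes riding on the noise floor.
#'
#' @param trace filtered voltage samples, uV.
#' @return Noise sigma in uV; an all-zero (or constant) trace returns 0
#'   with a warning.
#' @export
estimateNoise <- function(trace) {
  if (any(!is.finite(trace))) stop("trace contains non-finite samples")
  sigma <- stats::median(abs(trace - stats::median(trace))) / 0.6744898
  if (sigma == 0)
    warning("degenerate trace: noise estimate is 0")
  sigma
}

#' Detect spikes by negative threshold crossing
#'
#' Detects spike timestamps in a (filtered) trace as crossings of the
#' negative threshold \code{-thresholdFactor * sigma}, emitting one event
#' per dead-time window with the timestamp placed at the trough (most
#' negative sample) of the crossing.
#'
#' @param trace filtered voltage samples, uV.
#' @param samplingRateHz sampling rate, Hz.
#' @param params a \code{\link{detectionParams}}.
#' @param sigma noise s.d. in uV; estimated with \code{\link{estimateNoise}}
#'   when \code{NULL}.
#' @return Strictly increasing numeric vector of timestamps in seconds,
#'   with the applied threshold attached as attribute
#'   \code{"threshold_uv"}.
#' @export
detectSpikes <- function(trace, samplingRateHz, params = detectionParams(),
                         sigma = NULL) {
  if (any(!is.finite(trace))) stop("trace contains non-finite samples")
  if (is.null(sigma)) sigma <- suppressWarnings(estimateNoise(trace))
  thr <- -params$thresholdFactor * sigma
  n <- length(trace)
  out <- numeric(0)
  if (sigma > 0 && n > 1L) {
    below <- trace < thr
    crossings <- which(below & !c(FALSE, below[-n]))
    deadS <- max(1L, round(params$deadTimeMs / 1000 * samplingRateHz))
    lastTrough <- -Inf
    troughs <- integer(0)
    for (cx in crossings) {
      if (cx <= lastTrough + deadS && cx > lastTrough) next
      ## trough: most negative sample within the dead-time window
      hi <- min(n, cx + deadS - 1L)
      tr <- cx - 1L + which.min(trace[cx:hi])
      if (tr <= lastTrough) next
      troughs <- c(troughs, tr)
      lastTrough <- tr
    }
    out <- (troughs - 1L) / samplingRateHz
  }
  structure(out, threshold_uv = thr)
}

#' Detect spikes on every electrode of a recording
#'
#' Filters each trace, estimates its noise per electrode, detects threshold
#' crossings and assembles the result into a
#' \code{\linkS4class{SpikeTable}}.
#'
#' @param recording a \code{\linkS4class{Recording}}.
#' @param params a \code{\link{detectionParams}}.
#' @return A \code{\linkS4class{SpikeTable}} with the recording's layout
#'   and metadata.
#' @export
detectRecording <- function(recording, params = detectionParams()) {
  stopifnot(is(recording, "Recording"))
  fs <- recording@samplingRateHz
  durationS <- recordingDuration(recording)
  tab <- emptySpikeTable(recording@layout, durationS, recording@metadata)
  for (id in names(recording@traces)) {
    f <- highpassFilter(recording@traces[[id]], fs, params)
    ts <- as.numeric(detectSpikes(f, fs, params))
    tab@spikes[[id]] <- ts[ts <= durationS]
  }
  validObject(tab)
  tab
}
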