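## Auditory frontend: gammatone spectrogram and excitation patterns.

#' Equivalent rectangular bandwidth law
#'
#' ERB(f) = a*(b*f/1000 + 1) Hz; default coefficients (24.7, 4.37) are the
#' standard human law. The law is configurable per species via
#' \code{erbCoef} in \linkS4class{FrontendParams}.
#'
#' @param f frequency, Hz.
#' @param coef coefficients (a, b).
#' @return bandwidth in Hz.
#' @export
erbHz <- function(f, coef = c(24.7, 4.37)) coef[1] * (coef[2] * f / 1000 + 1)

#' ERB-rate scale (number of ERBs below frequency f)
#' @inheritParams erbHz
#' @return ERB-rate value (dimensionless).
#' @export
erbRate <- function(f, coef = c(24.7, 4.37)) {
  (1000 / (coef[1] * coef[2])) * log(coef[2] * f / 1000 + 1)
}

## Log-spaced center frequencies, fLow..fHigh inclusive.
gammatoneCenterFreqs <- function(params) {
  2^seq(log2(params@fLow), log2(params@fHigh), length.out = params@nChannels)
}

#' Gammatone log-energy spectrogram
#'
#' Filters the waveform through a bank of gammatone filters (order
#' \code{gammatoneOrder}, realized in the frequency domain as the analytic
#' gammatone response, equivalent to cascaded second-order sections),
#' extracts the envelope as the magnitude of the analytic filter output,
#' averages it over non-overlapping frames at \code{frameRate}, and
#' log-compresses with an additive floor: log(env + logFloor). Channel
#' bandwidths follow the ERB law at each center frequency.
#'
#' @param wave numeric vector of audio samples (full scale [-1, 1]).
#' @param rate sample rate, Hz; must be at least 2 * fHigh.
#' @param params a \linkS4class{FrontendParams}.
#' @return a \linkS4class{Spectrogram} with ceil(duration * frameRate) frames.
#' @examples
#' p <- frontendParams(fHigh = 8000)
#' s <- gammatoneSpectrogram(sin(2 * pi * 1000 * (0:7999) / 16000), 16000, p)
#' @export
gammatoneSpectrogram <- function(wave, rate, params = frontendParams()) {
  stopifnotMsg(all(is.finite(wave)), "waveform contains non-finite samples")
  if (rate < 2 * params@fHigh)
    stop(sprintf("sample rate %g Hz is below the Nyquist limit 2*fHigh = %g Hz",
                 rate, 2 * params@fHigh))
  n <- length(wave)
  cf <- gammatoneCenterFreqs(params)
  F <- params@nChannels
  ord <- params@gammatoneOrder
  ## bandwidth parameter b such that the filter's equivalent rectangular
  ## bandwidth equals ERB(fc):  ERB = b * sqrt(pi) * gamma(n - 1/2) / gamma(n)
  bwFactor <- sqrt(pi) * gamma(ord - 0.5) / gamma(ord)
  X <- fft(wave)
  freqs <- (seq_len(n) - 1) / n * rate
  pos <- freqs <= rate / 2          # analytic signal: keep positive half
  T <- ceiling(n / rate * params@frameRate)
  hop <- rate / params@frameRate
  frameIdx <- pmin(floor((seq_len(n) - 1) / hop) + 1L, T)
  vals <- matrix(0, F, T)
  for (ch in seq_len(F)) {
    b <- erbHz(cf[ch], params@erbCoef) / bwFactor
    H <- (1 + 1i * (freqs - cf[ch]) / b)^(-ord)
    H[!pos] <- 0
    env <- Mod(fft(X * H * 2, inverse = TRUE)) / n
    vals[ch, ] <- as.numeric(tapply(env, frameIdx, mean))
  }
  spectrogram(log(vals + params@logFloor), frameRate = params@frameRate,
              centerFreqs = cf)
}

#' Cosine filterbank for excitation patterns
#'
#' Half-cosine magnitude profiles evenly spaced on the ERB-rate axis,
#' coarsely mimicking cochlear filtering. Each filter spans two center
#' spacings, so adjacent filters overlap by half.
#'
#' @param freqs frequency grid, Hz.
#' @param nFilters number of filters.
#' @param fLow,fHigh frequency span of filter centers, Hz.
#' @param erbCoef ERB law coefficients.
#' @return nFilters x length(freqs) matrix of filter magnitudes.
#' @export
cosineFilterbank <- function(freqs, nFilters = 32L, fLow = 100, fHigh = 16000,
                             erbCoef = c(24.7, 4.37)) {
  E <- erbRate(freqs, erbCoef)
  centers <- seq(erbRate(fLow, erbCoef), erbRate(fHigh, erbCoef),
                 length.out = nFilters)
  dE <- diff(centers[1:2])
  W <- matrix(0, nFilters, length(freqs))
  for (j in seq_len(nFilters)) {
    u <- (E - centers[j]) / dE
    inside <- abs(u) < 1
    W[j, inside] <- cos(pi / 2 * u[inside])
  }
  W
}

#' Excitation pattern of a sound segment
#'
#' Multiplies the segment's power spectrum with a bank of cosine filters on
#' the ERB-rate axis and compresses the per-filter outputs with a power law
#' (default exponent 0.3). Used to measure spectral similarity between
#' candidate stimulus segments; the Pearson correlation between two patterns
#' is invariant to overall segment gain.
#'
#' @param segment numeric vector of audio samples.
#' @param rate sample rate, Hz.
#' @param nFilters number of cosine filters.
#' @param exponent compression exponent.
#' @param fLow,fHigh filter center span, Hz (fHigh is capped at Nyquist).
#' @param erbCoef ERB law coefficients.
#' @return non-negative numeric vector, one entry per cosine filter
#'   (attribute \code{exponent} records the compression used).
#' @export
excitationPattern <- function(segment, rate, nFilters = 32L, exponent = 0.3,
                              fLow = 100, fHigh = 16000,
                              erbCoef = c(24.7, 4.37)) {
  stopifnotMsg(length(segment) > 0, "empty segment")
  n <- length(segment)
  P <- Mod(fft(segment))^2
  half <- seq_len(floor(n / 2) + 1L)
  freqs <- (half - 1) / n * rate
  W <- cosineFilterbank(freqs, nFilters, fLow, min(fHigh, rate / 2), erbCoef)
  out <- as.numeric(W %*% P[half])^exponent
  attr(out, "exponent") <- exponent
  out
}
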