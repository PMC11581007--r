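## Quantitative tuning descriptors.

#' Noise-corrected prediction correlation
#'
#' Correlation between a model prediction and the trial-mean PSTH,
#' normalized by the response's noise ceiling estimated from trial-to-trial
#' covariance: the signal power SP = (var(sum_i R_i) - sum_i var(R_i)) /
#' (M (M-1)) for M trials, and the corrected coefficient is
#' cov(pred, PSTH) / sqrt(var(pred) * SP), clipped to [-1, 1]. With a
#' noiseless raster (all trials identical) this reduces exactly to the plain
#' Pearson correlation.
#'
#' @param pred predicted rate series (length T).
#' @param raster trials x T matrix of single-trial responses (>= 2 trials).
#' @param method "noise-corrected" (default) or "pearson" (no correction).
#' @return scalar correlation estimate.
#' @export
noiseCorrectedPredictionCorrelation <- function(pred, raster,
                                                method = c("noise-corrected",
                                                           "pearson")) {
  method <- match.arg(method)
  stopifnotMsg(is.matrix(raster) && nrow(raster) >= 2L, "need >= 2 trials")
  stopifnotMsg(ncol(raster) == length(pred), "pred/raster length mismatch")
  psth <- colMeans(raster)
  if (sd(pred) == 0) {
    warning("zero-variance prediction; returning 0")
    return(0)
  }
  if (method == "pearson") return(cor(pred, psth))
  M <- nrow(raster)
  vTot <- var(colSums(raster))
  vInd <- sum(apply(raster, 1, var))
  SP <- (vTot - vInd) / (M * (M - 1))
  if (!is.finite(SP) || SP <= 0) {
    warning("non-positive signal-power estimate; returning 0")
    return(0)
  }
  cc <- cov(pred, psth) / sqrt(var(pred) * SP)
  min(max(cc, -1), 1)
}

#' Signal correlation between two PSTHs
#'
#' Plain Pearson correlation; constant input yields NA (flagged missing).
#'
#' @param psthA,psthB equal-length rate series.
#' @return correlation coefficient, or NA if either input is constant.
#' @export
signalCorrelation <- function(psthA, psthB) {
  stopifnotMsg(length(psthA) == length(psthB), "length mismatch")
  safeCor(psthA, psthB)
}

#' Subspace similarity index (SSI)
#'
#' SSI = sum_{m,n} |cc(g_a,m, g_b,n)| / min(M, N), with cc the Pearson
#' correlation between flattened filters and M, N the filter counts compared
#' (capped at \code{nFilters}, default 4). Absolute correlations make the
#' index invariant to the arbitrary sign of PCA components, anchoring it to
#' [0, 1]-like behavior: 1 indicates complete overlap between two neurons'
#' subspaces, 0 no overlap.
#'
#' @param subA,subB \linkS4class{TuningSubspace} objects (or filter
#'   matrices, columns = flattened filters).
#' @param nFilters cap on the number of leading filters compared per neuron.
#' @return scalar SSI.
#' @export
subspaceSimilarityIndex <- function(subA, subB, nFilters = 4L) {
  GA <- if (is(subA, "TuningSubspace")) filters(subA) else subA
  GB <- if (is(subB, "TuningSubspace")) filters(subB) else subB
  M <- min(ncol(GA), nFilters); N <- min(ncol(GB), nFilters)
  stopifnotMsg(M >= 1L && N >= 1L, "each subspace needs at least 1 filter")
  s <- 0
  for (m in seq_len(M)) for (n in seq_len(N)) {
    cc <- safeCor(GA[, m], GB[, n])
    if (!is.na(cc)) s <- s + abs(cc)
  }
  s / min(M, N)
}

#' Tuning symmetry index (TSI)
#'
#' Distinguishes symmetric upward-facing (+1), symmetric downward-facing
#' (-1) and asymmetric/monotone (0) tuning curves. With y' the adjacent-bin
#' derivative of the binned curve:
#' TSI = 1 - |sum y'| / sum |y'| if the summed derivative above zero exceeds
#' that below zero, else -1 + |sum y'| / sum |y'|. Invariant to adding a
#' constant to the curve and to positive rescaling.
#'
#' @param y binned tuning-curve values (typically 20 bins spanning the
#'   central 99% of projection values; see \code{\link{tuningCurve}}).
#' @param x bin centers (default: symmetric unit grid).
#' @return TSI in [-1, 1]; NA for a flat curve (no derivative mass). Bins
#'   with NA y (unoccupied) are dropped.
#' @export
tuningSymmetryIndex <- function(y, x = seq(-1, 1, length.out = length(y))) {
  ok <- !is.na(y)
  y <- y[ok]; x <- x[ok]
  stopifnotMsg(length(y) >= 3L, "need at least 3 occupied bins")
  dy <- diff(y)
  xm <- (head(x, -1) + tail(x, -1)) / 2            # derivative positions
  tot <- sum(abs(dy))
  if (tot == 0) return(NA_real_)
  ratio <- abs(sum(dy)) / tot
  above <- sum(dy[xm >= 0]); below <- sum(dy[xm < 0])
  if (above - below > 0) 1 - ratio else -1 + ratio
}

#' Marginal tuning curve for symmetry analysis
#'
#' Bins one projection dimension into \code{nBins} bins spanning the central
#' \code{span} quantile range and averages the rate per bin.
#'
#' @param x projection values (one dimension).
#' @param rate rate series, same length.
#' @param nBins number of bins (default 20).
#' @param span central quantile span (default 0.99).
#' @param minOccupancy minimum samples per bin.
#' @return list with \code{centers} and \code{y} (NA for unoccupied bins).
#' @export
tuningCurve <- function(x, rate, nBins = 20L, span = 0.99, minOccupancy = 5L) {
  q <- quantile(x, c((1 - span) / 2, 1 - (1 - span) / 2), names = FALSE)
  edges <- seq(q[1], q[2], length.out = nBins + 1L)
  i <- findInterval(x, edges, rightmost.closed = TRUE)
  i[i < 1L | i > nBins] <- NA_integer_
  occ <- tabulate(i, nBins)
  y <- rep(NA_real_, nBins)
  ok <- !is.na(i)
  sums <- tapply(rate[ok], i[ok], sum)
  y[as.integer(names(sums))] <- sums / occ[as.integer(names(sums))]
  y[occ < minOccupancy] <- NA_real_
  list(centers = (head(edges, -1) + tail(edges, -1)) / 2, y = y,
       occupancy = occ)
}

#' Modulation power spectrum of a spectro-temporal filter
#'
#' Squared magnitude of the 2-D Fourier transform over (log-frequency, lag),
#' with axes in physical units: temporal modulation in Hz and spectral
#' modulation in cycles/octave. Quadrants are centered (zero modulation in
#' the middle). Total power equals the filter's sum of squares divided by
#' the number of elements (Parseval with the 1/(F*U) convention).
#'
#' @param filt F x U filter matrix.
#' @param frameRate temporal sampling rate, Hz.
#' @param octavesPerChannel spectral axis step, octaves.
#' @return list with \code{power} (F x U centered power map),
#'   \code{temporalHz}, \code{spectralCycPerOct} (axis values).
#' @export
modulationPowerSpectrum <- function(filt, frameRate = 100,
                                    octavesPerChannel = 1 / 6) {
  stopifnotMsg(all(is.finite(filt)), "non-finite filter")
  Fd <- nrow(filt); U <- ncol(filt)
  P <- Mod(fft(filt))^2 / (Fd * U)
  shift <- function(n) {
    h <- floor(n / 2)
    c((h + 1):n, 1:h)
  }
  P <- P[shift(Fd), shift(U)]
  fftfreq <- function(n, d) {
    k <- c(seq(0, floor(n / 2) - 1 + n %% 2), seq(-floor(n / 2), -1)) / (n * d)
    k[shift(n)]
  }
  list(power = P,
       spectralCycPerOct = fftfreq(Fd, octavesPerChannel),
       temporalHz = fftfreq(U, 1 / frameRate))
}

#' Group-average modulation power spectra
#' @param filtList list of F x U filters.
#' @param ... passed to \code{\link{modulationPowerSpectrum}}.
#' @return averaged MPS list (same structure).
#' @export
averageMPS <- function(filtList, ...) {
  mps <- lapply(filtList, modulationPowerSpectrum, ...)
  out <- mps[[1]]
  out$power <- Reduce(`+`, lapply(mps, `[[`, "power")) / length(mps)
  out
}

#' Response field of a neuron in a shared tuning surface
#'
#' Grid mask over a site-level 2-D tuning surface marking bins where the
#' neuron's mean rate exceeds \code{frac} of its maximum (over occupied
#' bins).
#'
#' @param surface a \linkS4class{TuningSurface} (2-D).
#' @param frac threshold fraction of the maximum rate (default 0.8).
#' @return logical matrix mask (FALSE on unoccupied bins).
#' @export
responseField <- function(surface, frac = 0.8) {
  mr <- surface@meanRate
  stopifnotMsg(is.matrix(mr), "2-D tuning surface required")
  mx <- max(mr, na.rm = TRUE)
  mask <- !is.na(mr) & mr > frac * mx
  mask
}

#' Response-field tiling and overlap with shuffle control
#'
#' Counts, for every grid cell, how many neurons' response fields cover it;
#' reports the maximum overlap and its fraction of the unit count. The
#' chance level is estimated by shuffling each field with a seeded random
#' toroidal translation (preserving its shape and area) \code{nShuffles}
#' times.
#'
#' @param fields list of logical masks on one common grid.
#' @param nShuffles number of shuffles (default 100).
#' @param seed seed for the shuffle translations.
#' @return list with \code{maxOverlap}, \code{fractionMaxOverlap},
#'   \code{shuffledMaxOverlap} (vector of length nShuffles) and
#'   \code{overlapMap}.
#' @export
tilingOverlap <- function(fields, nShuffles = 100L, seed = 1L) {
  if (!length(fields)) stop("empty field list")
  dims <- dim(fields[[1]])
  stopifnotMsg(all(vapply(fields, function(f) identical(dim(f), dims), TRUE)),
               "fields must share one grid")
  overlap <- Reduce(`+`, lapply(fields, function(f) f * 1))
  maxOv <- max(overlap)
  tor <- function(mask, dr, dc) {
    nr <- nrow(mask); nc <- ncol(mask)
    mask[((seq_len(nr) - 1 - dr) %% nr) + 1, ((seq_len(nc) - 1 - dc) %% nc) + 1]
  }
  shuffled <- withSeed(substreamSeed(seed, "tiling-shuffle"), {
    vapply(seq_len(nShuffles), function(i) {
      sh <- lapply(fields, function(f)
        tor(f, sample.int(dims[1], 1) - 1L, sample.int(dims[2], 1) - 1L))
      max(Reduce(`+`, lapply(sh, function(f) f * 1)))
    }, 0)
  })
  list(maxOverlap = maxOv,
       fractionMaxOverlap = maxOv / length(fields),
       shuffledMaxOverlap = shuffled,
       overlapMap = overlap)
}

#' Classify a unit by spike width
#'
#' Narrow-spiking (putative inhibitory) if the peak-to-trough width is
#' strictly below the threshold, regular-spiking otherwise (a width exactly
#' at threshold is regular). Thresholds of 0.35 ms and 0.375 ms suit the two
#' probe types whose filtering differs.
#'
#' @param width spike peak-to-trough width, ms.
#' @param threshold classification threshold, ms (default 0.35).
#' @return "narrow" or "regular" (vectorized).
#' @export
classifySpikeWidth <- function(width, threshold = 0.35) {
  stopifnotMsg(all(width > 0), "spike width must be positive")
  ifelse(width < threshold, "narrow", "regular")
}
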