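## Ground-truth stimuli and neural populations with known subspaces, for
## validating every pipeline stage by parameter recovery.

#' Gabor ripple spectro-temporal filter
#'
#' A Gaussian-windowed ripple on the (channel, lag) grid:
#' cos(2*pi*(wf*f + wt*u) + phase) under a Gaussian envelope. The workhorse
#' for constructing ground-truth filters; a 90-degree phase shift gives the
#' quadrature partner.
#'
#' @param F,U grid size (channels x lags).
#' @param f0,u0 envelope center (bins).
#' @param wf,wt spectral / temporal modulation (cycles per bin).
#' @param phase carrier phase, radians.
#' @param sigmaF,sigmaU envelope widths (bins).
#' @return F x U matrix, unit Frobenius norm.
#' @export
gaborFilter <- function(F = 32L, U = 25L, f0 = F / 2, u0 = 8, wf = 0.08,
                        wt = 0.12, phase = 0, sigmaF = 4, sigmaU = 4) {
  f <- matrix(seq_len(F), F, U)
  u <- matrix(seq_len(U), F, U, byrow = TRUE)
  env <- exp(-((f - f0)^2 / (2 * sigmaF^2) + (u - u0)^2 / (2 * sigmaU^2)))
  g <- env * cos(2 * pi * (wf * f + wt * u) + phase)
  g / vecnorm(g)
}

#' Quadrature pair of Gabor filters
#' @inheritParams gaborFilter
#' @return list of two unit-norm F x U filters 90 degrees apart in carrier
#'   phase.
#' @export
quadraturePair <- function(F = 32L, U = 25L, f0 = F / 2, u0 = 8, wf = 0.08,
                           wt = 0.12, phase = 0, sigmaF = 4, sigmaU = 4) {
  list(gaborFilter(F, U, f0, u0, wf, wt, phase, sigmaF, sigmaU),
       gaborFilter(F, U, f0, u0, wf, wt, phase + pi / 2, sigmaF, sigmaU))
}

#' Construct a ground-truth neuron
#'
#' @param kind "linear", "energy", "gain_control" or "and_gate".
#' @param filterList list of F x U true filters (1 for linear, 2 otherwise;
#'   energy neurons should hold a quadrature pair). Filters are normalized
#'   to unit norm.
#' @param beta suppression strength for gain control (default 4, in units of
#'   standardized projection).
#' @param outNL single-neuron \linkS4class{DoubleExpParams}.
#' @param rateScale peak rate, spikes/s.
#' @return a \linkS4class{GroundTruthNeuron}.
#' @export
groundTruthNeuron <- function(kind, filterList, beta = 4,
                              outNL = doubleExpParams(b = 0, a = 1, s = 0.5, k = 2),
                              rateScale = 50) {
  Fd <- nrow(filterList[[1]]); U <- ncol(filterList[[1]])
  G <- vapply(filterList, function(g) as.vector(g) / vecnorm(g),
              numeric(Fd * U))
  new("GroundTruthNeuron", kind = kind, filters = G, beta = beta,
      outNL = outNL, rateScale = rateScale, F = as.integer(Fd),
      U = as.integer(U))
}

#' Default synthetic population: two neurons of each kind
#'
#' Eight neurons (2 linear, 2 energy, 2 gain-control, 2 and-gate) with
#' seeded random Gabor tuning spread over the spectrogram.
#'
#' @param F,U filter grid.
#' @param seed integer seed.
#' @return list of \linkS4class{GroundTruthNeuron}.
#' @export
defaultPopulation <- function(F = 32L, U = 25L, seed = 1L) {
  withSeed(substreamSeed(seed, "population"), {
    mk <- function(kind) {
      f0 <- runif(1, F * 0.3, F * 0.7)
      u0 <- runif(1, 5, 10)
      wf <- runif(1, 0.05, 0.12)
      wt <- runif(1, 0.08, 0.16)
      qp <- quadraturePair(F, U, f0, u0, wf, wt)
      if (kind == "linear") groundTruthNeuron(kind, qp[1])
      else groundTruthNeuron(kind, qp)
    }
    lapply(rep(c("linear", "energy", "gain_control", "and_gate"), each = 2), mk)
  })
}

#' Generate a synthetic spectrogram stimulus
#'
#' Kinds: "smoothed_noise" (Gaussian noise smoothed over channels and
#' frames), "ripple_mixture" (sum of drifting spectro-temporal ripples) and
#' "segment_sequence" (concatenated blocks of heterogeneous smoothed-noise
#' statistics with per-block level roving, mimicking the natural-segment
#' sequence design).
#'
#' @param kind stimulus kind.
#' @param T number of frames.
#' @param F number of channels.
#' @param params kind-specific parameters: smoothed_noise takes
#'   \code{sigmaF}, \code{sigmaT} (smoothing widths, bins); ripple_mixture
#'   takes \code{ripples} (data.frame wtHz, wfCycPerOct, amp, phase) and
#'   \code{depth}; segment_sequence takes \code{blockLen} (frames) and
#'   \code{roveDb}.
#' @param frameRate frames per second.
#' @param octavesPerChannel spectral axis step used by ripple frequencies.
#' @param seed integer seed (identical seed, identical stimulus).
#' @return a \linkS4class{Spectrogram}.
#' @export
generateStimulus <- function(kind = c("smoothed_noise", "ripple_mixture",
                                      "segment_sequence"),
                             T = 12000L, F = 32L, params = list(),
                             frameRate = 100, octavesPerChannel = 1 / 6,
                             seed = 1L) {
  kind <- match.arg(kind)
  smooth1 <- function(x, w) {
    if (w <= 0) return(x)
    k <- exp(-0.5 * (seq(-3 * w, 3 * w) / w)^2)
    k <- k / sum(k)
    apply(x, 2, function(col) {
      n <- length(col)
      as.numeric(stats::filter(c(rev(col[seq_len(3 * w)]), col,
                                 rev(col[n - seq_len(3 * w) + 1])), k,
                               sides = 2))[3 * w + seq_len(n)]
    })
  }
  vals <- withSeed(substreamSeed(seed, paste0("stimulus-", kind)), {
    if (kind == "smoothed_noise") {
      p <- modifyList(list(sigmaF = 2L, sigmaT = 2L), params)
      v <- matrix(rnorm(F * T), F, T)
      v <- smooth1(v, p$sigmaF)              # over channels
      v <- t(smooth1(t(v), p$sigmaT))        # over frames
      v / sd(v)
    } else if (kind == "ripple_mixture") {
      p <- modifyList(list(
        ripples = data.frame(wtHz = c(4, 12), wfCycPerOct = c(0.5, 1.2),
                             amp = c(1, 0.7), phase = c(0, 1)),
        depth = 1), params)
      f <- matrix(seq_len(F), F, T)
      tt <- matrix(seq_len(T), F, T, byrow = TRUE)
      v <- matrix(0, F, T)
      if (p$depth > 0) {
        for (i in seq_len(nrow(p$ripples))) {
          rp <- p$ripples[i, ]
          v <- v + p$depth * rp$amp *
            cos(2 * pi * (rp$wtHz * tt / frameRate +
                          rp$wfCycPerOct * f * octavesPerChannel) + rp$phase)
        }
      }
      v
    } else {
      p <- modifyList(list(blockLen = 100L, roveDb = 20), params)
      nb <- ceiling(T / p$blockLen)
      cols <- lapply(seq_len(nb), function(i) {
        sF <- sample(0:3, 1); sT <- sample(0:3, 1)
        v <- matrix(rnorm(F * p$blockLen), F, p$blockLen)
        if (sF > 0) v <- smooth1(v, sF)
        if (sT > 0) v <- t(smooth1(t(v), sT))
        v / sd(v) * dbToAmp(runif(1, -p$roveDb / 2, p$roveDb / 2))
      })
      do.call(cbind, cols)[, seq_len(T), drop = FALSE]
    }
  })
  spectrogram(vals, frameRate = frameRate,
              centerFreqs = 200 * 2^(seq(0, 6.64, length.out = F)))
}

## Standardized causal projections of a stimulus onto a neuron's filters.
## All of a neuron's filters share one scale (the root-mean variance across
## filters): a common scale keeps quadrature pairs circular, so energy
## neurons stay phase invariant.
.truthProjections <- function(neuron, S) {
  X <- lagStack(t(S), neuron@U) %*% neuron@filters   # T x k
  sc <- sqrt(mean(apply(X, 2, function(v) mean((v - mean(v))^2))))
  if (sc == 0) sc <- 1
  X / sc
}

#' True rate of a ground-truth neuron
#' @param neuron a \linkS4class{GroundTruthNeuron}.
#' @param s a \linkS4class{Spectrogram} (or F x T matrix).
#' @return rate series, spikes/s.
#' @export
trueRate <- function(neuron, s) {
  S <- if (is(s, "Spectrogram")) specValues(s) else s
  X <- .truthProjections(neuron, S)
  g <- function(v) doubleExponential(v, neuron@outNL)
  r <- switch(neuron@kind,
    linear = g(X[, 1]),
    energy = g(sqrt(X[, 1]^2 + X[, 2]^2)),
    gain_control = g(X[, 1]) * exp(-neuron@beta * X[, 2]^2),
    and_gate = g(pmin(X[, 1], X[, 2])))
  neuron@rateScale * r
}

#' Simulate a population response with Poisson trial noise
#'
#' Evaluates each neuron's combination rule on the stimulus projections
#' (standardized to unit variance over the stimulus) and draws
#' spike-count rasters as Poisson(rate / frameRate) per 10-ms bin and trial.
#'
#' @param neurons list of \linkS4class{GroundTruthNeuron}.
#' @param s a \linkS4class{Spectrogram}.
#' @param nTrials trials per neuron (default 10).
#' @param seed integer seed; regeneration is bit-identical.
#' @return a \linkS4class{SyntheticDataset}.
#' @export
simulatePopulation <- function(neurons, s, nTrials = 10L, seed = 1L) {
  stopifnotMsg(all(vapply(neurons, function(n) n@rateScale, 0) >= 0),
               "negative rate scale")
  S <- specValues(s)
  T <- ncol(S); N <- length(neurons)
  rateM <- t(vapply(neurons, trueRate, numeric(T), s = s))
  fr <- frameRate(s)
  rasters <- withSeed(substreamSeed(seed, "poisson"), {
    lapply(seq_len(N), function(i)
      matrix(rpois(nTrials * T, rep(rateM[i, ] / fr, each = nTrials)),
             nTrials, T))
  })
  psth <- t(vapply(rasters, function(r) colMeans(r) * fr, numeric(T)))
  meta <- data.frame(id = seq_len(N),
                     kind = vapply(neurons, function(n) n@kind, ""))
  resp <- responseSet(psth, frameRate = fr, rasters = rasters, meta = meta)
  new("SyntheticDataset", stimulus = s, neurons = neurons, responses = resp,
      trueRates = rateM, seed = as.integer(seed))
}

#' Principal angles between true and recovered subspaces
#'
#' @param trueFilters (F*U) x k matrix (or list of F x U matrices) spanning
#'   the ground-truth subspace.
#' @param recovered a \linkS4class{TuningSubspace} or basis matrix.
#' @return ascending principal angles in degrees.
#' @export
subspaceRecoveryError <- function(trueFilters, recovered) {
  A <- if (is.list(trueFilters))
    vapply(trueFilters, as.vector, numeric(length(trueFilters[[1]])))
  else trueFilters
  B <- if (is(recovered, "TuningSubspace")) filters(recovered) else recovered
  principalAngles(A, B)
}
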