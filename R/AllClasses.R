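#' Gammatone frontend parameters
#'
#' Parameters of the cochlea-like spectrogram frontend: a bank of
#' \code{nChannels} gammatone filters with log-spaced center frequencies
#' between \code{fLow} and \code{fHigh}, whose rectified envelopes are
#' frame-averaged to \code{frameRate} and log-compressed with an additive
#' floor (\code{log(x + logFloor)}) so digital silence stays finite.
#'
#' @slot nChannels number of filterbank channels (F).
#' @slot fLow,fHigh lowest/highest center frequency in Hz.
#' @slot frameRate output frame rate in Hz (10-ms frames at the default 100).
#' @slot gammatoneOrder order of the gammatone magnitude response; the filter
#'   is realized as this many cascaded second-order (one complex pole)
#'   sections.
#' @slot logFloor additive offset inside the log compression, in units of
#'   full-scale envelope amplitude.
#' @slot erbCoef coefficients (a, b) of the equivalent rectangular bandwidth
#'   law ERB(f) = a*(b*f/1000 + 1) Hz. Default is the standard human formula
#'   (24.7, 4.37); species-specific laws can be substituted.
#' @exportClass FrontendParams
setClass("FrontendParams", representation(
  nChannels = "integer", fLow = "numeric", fHigh = "numeric",
  frameRate = "numeric", gammatoneOrder = "integer",
  logFloor = "numeric", erbCoef = "numeric"),
  prototype(nChannels = 32L, fLow = 200, fHigh = 20000, frameRate = 100,
            gammatoneOrder = 2L, logFloor = 1e-4, erbCoef = c(24.7, 4.37)))

setValidity("FrontendParams", function(object) {
  msg <- character()
  if (object@fLow >= object@fHigh) msg <- c(msg, "fLow must be < fHigh")
  if (object@nChannels < 2L) msg <- c(msg, "need at least 2 channels")
  if (object@frameRate <= 0) msg <- c(msg, "frameRate must be positive")
  if (object@logFloor <= 0) msg <- c(msg, "logFloor must be positive")
  if (length(msg)) msg else TRUE
})

#' Constructor for FrontendParams
#' @param nChannels,fLow,fHigh,frameRate,gammatoneOrder,logFloor,erbCoef see
#'   the class documentation.
#' @return a \linkS4class{FrontendParams} object.
#' @export
frontendParams <- function(nChannels = 32L, fLow = 200, fHigh = 20000,
                           frameRate = 100, gammatoneOrder = 2L,
                           logFloor = 1e-4, erbCoef = c(24.7, 4.37)) {
  new("FrontendParams", nChannels = as.integer(nChannels), fLow = fLow,
      fHigh = fHigh, frameRate = frameRate,
      gammatoneOrder = as.integer(gammatoneOrder), logFloor = logFloor,
      erbCoef = erbCoef)
}

#' Log-energy spectrogram
#'
#' F x T matrix of log-compressed gammatone channel energies, the model input
#' s(f, t). Rows are frequency channels (center frequencies in
#' \code{centerFreqs}), columns are 1/frameRate frames.
#'
#' @slot values F x T numeric matrix.
#' @slot frameRate frames per second.
#' @slot centerFreqs channel center frequencies, Hz, strictly increasing.
#' @exportClass Spectrogram
setClass("Spectrogram", representation(
  values = "matrix", frameRate = "numeric", centerFreqs = "numeric"))

setValidity("Spectrogram", function(object) {
  msg <- character()
  if (any(!is.finite(object@values))) msg <- c(msg, "non-finite spectrogram values")
  if (length(object@centerFreqs) != nrow(object@values))
    msg <- c(msg, "centerFreqs length must equal channel count")
  if (is.unsorted(object@centerFreqs, strictly = TRUE))
    msg <- c(msg, "centerFreqs must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' @param values,frameRate,centerFreqs slots; see \linkS4class{Spectrogram}.
#' @rdname Spectrogram-class
#' @export
spectrogram <- function(values, frameRate = 100,
                        centerFreqs = seq_len(nrow(values))) {
  new("Spectrogram", values = values, frameRate = frameRate,
      centerFreqs = as.numeric(centerFreqs))
}

setMethod("show", "Spectrogram", function(object) {
  cat(sprintf("Spectrogram: %d channels x %d frames @ %g Hz (%.2f s)\n",
              nrow(object@values), ncol(object@values), object@frameRate,
              ncol(object@values) / object@frameRate))
  cat(sprintf("  center freqs %.0f-%.0f Hz\n",
              min(object@centerFreqs), max(object@centerFreqs)))
})

#' Neural response set
#'
#' Per-neuron peristimulus time histograms (PSTHs, spikes/s) sampled at the
#' spectrogram frame rate, with optional single-trial spike-count rasters and
#' neuron metadata (depth, spike width).
#'
#' @slot rates N x T matrix of trial-averaged firing rate, spikes/s.
#' @slot frameRate sampling rate, Hz.
#' @slot rasters list of length N; each element a trials x T count matrix or
#'   NULL when rasters were not recorded.
#' @slot meta data.frame with one row per neuron (columns such as id, depth,
#'   spikeWidth are free-form).
#' @exportClass ResponseSet
setClass("ResponseSet", representation(
  rates = "matrix", frameRate = "numeric", rasters = "list", meta = "data.frame"))

setValidity("ResponseSet", function(object) {
  msg <- character()
  if (length(object@rasters) && length(object@rasters) != nrow(object@rates))
    msg <- c(msg, "rasters list length must equal neuron count")
  if (nrow(object@meta) && nrow(object@meta) != nrow(object@rates))
    msg <- c(msg, "meta rows must equal neuron count")
  if (length(msg)) msg else TRUE
})

#' @param rates,frameRate,rasters,meta slots; see \linkS4class{ResponseSet}.
#' @rdname ResponseSet-class
#' @export
responseSet <- function(rates, frameRate = 100, rasters = list(),
                        meta = data.frame()) {
  new("ResponseSet", rates = rates, frameRate = frameRate,
      rasters = rasters, meta = meta)
}

setMethod("show", "ResponseSet", function(object) {
  cat(sprintf("ResponseSet: %d neurons x %d frames @ %g Hz; rasters for %d neurons\n",
              nrow(object@rates), ncol(object@rates), object@frameRate,
              sum(!vapply(object@rasters, is.null, logical(1)))))
})

#' Double-exponential output nonlinearity parameters
#'
#' Per-neuron parameters of the sigmoid output nonlinearity
#' r = b + a*exp(-exp(-k*(x - s))): baseline rate b, response amplitude a,
#' threshold location s and gain k. With k > 0 the curve rises from b to
#' b + a (Gompertz form).
#'
#' @slot b,a,s,k numeric vectors, one entry per neuron.
#' @exportClass DoubleExpParams
setClass("DoubleExpParams", representation(
  b = "numeric", a = "numeric", s = "numeric", k = "numeric"))

setValidity("DoubleExpParams", function(object) {
  n <- length(object@b)
  if (length(object@a) != n || length(object@s) != n || length(object@k) != n)
    return("b, a, s, k must have equal length")
  if (any(object@a < 0)) return("amplitude a must be non-negative")
  if (any(!is.finite(object@k))) return("gain k must be finite")
  TRUE
})

#' @param b,a,s,k parameter vectors (recycled to a common length).
#' @rdname DoubleExpParams-class
#' @export
doubleExpParams <- function(b = 0, a = 1, s = 0, k = 1) {
  n <- max(length(b), length(a), length(s), length(k))
  new("DoubleExpParams", b = rep_len(b, n), a = rep_len(a, n),
      s = rep_len(s, n), k = rep_len(k, n))
}

#' Virtual parent of all encoding-model families
#'
#' @slot outNL per-neuron output nonlinearity.
#' @slot norm normalization affine maps stored by fitting (empty until fit).
#' @slot identityOut if TRUE the output nonlinearity is bypassed (an identity
#'   output stage), giving a purely linear model for analysis.
#' @exportClass EncodingModel
setClass("EncodingModel", representation("VIRTUAL",
  outNL = "DoubleExpParams", norm = "list", identityOut = "logical"),
  prototype(identityOut = FALSE))

#' Population linear-nonlinear (LN) model
#'
#' A bank of M rank-1 spectro-temporal FIR filters shared across neurons
#' (each filter the outer product of a spectral and a temporal profile),
#' per-neuron linear readout weights over the filter bank, and a per-neuron
#' double-exponential output nonlinearity.
#'
#' @slot spectral F x M matrix of spectral profiles.
#' @slot temporal U x M matrix of temporal profiles (lag 0..U-1).
#' @slot weights M x N readout weight matrix.
#' @slot outNL per-neuron \linkS4class{DoubleExpParams}.
#' @slot norm input/output min-max normalization maps (set by fitting).
#' @exportClass LNModel
setClass("LNModel", contains = "EncodingModel", representation(
  spectral = "matrix", temporal = "matrix", weights = "matrix"))

setValidity("LNModel", function(object) {
  M <- ncol(object@spectral)
  if (ncol(object@temporal) != M) return("spectral/temporal filter counts differ")
  if (nrow(object@weights) != M) return("weights rows must equal filter count M")
  TRUE
})

setMethod("show", "LNModel", function(object) {
  cat(sprintf("LNModel: %d rank-1 filters (%d channels x %d lags) -> %d neurons\n",
              ncol(object@spectral), nrow(object@spectral),
              nrow(object@temporal), ncol(object@weights)))
})

#' Population convolutional network encoding model
#'
#' Causal architecture: conv layer 1 (C1 filters over F input channels x K1
#' time taps), ReLU, conv layer 2 (C2 filters over C1 x K2), ReLU, dense
#' C2 x D3, ReLU, dense D3 x N, then a per-neuron double-exponential output
#' nonlinearity. Convolutions are causal via zero left-padding, so output at
#' frame t never depends on frames after t. Weight matrices act on lag-stacked
#' inputs: W1 is (F*K1) x C1 with lag-major blocks, W2 is (C1*K2) x C2.
#'
#' @slot W1,b1 conv layer 1 weights/biases.
#' @slot W2,b2 conv layer 2 weights/biases.
#' @slot W3,b3 first dense layer.
#' @slot W4,b4 per-neuron readout layer.
#' @slot dims named integer vector (F, K1, C1, K2, C2, D3, N).
#' @exportClass PopulationCNN
setClass("PopulationCNN", contains = "EncodingModel", representation(
  W1 = "matrix", b1 = "numeric", W2 = "matrix", b2 = "numeric",
  W3 = "matrix", b3 = "numeric", W4 = "matrix", b4 = "numeric",
  dims = "integer"))

setValidity("PopulationCNN", function(object) {
  d <- object@dims
  need <- c("F", "K1", "C1", "K2", "C2", "D3", "N")
  if (!all(need %in% names(d))) return("dims must name F, K1, C1, K2, C2, D3, N")
  if (!all(dim(object@W1) == c(d["F"] * d["K1"], d["C1"]))) return("W1 shape")
  if (!all(dim(object@W2) == c(d["C1"] * d["K2"], d["C2"]))) return("W2 shape")
  if (!all(dim(object@W3) == c(d["C2"], d["D3"]))) return("W3 shape")
  if (!all(dim(object@W4) == c(d["D3"], d["N"]))) return("W4 shape")
  TRUE
})

setMethod("show", "PopulationCNN", function(object) {
  d <- object@dims
  cat(sprintf("PopulationCNN: conv %dx%d(%d) -> conv %dx%d(%d) -> dense %d -> %d neurons\n",
              d["F"], d["K1"], d["C1"], d["C1"], d["K2"], d["C2"], d["D3"], d["N"]))
})

#' Dense subspace readout model
#'
#' Two-layer ReLU network from subspace projections x_1..x_N to one neuron's
#' firing rate, with a double-exponential output nonlinearity. This is the
#' compact model refit after the stimulus is projected into a neuron's tuning
#' subspace; it can express arbitrary nonlinear interactions within the
#' subspace but no tuning outside it.
#'
#' @slot W1,b1,W2,b2,W3,b3 layer parameters (input width = subspace dim).
#' @exportClass SubspaceReadout
setClass("SubspaceReadout", contains = "EncodingModel", representation(
  W1 = "matrix", b1 = "numeric", W2 = "matrix", b2 = "numeric",
  W3 = "matrix", b3 = "numeric"))

setMethod("show", "SubspaceReadout", function(object) {
  cat(sprintf("SubspaceReadout: %d -> %d -> %d -> 1 (+ double-exp)\n",
              nrow(object@W1), ncol(object@W1), ncol(object@W2)))
})

#' Polynomial subspace readout
#'
#' First- or second-order polynomial map from subspace projections to rate:
#' r(t) = sum_ij w_ij x_i x_j + sum_i v_i x_i + r0, with symmetric w. Order 1
#' constrains all w_ij to zero, reproducing the LN model within the subspace.
#'
#' @slot order 1 or 2.
#' @slot W symmetric second-order coefficient matrix (all-zero when order 1).
#' @slot v linear coefficients.
#' @slot r0 intercept.
#' @slot outNL optional double-exponential output stage applied to the
#'   polynomial value when \code{useOutNL} is TRUE; fitted readouts carry it
#'   so that the order-1 variant reproduces the LN model within the
#'   subspace (polynomial drive, shared spike-threshold output).
#' @slot useOutNL whether the output stage is applied (default FALSE: the
#'   readout is the pure polynomial).
#' @exportClass PolyReadout
setClass("PolyReadout", representation(
  order = "integer", W = "matrix", v = "numeric", r0 = "numeric",
  outNL = "DoubleExpParams", useOutNL = "logical"),
  prototype(outNL = new("DoubleExpParams", b = 0, a = 1, s = 0, k = 1),
            useOutNL = FALSE))

setValidity("PolyReadout", function(object) {
  if (!object@order %in% 1:2) return("order must be 1 or 2")
  if (object@order == 1L && any(object@W != 0)) return("order-1 readout must have zero W")
  if (max(abs(object@W - t(object@W))) > 1e-10) return("W must be symmetric")
  if (nrow(object@W) != length(object@v)) return("W/v dimension mismatch")
  TRUE
})

#' @param order,W,v,r0 slots; see \linkS4class{PolyReadout}.
#' @rdname PolyReadout-class
#' @export
polyReadout <- function(order, v, W = matrix(0, length(v), length(v)), r0 = 0) {
  new("PolyReadout", order = as.integer(order), W = (W + t(W)) / 2,
      v = v, r0 = r0)
}

#' Jackknife ensemble of fitted models
#'
#' One fitted model per jackknife fold, each trained with a distinct
#' contiguous 1/n_folds share of the fit timepoints excluded; the excluded
#' share doubles as the fold's internal validation set for early stopping and
#' best-of-inits selection.
#'
#' @slot members list of fitted \linkS4class{EncodingModel}s.
#' @slot foldMasks list of integer vectors: timepoints excluded per fold.
#' @slot diagnostics per-member data.frame (fold, init, loss, epochs).
#' @slot cfg the \code{fitConfig} list used.
#' @exportClass JackknifeEnsemble
setClass("JackknifeEnsemble", representation(
  members = "list", foldMasks = "list", diagnostics = "data.frame", cfg = "list"))

setValidity("JackknifeEnsemble", function(object) {
  if (length(object@members) != length(object@foldMasks))
    return("one fold mask per member required")
  all_idx <- sort(unlist(object@foldMasks))
  if (any(duplicated(all_idx))) return("fold masks must be disjoint")
  TRUE
})

setMethod("show", "JackknifeEnsemble", function(object) {
  cat(sprintf("JackknifeEnsemble: %d members (%s)\n", length(object@members),
              class(object@members[[1]])))
})

#' Dynamic STRF stack
#'
#' The locally linear filters d_t(f, u) of one neuron: at each evaluated
#' stimulus timepoint, the derivative of the model's predicted rate with
#' respect to the spectrogram at lags u = 0..U-1.
#'
#' @slot filters T_sel x F x U array.
#' @slot times evaluated frame indices (1-based).
#' @slot maxLag U, frames.
#' @slot stride timepoint subsampling stride used.
#' @slot modelId free-form identifier of the source model.
#' @exportClass DSTRFStack
setClass("DSTRFStack", representation(
  filters = "array", times = "integer", maxLag = "integer",
  stride = "integer", modelId = "character"))

setValidity("DSTRFStack", function(object) {
  d <- dim(object@filters)
  if (length(d) != 3L) return("filters must be T x F x U")
  if (d[1] != length(object@times)) return("times length mismatch")
  if (d[3] != object@maxLag) return("third dim must equal maxLag")
  if (any(!is.finite(object@filters))) return("non-finite dSTRF entries")
  TRUE
})

setMethod("show", "DSTRFStack", function(object) {
  d <- dim(object@filters)
  cat(sprintf("DSTRFStack: %d timepoints, %d channels x %d lags (stride %d)\n",
              d[1], d[2], d[3], object@stride))
})

#' Tuning subspace
#'
#' Ordered orthonormal spectro-temporal filters g_j(f, u) spanning the
#' principal subspace of a neuron's dSTRF collection, with the cumulative
#' explained-variance curve. N is the smallest component count whose
#' cumulative variance reaches \code{varThreshold}.
#'
#' @slot filters (F*U) x N matrix, columns orthonormal flattened filters.
#' @slot explainedVariance cumulative variance fraction for components
#'   1..min(T, F*U) (monotone nondecreasing, last entry 1).
#' @slot varThreshold variance threshold used to choose N.
#' @slot F,U filter grid dimensions.
#' @slot id neuron id, or "site" for pooled subspaces.
#' @exportClass TuningSubspace
setClass("TuningSubspace", representation(
  filters = "matrix", explainedVariance = "numeric", varThreshold = "numeric",
  F = "integer", U = "integer", id = "character"))

setValidity("TuningSubspace", function(object) {
  if (nrow(object@filters) != object@F * object@U)
    return("filters rows must equal F*U")
  G <- crossprod(object@filters)
  if (max(abs(G - diag(ncol(object@filters)))) > 1e-6)
    return("filters must be orthonormal")
  ev <- object@explainedVariance
  if (any(diff(ev) < -1e-12)) return("explainedVariance must be nondecreasing")
  TRUE
})

setMethod("show", "TuningSubspace", function(object) {
  cat(sprintf("TuningSubspace '%s': %d filters (%d x %d), %.1f%% dSTRF variance at N\n",
              object@id, ncol(object@filters), object@F, object@U,
              100 * object@explainedVariance[ncol(object@filters)]))
})

#' Subspace projection of a stimulus
#'
#' x_j(t) = sum_f sum_u g_j(f,u) s(f, t-u): the stimulus convolved with each
#' subspace filter (causal, zero left-padded).
#'
#' @slot x N x T projection matrix.
#' @slot subspaceId,stimulusId provenance identifiers.
#' @exportClass SubspaceProjection
setClass("SubspaceProjection", representation(
  x = "matrix", subspaceId = "character", stimulusId = "character"))

#' Tuning surface / marginal tuning curve
#'
#' Mean firing rate binned over projections onto one subspace dimension
#' (marginal curve) or a pair of dimensions (surface). Bins with fewer than
#' \code{minOccupancy} samples are flagged empty (NA mean rate) and excluded
#' from downstream maxima.
#'
#' @slot dims the subspace dimension(s) used (length 1 or 2).
#' @slot edges list of bin-edge vectors, one per dim.
#' @slot meanRate vector (1-D) or matrix (2-D) of per-bin mean rate, NA where
#'   unoccupied.
#' @slot occupancy per-bin sample counts (same shape as meanRate).
#' @slot minOccupancy occupancy threshold used.
#' @exportClass TuningSurface
setClass("TuningSurface", representation(
  dims = "integer", edges = "list", meanRate = "ANY", occupancy = "ANY",
  minOccupancy = "integer"))

#' Ground-truth simulated neuron
#'
#' A neuron with known tuning subspace and combination rule, for pipeline
#' validation by parameter recovery. Kinds: "linear" (r = g(x1)),
#' "energy" (r = g(sqrt(x1^2 + x2^2)), quadrature pair), "gain_control"
#' (r = g(x1) * exp(-beta x2^2)) and "and_gate" (r = g(min(x1, x2))),
#' where g is the double-exponential nonlinearity.
#'
#' @slot kind one of linear, energy, gain_control, and_gate.
#' @slot filters (F*U) x k matrix of unit-norm true filters (k = 1 or 2).
#' @slot beta suppression strength (gain_control only).
#' @slot outNL single-neuron \linkS4class{DoubleExpParams}.
#' @slot rateScale peak firing rate scale, spikes/s.
#' @slot F,U filter grid dimensions.
#' @exportClass GroundTruthNeuron
setClass("GroundTruthNeuron", representation(
  kind = "character", filters = "matrix", beta = "numeric",
  outNL = "DoubleExpParams", rateScale = "numeric", F = "integer", U = "integer"))

setValidity("GroundTruthNeuron", function(object) {
  if (!object@kind %in% c("linear", "energy", "gain_control", "and_gate"))
    return("unknown neuron kind")
  k <- ncol(object@filters)
  if (object@kind == "linear" && k < 1L) return("linear neuron needs 1 filter")
  if (object@kind != "linear" && k < 2L) return("two filters required")
  nrm <- sqrt(colSums(object@filters^2))
  if (any(abs(nrm - 1) > 1e-8)) return("true filters must be unit norm")
  if (object@rateScale < 0) return("rateScale must be non-negative")
  TRUE
})

#' Synthetic dataset with known ground truth
#'
#' @slot stimulus \linkS4class{Spectrogram}.
#' @slot neurons list of \linkS4class{GroundTruthNeuron}.
#' @slot responses \linkS4class{ResponseSet} built from the true rates plus
#'   Poisson trial noise.
#' @slot trueRates N x T noiseless rates, spikes/s.
#' @slot seed generator seed (regeneration is bit-identical).
#' @exportClass SyntheticDataset
setClass("SyntheticDataset", representation(
  stimulus = "Spectrogram", neurons = "list", responses = "ResponseSet",
  trueRates = "matrix", seed = "integer"))

setMethod("show", "SyntheticDataset", function(object) {
  cat(sprintf("SyntheticDataset: %d neurons (%s), %d frames, seed %d\n",
              length(object@neurons),
              paste(unique(vapply(object@neurons, function(n) n@kind, "")), collapse = "/"),
              ncol(object@trueRates), object@seed))
})
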