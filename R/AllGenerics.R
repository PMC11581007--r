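#' Predict firing rates from a fitted encoding model
#'
#' Runs the model forward on a stimulus and returns predicted rates. When the
#' model carries normalization maps from fitting, the stimulus is normalized
#' with the stored (fit-derived) maps and predictions are returned on the
#' original rate scale.
#'
#' @param model an \linkS4class{EncodingModel}.
#' @param stim a \linkS4class{Spectrogram} (or, for
#'   \linkS4class{SubspaceReadout}, an N x T projection matrix or
#'   \linkS4class{SubspaceProjection}).
#' @param ... method-specific arguments.
#' @return N x T matrix of predicted rates.
#' @export
setGeneric("predictRate", function(model, stim, ...) standardGeneric("predictRate"))

#' Pre-nonlinearity (linear-stage) response of an encoding model
#' @inheritParams predictRate
#' @return N x T matrix of inputs to the output nonlinearity.
#' @export
setGeneric("linearResponse", function(model, stim, ...) standardGeneric("linearResponse"))

#' Dynamic STRF by exact differentiation
#'
#' Computes the locally linear filter approximating the model at each
#' requested stimulus timepoint: d_t(f, u) = d r(t) / d s(f, t-u) for lags
#' u = 0..maxLag-1, evaluated at the actual stimulus (the Jacobian of the
#' model output with respect to its input).
#'
#' @param model a differentiable \linkS4class{EncodingModel}.
#' @param stim a \linkS4class{Spectrogram}.
#' @param neuron neuron index.
#' @param times frame indices to evaluate (default: all, subject to
#'   \code{stride}).
#' @param maxLag maximum lag U in frames (default 25, i.e. 250 ms at 100 Hz).
#' @param stride timepoint subsampling stride.
#' @param ... method-specific arguments.
#' @return a \linkS4class{DSTRFStack}.
#' @export
setGeneric("jacobianDSTRF", function(model, stim, neuron, times = NULL,
                                     maxLag = 25L, stride = 1L, ...)
  standardGeneric("jacobianDSTRF"))

#' Number of neurons an encoding model predicts
#' @param model an \linkS4class{EncodingModel}.
#' @return integer neuron count.
#' @export
setGeneric("nNeurons", function(model) standardGeneric("nNeurons"))

#' Spectrogram values accessor
#' @param x a \linkS4class{Spectrogram}.
#' @return F x T matrix.
#' @export
setGeneric("specValues", function(x) standardGeneric("specValues"))
setMethod("specValues", "Spectrogram", function(x) x@values)

#' Frame-rate accessor
#' @param x a \linkS4class{Spectrogram} or \linkS4class{ResponseSet}.
#' @return frames per second.
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))
setMethod("frameRate", "Spectrogram", function(x) x@frameRate)
setMethod("frameRate", "ResponseSet", function(x) x@frameRate)

#' Center-frequency accessor
#' @param x a \linkS4class{Spectrogram}.
#' @return numeric vector of channel center frequencies (Hz).
#' @export
setGeneric("centerFreqs", function(x) standardGeneric("centerFreqs"))
setMethod("centerFreqs", "Spectrogram", function(x) x@centerFreqs)

#' PSTH accessor
#' @param x a \linkS4class{ResponseSet}.
#' @return N x T rate matrix (spikes/s).
#' @export
setGeneric("rates", function(x) standardGeneric("rates"))
setMethod("rates", "ResponseSet", function(x) x@rates)

#' Subspace filter accessor
#' @param x a \linkS4class{TuningSubspace} or \linkS4class{DSTRFStack}.
#' @param ... unused.
#' @return for a subspace, the (F*U) x N orthonormal filter matrix; for a
#'   dSTRF stack, the T x F x U array.
#' @export
setGeneric("filters", function(x, ...) standardGeneric("filters"))
setMethod("filters", "TuningSubspace", function(x, ...) x@filters)
setMethod("filters", "DSTRFStack", function(x, ...) x@filters)

#' Explained-variance curve accessor
#' @param x a \linkS4class{TuningSubspace}.
#' @return cumulative explained-variance fractions.
#' @export
setGeneric("explainedVariance", function(x) standardGeneric("explainedVariance"))
setMethod("explainedVariance", "TuningSubspace", function(x) x@explainedVariance)

#' Ensemble member accessor
#' @param x a \linkS4class{JackknifeEnsemble}.
#' @return list of fitted models (one per jackknife fold).
#' @export
setGeneric("members", function(x) standardGeneric("members"))
setMethod("members", "JackknifeEnsemble", function(x) x@members)

#' Fold-mask accessor
#' @param x a \linkS4class{JackknifeEnsemble}.
#' @return list of integer vectors of excluded timepoints per fold.
#' @export
setGeneric("foldMasks", function(x) standardGeneric("foldMasks"))
setMethod("foldMasks", "JackknifeEnsemble", function(x) x@foldMasks)

#' Projection matrix accessor
#' @param x a \linkS4class{SubspaceProjection}.
#' @return N x T matrix of projections.
#' @export
setGeneric("projections", function(x) standardGeneric("projections"))
setMethod("projections", "SubspaceProjection", function(x) x@x)
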