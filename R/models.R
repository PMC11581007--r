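## Forward computations of the encoding-model families.

#' Double-exponential output nonlinearity
#'
#' r = b + a * exp(-exp(-k * (x - s))): a smooth sigmoid mimicking spike
#' threshold and firing-rate saturation. With gain k > 0 the curve rises
#' monotonically from baseline b (x -> -Inf) to saturation b + a
#' (x -> +Inf); at x = s the output is b + a/e. The inner exponent is
#' clamped to avoid overflow; the clamp is far outside any fitted operating
#' range.
#'
#' @param x scalar, vector or matrix of linear-stage responses. For matrix
#'   input (T x N), parameter vectors apply per column (neuron).
#' @param p a \linkS4class{DoubleExpParams} (vectors recycled across neurons).
#' @param deriv if TRUE, also return the derivative dr/dx as attribute
#'   \code{"deriv"}.
#' @return rates, same shape as \code{x}.
#' @export
doubleExponential <- function(x, p, deriv = FALSE) {
  stopifnot(is(p, "DoubleExpParams"))
  if (is.matrix(x)) {
    N <- ncol(x)
    b <- rep_len(p@b, N); a <- rep_len(p@a, N)
    s <- rep_len(p@s, N); k <- rep_len(p@k, N)
    inner <- sweep(sweep(x, 2, s, "-"), 2, k, "*")
    inner <- pmin(pmax(-inner, -700), 30)           # -k(x-s), clamped
    E <- exp(-exp(inner))
    r <- sweep(sweep(E, 2, a, "*"), 2, b, "+")
    if (deriv) attr(r, "deriv") <- sweep(E * exp(inner), 2, a * k, "*")
  } else {
    inner <- pmin(pmax(-p@k[1] * (x - p@s[1]), -700), 30)
    E <- exp(-exp(inner))
    r <- p@b[1] + p@a[1] * E
    if (deriv) attr(r, "deriv") <- p@a[1] * p@k[1] * E * exp(inner)
  }
  r
}

## ---- normalization plumbing ----------------------------------------------

applyInputNorm <- function(model, S) {
  nm <- model@norm
  if (is.null(nm$inOffset)) return(S)
  sweep(sweep(S, 1, nm$inOffset, "-"), 1, nm$inScale, "/")
}

applyOutputDenorm <- function(model, R) {
  nm <- model@norm
  if (is.null(nm$outOffset)) return(R)
  t(sweep(sweep(t(R), 2, nm$outScale, "*"), 2, nm$outOffset, "+"))
}

## ---- LN model --------------------------------------------------------------

#' Construct an LN model
#'
#' @param spectral F x M spectral profiles.
#' @param temporal U x M temporal profiles.
#' @param weights M x N per-neuron readout weights.
#' @param outNL per-neuron \linkS4class{DoubleExpParams} (default identity-like
#'   unit ramp is replaced by (0, 1, 0, 1) per neuron).
#' @return an \linkS4class{LNModel}.
#' @export
lnModel <- function(spectral, temporal, weights,
                    outNL = doubleExpParams(b = rep(0, ncol(weights)))) {
  new("LNModel", spectral = spectral, temporal = temporal, weights = weights,
      outNL = outNL, norm = list())
}

#' Materialized rank-1 filters of an LN model
#' @param model an \linkS4class{LNModel}.
#' @param m filter index (default: all).
#' @return F x U matrix (single m) or list of them.
#' @export
lnFilters <- function(model, m = NULL) {
  idx <- m %||% seq_len(ncol(model@spectral))
  out <- lapply(idx, function(j) outer(model@spectral[, j], model@temporal[, j]))
  if (length(idx) == 1L) out[[1]] else out
}

## Pre-nonlinearity LN response on an already-normalized F x T matrix.
lnLinear <- function(model, S) {
  P <- crossprod(model@spectral, S)                  # M x T spectral projection
  U <- nrow(model@temporal); T <- ncol(S)
  R <- model@temporal[1, ] * P
  for (u in seq_len(min(U, T))[-1]) {
    R[, u:T] <- R[, u:T] + model@temporal[u, ] * P[, 1:(T - u + 1), drop = FALSE]
  }
  crossprod(R, model@weights)                        # T x N
}

setMethod("linearResponse", signature("LNModel", "Spectrogram"),
  function(model, stim, ...) {
    S <- applyInputNorm(model, specValues(stim))
    if (nrow(S) != nrow(model@spectral))
      stop("spectrogram has ", nrow(S), " channels but model expects ",
           nrow(model@spectral))
    t(lnLinear(model, S))
  })

setMethod("predictRate", signature("LNModel", "Spectrogram"),
  function(model, stim, ...) {
    Z <- t(linearResponse(model, stim))              # T x N
    R <- if (model@identityOut) Z else doubleExponential(Z, model@outNL)
    applyOutputDenorm(model, t(R))
  })

setMethod("nNeurons", "LNModel", function(model) ncol(model@weights))

## ---- population CNN --------------------------------------------------------

#' Construct a population CNN with given architecture
#'
#' Weights are initialized to zero; use \code{\link{initPopulationCNN}} for a
#' seeded random initialization or fit with
#' \code{\link{fitPopulationModel}}.
#'
#' @param nNeurons number of output neurons N.
#' @param F input channels (default 32).
#' @param K1,C1 conv layer 1 time taps / filter count (defaults 15, 80).
#' @param K2,C2 conv layer 2 time taps / filter count (defaults 10, 100).
#' @param D3 width of the first dense layer (default 100).
#' @return a \linkS4class{PopulationCNN} with zero weights.
#' @export
populationCNN <- function(nNeurons, F = 32L, K1 = 15L, C1 = 80L,
                          K2 = 10L, C2 = 100L, D3 = 100L) {
  dims <- c(F = as.integer(F), K1 = as.integer(K1), C1 = as.integer(C1),
            K2 = as.integer(K2), C2 = as.integer(C2), D3 = as.integer(D3),
            N = as.integer(nNeurons))
  new("PopulationCNN",
      W1 = matrix(0, F * K1, C1), b1 = numeric(C1),
      W2 = matrix(0, C1 * K2, C2), b2 = numeric(C2),
      W3 = matrix(0, C2, D3), b3 = numeric(D3),
      W4 = matrix(0, D3, nNeurons), b4 = numeric(nNeurons),
      outNL = doubleExpParams(b = numeric(nNeurons)), dims = dims,
      norm = list())
}

#' Seeded random initialization of a population CNN
#'
#' Linear weights are drawn from a scaled uniform distribution
#' (+-sqrt(6 / (fanin + fanout))); biases start at a small positive value so
#' early ReLU units are active.
#'
#' @param model a \linkS4class{PopulationCNN} (architecture template).
#' @param seed integer seed.
#' @return the model with initialized weights.
#' @export
initPopulationCNN <- function(model, seed = 1L) {
  gl <- function(nr, nc) {
    lim <- sqrt(6 / (nr + nc))
    matrix(runif(nr * nc, -lim, lim), nr, nc)
  }
  withSeed(substreamSeed(seed, "cnn-init"), {
    model@W1 <- gl(nrow(model@W1), ncol(model@W1)); model@b1 <- rep(0.01, length(model@b1))
    model@W2 <- gl(nrow(model@W2), ncol(model@W2)); model@b2 <- rep(0.01, length(model@b2))
    model@W3 <- gl(nrow(model@W3), ncol(model@W3)); model@b3 <- rep(0.01, length(model@b3))
    model@W4 <- gl(nrow(model@W4), ncol(model@W4)); model@b4 <- numeric(length(model@b4))
  })
  model
}

## Forward pass on an already-normalized F x T matrix; returns all caches
## needed by backprop and the Jacobian.
cnnForwardCache <- function(model, S) {
  d <- model@dims
  if (nrow(S) != d["F"])
    stop("spectrogram has ", nrow(S), " channels but model expects ", d["F"])
  X1 <- lagStack(t(S), d["K1"])
  Z1 <- sweep(X1 %*% model@W1, 2, model@b1, "+")
  H1 <- relu(Z1)
  X2 <- lagStack(H1, d["K2"])
  Z2 <- sweep(X2 %*% model@W2, 2, model@b2, "+")
  H2 <- relu(Z2)
  Z3 <- sweep(H2 %*% model@W3, 2, model@b3, "+")
  H3 <- relu(Z3)
  Z4 <- sweep(H3 %*% model@W4, 2, model@b4, "+")
  list(X1 = X1, Z1 = Z1, H1 = H1, X2 = X2, Z2 = Z2, H2 = H2,
       Z3 = Z3, H3 = H3, Z4 = Z4)
}

setMethod("linearResponse", signature("PopulationCNN", "Spectrogram"),
  function(model, stim, ...) {
    S <- applyInputNorm(model, specValues(stim))
    t(cnnForwardCache(model, S)$Z4)
  })

setMethod("predictRate", signature("PopulationCNN", "Spectrogram"),
  function(model, stim, ...) {
    Z <- t(linearResponse(model, stim))
    R <- if (model@identityOut) Z else doubleExponential(Z, model@outNL)
    applyOutputDenorm(model, t(R))
  })

setMethod("nNeurons", "PopulationCNN", function(model) unname(model@dims["N"]))

## ---- subspace readout ------------------------------------------------------

#' Construct a dense subspace readout network
#'
#' @param nDim subspace dimensionality (input width).
#' @param hidden widths of the two hidden ReLU layers (default c(30, 20)).
#' @return a \linkS4class{SubspaceReadout} with zero weights.
#' @export
subspaceReadout <- function(nDim, hidden = c(30L, 20L)) {
  new("SubspaceReadout",
      W1 = matrix(0, nDim, hidden[1]), b1 = numeric(hidden[1]),
      W2 = matrix(0, hidden[1], hidden[2]), b2 = numeric(hidden[2]),
      W3 = matrix(0, hidden[2], 1L), b3 = numeric(1L),
      outNL = doubleExpParams(), norm = list())
}

initSubspaceReadout <- function(model, seed = 1L) {
  gl <- function(nr, nc) {
    lim <- sqrt(6 / (nr + nc))
    matrix(runif(nr * nc, -lim, lim), nr, nc)
  }
  withSeed(substreamSeed(seed, "readout-init"), {
    model@W1 <- gl(nrow(model@W1), ncol(model@W1)); model@b1 <- rep(0.01, length(model@b1))
    model@W2 <- gl(nrow(model@W2), ncol(model@W2)); model@b2 <- rep(0.01, length(model@b2))
    model@W3 <- gl(nrow(model@W3), ncol(model@W3)); model@b3 <- numeric(1L)
  })
  model
}

readoutForwardCache <- function(model, X) {       # X: T x nDim
  Z1 <- sweep(X %*% model@W1, 2, model@b1, "+"); H1 <- relu(Z1)
  Z2 <- sweep(H1 %*% model@W2, 2, model@b2, "+"); H2 <- relu(Z2)
  Z3 <- sweep(H2 %*% model@W3, 2, model@b3, "+")
  list(Z1 = Z1, H1 = H1, Z2 = Z2, H2 = H2, Z3 = Z3)
}

.projInput <- function(stim) {
  if (is(stim, "SubspaceProjection")) projections(stim) else stim
}

setMethod("linearResponse", signature("SubspaceReadout", "ANY"),
  function(model, stim, ...) {
    X <- .projInput(stim)                          # nDim x T
    if (nrow(X) != nrow(model@W1))
      stop("projection has ", nrow(X), " dims but readout expects ", nrow(model@W1))
    nm <- model@norm
    Xt <- t(X)
    if (!is.null(nm$inOffset))
      Xt <- sweep(sweep(Xt, 2, nm$inOffset, "-"), 2, nm$inScale, "/")
    t(readoutForwardCache(model, Xt)$Z3)
  })

setMethod("predictRate", signature("SubspaceReadout", "ANY"),
  function(model, stim, ...) {
    Z <- t(linearResponse(model, stim))
    R <- if (model@identityOut) Z else doubleExponential(Z, model@outNL)
    applyOutputDenorm(model, t(R))
  })

setMethod("nNeurons", "SubspaceReadout", function(model) 1L)

## ---- polynomial readout ----------------------------------------------------

#' Evaluate a polynomial subspace readout
#'
#' r(t) = sum_ij w_ij x_i(t) x_j(t) + sum_i v_i x_i(t) + r0, summed over all
#' ordered pairs (i, j) with symmetric w.
#'
#' @param readout a \linkS4class{PolyReadout}.
#' @param x N x T projection matrix or \linkS4class{SubspaceProjection}.
#' @return rate series of length T.
#' @export
polyReadoutForward <- function(readout, x) {
  X <- .projInput(x)
  stopifnotMsg(all(is.finite(X)), "non-finite projections")
  if (nrow(X) != length(readout@v))
    stop("projection has ", nrow(X), " dims but readout expects ", length(readout@v))
  quad <- if (readout@order == 2L) colSums(X * (readout@W %*% X)) else 0
  z <- as.numeric(quad + drop(crossprod(X, readout@v)) + readout@r0)
  if (isTRUE(readout@useOutNL)) doubleExponential(z, readout@outNL) else z
}

setMethod("predictRate", signature("PolyReadout", "ANY"),
  function(model, stim, ...) matrix(polyReadoutForward(model, stim), 1))
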