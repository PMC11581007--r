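## Tuning subspace: PCA of the dSTRF stack, stimulus projection, readout
## refits, tuning surfaces.

#' Principal tuning subspace of a dSTRF stack
#'
#' Flattens each timepoint's filter into a vector and performs uncentered
#' PCA (SVD of the T x (F*U) matrix; no mean subtraction, so the subspace
#' contains the mean dSTRF, which carries the LN-like component needed for
#' prediction). Components are ordered by singular value; each component's
#' sign is fixed so its largest-magnitude coefficient is positive. The
#' retained dimensionality N is the smallest component count whose
#' cumulative variance reaches \code{varThreshold} (inclusive).
#'
#' @param stack a \linkS4class{DSTRFStack}.
#' @param varThreshold cumulative variance fraction to reach (default 0.90).
#' @param center subtract the mean dSTRF before PCA (default FALSE).
#' @param id identifier for the resulting subspace.
#' @return a \linkS4class{TuningSubspace}.
#' @export
pcaSubspace <- function(stack, varThreshold = 0.90, center = FALSE,
                        id = "neuron") {
  D <- filters(stack)
  dms <- dim(D)
  X <- matrix(D, dms[1], dms[2] * dms[3])
  if (center) X <- sweep(X, 2, colMeans(X), "-")
  if (all(X == 0)) stop("degenerate dSTRF: all-zero stack")
  sv <- svd(X, nu = 0)
  pow <- sv$d^2
  ev <- cumsum(pow) / sum(pow)
  N <- which(ev >= varThreshold - 1e-12)[1]
  G <- sv$v[, seq_len(N), drop = FALSE]
  for (j in seq_len(N)) {
    i <- which.max(abs(G[, j]))
    if (G[i, j] < 0) G[, j] <- -G[, j]
  }
  new("TuningSubspace", filters = G, explainedVariance = ev,
      varThreshold = varThreshold, F = as.integer(dms[2]),
      U = as.integer(dms[3]), id = id)
}

#' Site-pooled tuning subspace
#'
#' PCA over dSTRFs pooled across all neurons of a recording site, giving a
#' single shared subspace in which per-neuron tuning surfaces and response
#' fields can be compared.
#'
#' @param stacks list of \linkS4class{DSTRFStack}, one per neuron.
#' @param varThreshold cumulative variance threshold.
#' @return a \linkS4class{TuningSubspace} with id "site".
#' @export
siteSubspace <- function(stacks, varThreshold = 0.90) {
  arrs <- lapply(stacks, filters)
  D <- do.call(abind3, arrs)
  pooled <- new("DSTRFStack", filters = D,
                times = seq_len(dim(D)[1]), maxLag = stacks[[1]]@maxLag,
                stride = stacks[[1]]@stride, modelId = "pooled")
  pcaSubspace(pooled, varThreshold, id = "site")
}

## row-bind 3-D arrays along dim 1
abind3 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  out <- array(0, c(sum(vapply(arrs, function(a) dim(a)[1], 0L)), d[2], d[3]))
  at <- 0L
  for (a in arrs) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

#' Project a stimulus into a tuning subspace
#'
#' x_j(t) = sum_f sum_u g_j(f, u) s(f, t-u) with zero left-padding: the
#' stimulus convolved causally with each subspace filter.
#'
#' @param sub a \linkS4class{TuningSubspace}.
#' @param s a \linkS4class{Spectrogram} (or a raw F x T matrix).
#' @param stimulusId provenance label.
#' @return a \linkS4class{SubspaceProjection} (N x T).
#' @export
projectStimulus <- function(sub, s, stimulusId = "stimulus") {
  S <- if (is(s, "Spectrogram")) specValues(s) else s
  if (nrow(S) != sub@F)
    stop("stimulus has ", nrow(S), " channels but subspace expects ", sub@F)
  ## lagStack column order (channel fastest within lag blocks) matches the
  ## column-major flattening of the F x U filters, so projection is one
  ## matrix product.
  X <- lagStack(t(S), sub@U)                     # T x (F*U)
  x <- t(X %*% filters(sub))
  new("SubspaceProjection", x = x, subspaceId = sub@id,
      stimulusId = stimulusId)
}

#' Tuning surface or marginal tuning curve
#'
#' Bins projection values (one dim: marginal curve; two dims: surface) on a
#' regular grid spanning the central 99% of each projection, and averages
#' the supplied rate within each bin. Bins with fewer than
#' \code{minOccupancy} samples are flagged empty (NA) and carry no mean.
#'
#' @param x a \linkS4class{SubspaceProjection} or N x T matrix.
#' @param rate rate series of length T (actual PSTH or model prediction; the
#'   choice is the caller's and should be logged).
#' @param dims one or two subspace dimension indices.
#' @param nBins bins per dimension (default 25 for surfaces; use 20 for the
#'   symmetry-index curves).
#' @param span central quantile span of the grid (default 0.99).
#' @param minOccupancy minimum samples per occupied bin (default 5).
#' @return a \linkS4class{TuningSurface}.
#' @export
estimateTuningSurface <- function(x, rate, dims, nBins = 25L, span = 0.99,
                                  minOccupancy = 5L) {
  X <- .projInput(x)
  stopifnotMsg(length(rate) == ncol(X), "rate length must equal T")
  dims <- as.integer(dims)
  edges <- lapply(dims, function(j) {
    q <- quantile(X[j, ], c((1 - span) / 2, 1 - (1 - span) / 2), names = FALSE)
    seq(q[1], q[2], length.out = nBins + 1L)
  })
  bin <- function(v, e) {
    i <- findInterval(v, e, rightmost.closed = TRUE)
    i[i < 1L | i > nBins] <- NA_integer_
    i
  }
  if (length(dims) == 1L) {
    i1 <- bin(X[dims, ], edges[[1]])
    occ <- tabulate(i1, nBins)
    mr <- rep(NA_real_, nBins)
    ok <- !is.na(i1)
    sums <- tapply(rate[ok], i1[ok], sum)
    mr[as.integer(names(sums))] <- sums / occ[as.integer(names(sums))]
    mr[occ < minOccupancy] <- NA_real_
  } else {
    i1 <- bin(X[dims[1], ], edges[[1]])
    i2 <- bin(X[dims[2], ], edges[[2]])
    ok <- !is.na(i1) & !is.na(i2)
    idx <- (i2 - 1L) * nBins + i1
    occ <- matrix(tabulate(idx[ok], nBins * nBins), nBins, nBins)
    mr <- matrix(NA_real_, nBins, nBins)
    sums <- tapply(rate[ok], idx[ok], sum)
    ii <- as.integer(names(sums))
    mr[ii] <- sums / occ[ii]
    mr[occ < minOccupancy] <- NA_real_
  }
  new("TuningSurface", dims = dims, edges = edges, meanRate = mr,
      occupancy = occ, minOccupancy = as.integer(minOccupancy))
}

#' Fit a subspace readout model
#'
#' Refits a compact model predicting one neuron's rate from its subspace
#' projections. The "dense" variant is a two-layer ReLU network with
#' double-exponential output, fitted with the full jackknife protocol; it
#' can express arbitrary nonlinear tuning within the subspace. The "poly1"
#' and "poly2" variants constrain the readout to a first- or second-order
#' polynomial and are fitted fold-wise by penalized least squares (the exact
#' minimizer of the same squared-error-plus-L2 objective).
#'
#' @param x a \linkS4class{SubspaceProjection} (or N x T matrix).
#' @param rate the neuron's rate series (length T).
#' @param cfg a \code{\link{fitConfig}}.
#' @param order "dense", "poly1" or "poly2".
#' @param hidden hidden-layer widths for the dense variant.
#' @param outputNL for the polynomial variants, fit a double-exponential
#'   output stage on top of the polynomial drive (default TRUE), so the
#'   order-1 variant reproduces the LN model within the subspace; FALSE
#'   gives the pure polynomial map.
#' @return a \linkS4class{JackknifeEnsemble} whose members are
#'   \linkS4class{SubspaceReadout} or \linkS4class{PolyReadout} models.
#' @export
fitSubspaceReadout <- function(x, rate, cfg = fitConfig(),
                               order = c("dense", "poly1", "poly2"),
                               hidden = c(30L, 20L), outputNL = TRUE) {
  order <- match.arg(order)
  X <- .projInput(x)
  nDim <- nrow(X)
  if (nDim == 0L) stop("empty subspace (N = 0)")
  stopifnotMsg(length(rate) == ncol(X), "projection and rate must share T")
  resp <- responseSet(matrix(rate, 1), frameRate = 100)
  if (order == "dense") {
    template <- subspaceReadout(nDim, hidden)
    return(fitPopulationModel(template, X, resp, cfg))
  }
  ## polynomial variants: exact ridge solution per fold
  T <- ncol(X)
  folds <- jackknifeFolds(T, cfg$nJackknife)
  Xt <- t(X)
  design <- if (order == "poly1") Xt else {
    quad <- matrix(0, T, nDim * (nDim + 1) / 2)
    cn <- 1L
    pairIdx <- list()
    for (i in seq_len(nDim)) for (j in i:nDim) {
      quad[, cn] <- Xt[, i] * Xt[, j]
      pairIdx[[cn]] <- c(i, j)
      cn <- cn + 1L
    }
    cbind(Xt, quad)
  }
  membersL <- vector("list", cfg$nJackknife)
  diag <- list()
  for (fi in seq_along(folds)) {
    incl <- setdiff(seq_len(T), folds[[fi]])
    A <- cbind(1, design[incl, , drop = FALSE])
    lam <- cfg$l2Strength * length(incl)
    pen <- diag(c(0, rep(lam, ncol(design))))
    beta <- solve(crossprod(A) + pen, crossprod(A, rate[incl]))
    r0 <- beta[1]; rest <- beta[-1]
    v <- rest[seq_len(nDim)]
    W <- matrix(0, nDim, nDim)
    if (order == "poly2") {
      qcoef <- rest[-seq_len(nDim)]
      cn <- 1L
      for (i in seq_len(nDim)) for (j in i:nDim) {
        ## stored coefficient applies to x_i x_j once; split across the
        ## symmetric ordered-pair sum
        W[i, j] <- W[i, j] + qcoef[cn] / ifelse(i == j, 1, 2)
        W[j, i] <- W[i, j]
        cn <- cn + 1L
      }
    }
    m <- polyReadout(if (order == "poly1") 1L else 2L, v = v, W = W, r0 = r0)
    if (outputNL) {
      ## second stage: double-exponential output on the polynomial drive
      z <- polyReadoutForward(m, X)
      yIn <- rate[incl]; zIn <- z[incl]
      obj <- function(p) {
        nl <- doubleExpParams(p[1], exp(p[2]), p[3], exp(p[4]))
        mean((doubleExponential(zIn, nl) - yIn)^2)
      }
      p0 <- c(min(yIn), log(max(diff(range(yIn)), 1e-6)), stats::median(zIn),
              log(1 / max(sd(zIn), 1e-6)))
      fit <- stats::optim(p0, obj, method = "BFGS",
                          control = list(maxit = 200))
      if (fit$value < mean((zIn - yIn)^2)) {
        m@outNL <- doubleExpParams(fit$par[1], exp(fit$par[2]), fit$par[3],
                                   exp(fit$par[4]))
        m@useOutNL <- TRUE
      }
    }
    membersL[[fi]] <- m
    pred <- polyReadoutForward(m, X)
    diag[[fi]] <- data.frame(fold = fi, init = 1L, stage = 1L,
                             loss = mean((pred[incl] - rate[incl])^2),
                             valLoss = mean((pred[folds[[fi]]] - rate[folds[[fi]]])^2),
                             epochs = 1L, note = "closed-form ridge")
  }
  new("JackknifeEnsemble", members = membersL, foldMasks = folds,
      diagnostics = do.call(rbind, diag), cfg = unclass(cfg))
}
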