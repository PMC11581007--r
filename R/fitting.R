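## Model fitting: min-max normalization, Adam with analytic gradients,
## two-stage schedule (level shift, then full double-exponential output),
## jackknifing with best-of-inits selection.

#' Fit configuration
#'
#' The two-stage schedule first fits with the output nonlinearity replaced by
#' a per-neuron level shift at a high learning rate, then restores the
#' double exponential and continues at a lower rate. Stopping: fitting halts
#' when the relative improvement of the running-best fold-internal
#' validation loss (on the fold's excluded share) over a patience window
#' (default 100 epochs) falls below the stage tolerance, or at maxEpochs.
#'
#' @param coarseLr,coarseTol stage-1 learning rate and stop tolerance.
#' @param fineLr,fineTol stage-2 learning rate and stop tolerance.
#' @param l2Strength L2 penalty on linear weights (never on biases or output
#'   nonlinearity parameters).
#' @param nJackknife number of jackknife folds (each excludes a distinct
#'   contiguous 1/nJackknife of the fit timepoints).
#' @param nInits random initializations per fold; the init with the lowest
#'   loss on the fold's excluded share is retained.
#' @param seed master seed; all fold/init randomness derives from it.
#' @param maxEpochs epoch cap per stage.
#' @param patience early-stopping patience window, epochs.
#' @return list of class \code{FitConfig}.
#' @export
fitConfig <- function(coarseLr = 0.01, coarseTol = 0.001, fineLr = 0.001,
                      fineTol = 1e-4, l2Strength = 1e-4, nJackknife = 8L,
                      nInits = 5L, seed = 1L, maxEpochs = 1000L,
                      patience = 100L) {
  stopifnotMsg(coarseLr > 0 && fineLr > 0, "learning rates must be positive")
  stopifnotMsg(coarseTol > 0 && fineTol > 0, "tolerances must be positive")
  stopifnotMsg(nJackknife >= 2L, "need at least 2 jackknife folds")
  structure(list(coarseLr = coarseLr, coarseTol = coarseTol, fineLr = fineLr,
                 fineTol = fineTol, l2Strength = l2Strength,
                 nJackknife = as.integer(nJackknife), nInits = as.integer(nInits),
                 seed = as.integer(seed), maxEpochs = as.integer(maxEpochs),
                 patience = as.integer(patience)),
            class = "FitConfig")
}

#' Per-channel min-max normalization
#'
#' Affinely maps each row (channel) of a matrix to [0, 1], recording the
#' offset/scale so the map can be inverted and reused on validation data.
#' A constant channel maps to all zeros (scale kept at 1).
#'
#' @param data channel x time matrix.
#' @return list with \code{values} (normalized matrix), \code{offset},
#'   \code{scale} (per-channel affine maps: values = (data - offset)/scale).
#' @export
normalizeMinmax <- function(data) {
  stopifnotMsg(all(is.finite(data)), "non-finite data")
  offset <- apply(data, 1, min)
  scale <- apply(data, 1, max) - offset
  scale[scale == 0] <- 1
  list(values = sweep(sweep(data, 1, offset, "-"), 1, scale, "/"),
       offset = offset, scale = scale)
}

#' Invert a min-max normalization
#' @param values normalized matrix (channels x time).
#' @param offset,scale maps from \code{\link{normalizeMinmax}}.
#' @return matrix on the original scale.
#' @export
denormalizeMinmax <- function(values, offset, scale) {
  sweep(sweep(values, 1, scale, "*"), 1, offset, "+")
}

## ---- family adapters -------------------------------------------------------
## Each family exposes: pack/unpack between model object and a flat named
## list of arrays, a forward to the pre-nonlinearity output Z (T x N), a
## backward from dL/dZ to parameter gradients, and the names of the linear
## weights subject to L2.

.lnAdapter <- function(template) {
  Fd <- nrow(template@spectral); M <- ncol(template@spectral)
  U <- nrow(template@temporal); N <- ncol(template@weights)
  list(
    pack = function(model) list(spectral = model@spectral,
                                temporal = model@temporal,
                                weights = model@weights),
    unpack = function(model, par) {
      model@spectral <- par$spectral; model@temporal <- par$temporal
      model@weights <- par$weights; model
    },
    init = function(seed) withSeed(seed, {
      sc <- 1 / sqrt(Fd * M)
      list(spectral = matrix(runif(Fd * M, -sc, sc) * sqrt(M), Fd, M),
           temporal = matrix(runif(U * M, -1, 1) / sqrt(U), U, M),
           weights = matrix(runif(M * N, -1, 1) / M, M, N))
    }),
    prep = function(S) S,
    fwd = function(par, S) {
      P <- crossprod(par$spectral, S)
      T <- ncol(S)
      R <- par$temporal[1, ] * P
      for (u in 2:min(U, T))
        R[, u:T] <- R[, u:T] + par$temporal[u, ] * P[, 1:(T - u + 1), drop = FALSE]
      list(Z = crossprod(R, par$weights), cache = list(P = P, R = R))
    },
    bwd = function(par, S, cache, G) {            # G: T x N = dL/dZ
      T <- ncol(S)
      dW <- cache$R %*% G
      GR <- par$weights %*% t(G)                   # M x T
      dTau <- matrix(0, U, M)
      dP <- matrix(0, M, T)
      for (u in seq_len(min(U, T))) {
        a <- u:T; b <- 1:(T - u + 1)
        dTau[u, ] <- rowSums(GR[, a, drop = FALSE] * cache$P[, b, drop = FALSE])
        dP[, b] <- dP[, b] + par$temporal[u, ] * GR[, a, drop = FALSE]
      }
      list(spectral = S %*% t(dP), temporal = dTau, weights = dW)
    },
    l2names = c("spectral", "temporal", "weights"),
    nNeurons = N)
}

.unlag <- function(dX, K, C) {                     # transpose of lagStack
  T <- nrow(dX)
  out <- matrix(0, T, C)
  for (k in seq_len(K)) {
    rows <- k:T
    out[seq_len(T - k + 1L), ] <- out[seq_len(T - k + 1L), ] +
      dX[rows, ((k - 1L) * C + 1L):(k * C), drop = FALSE]
  }
  out
}

.cnnAdapter <- function(template) {
  d <- template@dims
  list(
    pack = function(model) list(W1 = model@W1, b1 = model@b1, W2 = model@W2,
                                b2 = model@b2, W3 = model@W3, b3 = model@b3,
                                W4 = model@W4, b4 = model@b4),
    unpack = function(model, par) {
      model@W1 <- par$W1; model@b1 <- par$b1; model@W2 <- par$W2
      model@b2 <- par$b2; model@W3 <- par$W3; model@b3 <- par$b3
      model@W4 <- par$W4; model@b4 <- par$b4; model
    },
    init = function(seed) {
      m <- initPopulationCNN(template, seed)
      list(W1 = m@W1, b1 = m@b1, W2 = m@W2, b2 = m@b2,
           W3 = m@W3, b3 = m@b3, W4 = m@W4, b4 = m@b4)
    },
    prep = function(S) list(X1 = lagStack(t(S), d["K1"])),
    fwd = function(par, pin) {
      X1 <- pin$X1
      Z1 <- sweep(X1 %*% par$W1, 2, par$b1, "+"); H1 <- relu(Z1)
      X2 <- lagStack(H1, d["K2"])
      Z2 <- sweep(X2 %*% par$W2, 2, par$b2, "+"); H2 <- relu(Z2)
      Z3 <- sweep(H2 %*% par$W3, 2, par$b3, "+"); H3 <- relu(Z3)
      Z4 <- sweep(H3 %*% par$W4, 2, par$b4, "+")
      list(Z = Z4, cache = list(X1 = X1, Z1 = Z1, X2 = X2, Z2 = Z2,
                                H2 = H2, Z3 = Z3, H3 = H3))
    },
    bwd = function(par, pin, cc, G4) {
      G3 <- (G4 %*% t(par$W4)) * reluGrad(cc$Z3)
      G2 <- (G3 %*% t(par$W3)) * reluGrad(cc$Z2)
      dH1 <- .unlag(G2 %*% t(par$W2), d["K2"], d["C1"])
      G1 <- dH1 * reluGrad(cc$Z1)
      list(W1 = crossprod(cc$X1, G1), b1 = colSums(G1),
           W2 = crossprod(cc$X2, G2), b2 = colSums(G2),
           W3 = crossprod(cc$H2, G3), b3 = colSums(G3),
           W4 = crossprod(cc$H3, G4), b4 = colSums(G4))
    },
    l2names = c("W1", "W2", "W3", "W4"),
    nNeurons = unname(d["N"]))
}

.readoutAdapter <- function(template) {
  list(
    pack = function(model) list(W1 = model@W1, b1 = model@b1, W2 = model@W2,
                                b2 = model@b2, W3 = model@W3, b3 = model@b3),
    unpack = function(model, par) {
      model@W1 <- par$W1; model@b1 <- par$b1; model@W2 <- par$W2
      model@b2 <- par$b2; model@W3 <- par$W3; model@b3 <- par$b3; model
    },
    init = function(seed) {
      m <- initSubspaceReadout(template, seed)
      list(W1 = m@W1, b1 = m@b1, W2 = m@W2, b2 = m@b2, W3 = m@W3, b3 = m@b3)
    },
    prep = function(X) X,
    fwd = function(par, X) {                       # X: T x nDim
      m <- template
      m@W1 <- par$W1; m@b1 <- par$b1; m@W2 <- par$W2; m@b2 <- par$b2
      m@W3 <- par$W3; m@b3 <- par$b3
      cc <- readoutForwardCache(m, X)
      list(Z = cc$Z3, cache = cc)
    },
    bwd = function(par, X, cc, G3) {
      G2 <- (G3 %*% t(par$W3)) * reluGrad(cc$Z2)
      G1 <- (G2 %*% t(par$W2)) * reluGrad(cc$Z1)
      list(W1 = crossprod(X, G1), b1 = colSums(G1),
           W2 = crossprod(cc$H1, G2), b2 = colSums(G2),
           W3 = crossprod(cc$H2, G3), b3 = colSums(G3))
    },
    l2names = c("W1", "W2", "W3"),
    nNeurons = 1L)
}

.adapterFor <- function(model) {
  if (is(model, "LNModel")) .lnAdapter(model)
  else if (is(model, "PopulationCNN")) .cnnAdapter(model)
  else if (is(model, "SubspaceReadout")) .readoutAdapter(model)
  else stop("no fitting adapter for class ", class(model))
}

## ---- Adam ------------------------------------------------------------------

.adamInit <- function(par) list(m = lapply(par, function(p) p * 0),
                                v = lapply(par, function(p) p * 0), t = 0L)

.adamStep <- function(par, grad, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  c1 <- 1 - beta1^st$t; c2 <- 1 - beta2^st$t
  for (nm in names(par)) {
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * grad[[nm]]
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * grad[[nm]]^2
    par[[nm]] <- par[[nm]] - lr * (st$m[[nm]] / c1) /
      (sqrt(st$v[[nm]] / c2) + eps)
  }
  list(par = par, st = st)
}

## ---- two-stage training core ----------------------------------------------

## Output-layer forward/grad. mode "shift": R = Z + c. mode "dexp": per-neuron
## double exponential. out is a list of per-neuron vectors.
.outForward <- function(Z, out, mode) {
  if (mode == "shift") {
    sweep(Z, 2, out$shift, "+")
  } else {
    inner <- pmin(pmax(-sweep(sweep(Z, 2, out$s, "-"), 2, out$k, "*"), -700), 30)
    E <- exp(-exp(inner))
    attr(E, "inner") <- inner
    sweep(sweep(E, 2, out$a, "*"), 2, out$b, "+")
  }
}

.outBackward <- function(Z, out, mode, R, dLdR) {
  if (mode == "shift") {
    list(dZ = dLdR, grads = list(shift = colSums(dLdR)))
  } else {
    inner <- pmin(pmax(-sweep(sweep(Z, 2, out$s, "-"), 2, out$k, "*"), -700), 30)
    E <- exp(-exp(inner))
    EeI <- E * exp(inner)
    dZ <- dLdR * sweep(EeI, 2, out$a * out$k, "*")
    Zs <- sweep(Z, 2, out$s, "-")
    list(dZ = dZ,
         grads = list(b = colSums(dLdR),
                      a = colSums(dLdR * E),
                      s = -colSums(dLdR * sweep(EeI, 2, out$a * out$k, "*")),
                      k = colSums(dLdR * sweep(EeI * Zs, 2, out$a, "*"))))
  }
}

## Train one stage with Adam + patience-window early stopping on the fold's
## excluded (validation) rows. Returns NULL (with a message attribute) if the
## loss goes non-finite.
.trainStage <- function(par, out, mode, adapter, input, Y, incl, excl,
                        lr, tol, l2, maxEpochs, patience = 100L,
                        minEpochs = max(120L, patience)) {
  st <- .adamInit(par)
  stOut <- .adamInit(out)
  nIncl <- length(incl); N <- ncol(Y)
  l2names <- adapter$l2names
  bestHist <- rep(NA_real_, maxEpochs)
  best <- list(val = Inf, par = par, out = out, train = NA_real_)
  for (ep in seq_len(maxEpochs)) {
    fw <- adapter$fwd(par, input)
    R <- .outForward(fw$Z, out, mode)
    err <- R - Y
    loss <- mean(err[incl, ]^2) +
      l2 * sum(vapply(l2names, function(nm) sum(par[[nm]]^2), 0))
    valLoss <- if (length(excl)) mean(err[excl, , drop = FALSE]^2) else loss
    if (!is.finite(loss) || !is.finite(valLoss)) {
      res <- NULL; attr(res, "diagnostic") <- sprintf("non-finite loss at epoch %d", ep)
      return(res)
    }
    if (valLoss < best$val)
      best <- list(val = valLoss, par = par, out = out, train = loss)
    bestHist[ep] <- best$val
    ## stop when the running-best validation loss has improved by less than
    ## tol (relative) over the last `patience` epochs
    if (ep >= minEpochs && ep > patience) {
      ref <- bestHist[ep - patience]
      if ((ref - best$val) / max(ref, 1e-12) < tol) break
    }
    dLdR <- matrix(0, nrow(Y), N)
    dLdR[incl, ] <- 2 * err[incl, , drop = FALSE] / (nIncl * N)
    ob <- .outBackward(fw$Z, out, mode, R, dLdR)
    grads <- adapter$bwd(par, input, fw$cache, ob$dZ)
    for (nm in l2names) grads[[nm]] <- grads[[nm]] + 2 * l2 * par[[nm]]
    up <- .adamStep(par, grads, st, lr); par <- up$par; st <- up$st
    upo <- .adamStep(out, ob$grads, stOut, lr); out <- upo$par; stOut <- upo$st
  }
  list(par = best$par, out = best$out, epochs = ep, valLoss = best$val,
       trainLoss = best$train)
}

## Contiguous fold masks: fold i excludes block i of the timeline.
jackknifeFolds <- function(T, nFolds) {
  edges <- round(seq(0, T, length.out = nFolds + 1))
  lapply(seq_len(nFolds), function(i) (edges[i] + 1L):edges[i + 1L])
}

#' Fit an encoding model with the jackknife protocol
#'
#' Normalizes stimulus channels and response rates to [0, 1] (maps derived
#' from the supplied fit data and stored in each fitted member for reuse on
#' validation data), then for each of \code{nJackknife} folds (each excluding
#' a distinct contiguous share of the timeline) runs \code{nInits} seeded
#' initializations through the two-stage schedule: stage 1 with the output
#' nonlinearity replaced by a per-neuron level shift (coarse learning rate),
#' stage 2 with the full double exponential restored (fine learning rate),
#' continuing from the stage-1 linear parameters. The loss is the mean
#' squared error over all neurons simultaneously plus an L2 penalty on the
#' linear weights. Per fold, the initialization with the lowest loss on the
#' excluded share is retained. An initialization whose loss goes non-finite
#' is dropped with a logged diagnostic; the ensemble is still returned as
#' long as any initialization of each fold survives.
#'
#' @param model architecture template: an \linkS4class{LNModel} or
#'   \linkS4class{PopulationCNN} (weights ignored), or a
#'   \linkS4class{SubspaceReadout} when \code{stim} is a projection.
#' @param stim a \linkS4class{Spectrogram} (or N x T projection matrix /
#'   \linkS4class{SubspaceProjection} for readout models).
#' @param resp a \linkS4class{ResponseSet} sharing T and frame rate.
#' @param cfg a \code{\link{fitConfig}}.
#' @return a \linkS4class{JackknifeEnsemble}.
#' @export
fitPopulationModel <- function(model, stim, resp, cfg = fitConfig()) {
  isSpec <- is(stim, "Spectrogram")
  raw <- if (isSpec) specValues(stim) else .projInput(stim)
  Y0 <- rates(resp)
  stopifnotMsg(ncol(raw) == ncol(Y0), "stimulus and responses must share T")
  if (isSpec)
    stopifnotMsg(abs(frameRate(stim) - frameRate(resp)) < 1e-9,
                 "stimulus and responses must share frame rate")
  inN <- normalizeMinmax(raw)
  outN <- normalizeMinmax(Y0)
  Y <- t(outN$values)                              # T x N
  adapter <- .adapterFor(model)
  input <- if (is(model, "SubspaceReadout")) t(inN$values) else inN$values
  input <- adapter$prep(input)
  T <- ncol(raw)
  folds <- jackknifeFolds(T, cfg$nJackknife)
  membersL <- vector("list", cfg$nJackknife)
  diag <- list()
  for (fi in seq_len(cfg$nJackknife)) {
    excl <- folds[[fi]]
    incl <- setdiff(seq_len(T), excl)
    best <- NULL
    for (ii in seq_len(cfg$nInits)) {
      seed <- substreamSeed(cfg$seed, sprintf("fold%d-init%d", fi, ii))
      par <- adapter$init(seed)
      N <- adapter$nNeurons
      s1 <- .trainStage(par, list(shift = numeric(N)), "shift", adapter,
                        input, Y, incl, excl, cfg$coarseLr, cfg$coarseTol,
                        cfg$l2Strength, cfg$maxEpochs, cfg$patience %||% 100L)
      if (is.null(s1)) {
        diag[[length(diag) + 1L]] <- data.frame(
          fold = fi, init = ii, stage = 1L, loss = NA_real_, valLoss = NA_real_,
          epochs = NA_integer_, note = attr(s1, "diagnostic") %||% "failed")
        next
      }
      nl0 <- list(b = colMeans(Y[incl, , drop = FALSE]),
                  a = apply(Y[incl, , drop = FALSE], 2, function(y) diff(range(y))),
                  s = numeric(N), k = rep(1, N))
      s2 <- .trainStage(s1$par, nl0, "dexp", adapter, input, Y, incl, excl,
                        cfg$fineLr, cfg$fineTol, cfg$l2Strength, cfg$maxEpochs,
                        cfg$patience %||% 100L)
      if (is.null(s2)) {
        diag[[length(diag) + 1L]] <- data.frame(
          fold = fi, init = ii, stage = 2L, loss = NA_real_, valLoss = NA_real_,
          epochs = NA_integer_, note = attr(s2, "diagnostic") %||% "failed")
        next
      }
      diag[[length(diag) + 1L]] <- data.frame(
        fold = fi, init = ii, stage = 2L, loss = s2$trainLoss,
        valLoss = s2$valLoss, epochs = s1$epochs + s2$epochs, note = "",
        stringsAsFactors = FALSE)
      cand <- list(par = s2$par, out = s2$out, valLoss = s2$valLoss,
                   stage1Val = s1$valLoss)
      if (is.null(best) || cand$valLoss < best$valLoss) best <- cand
    }
    if (is.null(best))
      stop("all initializations failed for fold ", fi)
    m <- adapter$unpack(model, best$par)
    m@outNL <- doubleExpParams(b = best$out$b, a = pmax(best$out$a, 0),
                               s = best$out$s, k = best$out$k)
    m@norm <- list(inOffset = inN$offset, inScale = inN$scale,
                   outOffset = outN$offset, outScale = outN$scale,
                   stage1ValLoss = best$stage1Val, stage2ValLoss = best$valLoss)
    membersL[[fi]] <- m
  }
  new("JackknifeEnsemble", members = membersL, foldMasks = folds,
      diagnostics = do.call(rbind, diag), cfg = unclass(cfg))
}

#' Averaged prediction of a jackknife ensemble
#' @param ens a \linkS4class{JackknifeEnsemble}.
#' @param stim stimulus accepted by the members' \code{predictRate}.
#' @return N x T matrix: mean of member predictions.
#' @export
ensemblePredict <- function(ens, stim) {
  preds <- lapply(members(ens), predictRate, stim = stim)
  Reduce(`+`, preds) / length(preds)
}

#' Write per-fold training diagnostics as TSV
#' @param ens a \linkS4class{JackknifeEnsemble}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeFitDiagnostics <- function(ens, path) {
  write.table(ens@diagnostics, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
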