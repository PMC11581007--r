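## Dynamic STRF: exact Jacobians of fitted models, the finite-difference
## oracle, and jackknife shrinkage averaging.

## Derivative of the full input->rate map, including the stored min-max
## normalization affine maps, so dSTRFs are in rate units per spectrogram
## unit regardless of normalization.
.normJacScale <- function(model, neuron) {
  nm <- model@norm
  list(inScale = if (is.null(nm$inScale)) NULL else nm$inScale,
       outScale = if (is.null(nm$outScale)) 1 else nm$outScale[neuron])
}

.applyNormScale <- function(D, model, neuron) {
  sc <- .normJacScale(model, neuron)
  if (!is.null(sc$inScale)) {
    for (f in seq_len(dim(D)[2])) D[, f, ] <- D[, f, ] / sc$inScale[f]
  }
  D * sc$outScale
}

.resolveTimes <- function(times, T, stride) {
  if (is.null(times)) times <- seq(1L, T, by = stride)
  stopifnotMsg(all(times >= 1 & times <= T), "times out of range")
  as.integer(times)
}

#' @describeIn jacobianDSTRF For the LN model the Jacobian has a closed
#'   form: the neuron's effective filter (weighted sum of the rank-1 filter
#'   bank) scaled at each timepoint by the slope of the output nonlinearity
#'   at that timepoint's linear response.
setMethod("jacobianDSTRF", signature("LNModel", "Spectrogram"),
  function(model, stim, neuron, times = NULL, maxLag = 25L, stride = 1L, ...) {
    S <- applyInputNorm(model, specValues(stim))
    T <- ncol(S); Fd <- nrow(S); U <- as.integer(maxLag)
    times <- .resolveTimes(times, T, stride)
    ## effective filter h_i(f, u) = sum_m w_mi phi_m(f) tau_m(u)
    wm <- model@weights[, neuron]
    h <- model@spectral %*% (wm * t(model@temporal))   # F x U0
    U0 <- nrow(model@temporal)
    hFull <- matrix(0, Fd, U)
    hFull[, seq_len(min(U, U0))] <- h[, seq_len(min(U, U0))]
    z <- lnLinear(model, S)[times, neuron]
    gain <- if (model@identityOut) rep(1, length(times)) else {
      p <- model@outNL
      i <- neuron
      r <- doubleExponential(z, doubleExpParams(p@b[i], p@a[i], p@s[i], p@k[i]),
                             deriv = TRUE)
      attr(r, "deriv")
    }
    D <- array(0, c(length(times), Fd, U))
    for (ti in seq_along(times)) D[ti, , ] <- hFull * gain[ti]
    for (ti in seq_along(times)) {              # no derivative into padding
      u <- times[ti]
      if (u < U) D[ti, , (u + 1L):U] <- 0
    }
    D <- .applyNormScale(D, model, neuron)
    new("DSTRFStack", filters = D, times = times, maxLag = U,
        stride = as.integer(stride), modelId = "LNModel")
  })

#' @describeIn jacobianDSTRF Exact backpropagation through the network: for
#'   each requested timepoint the derivative of that output frame is chained
#'   through the dense layers and both causal convolutions back to the
#'   spectrogram, batched over timepoints.
setMethod("jacobianDSTRF", signature("PopulationCNN", "Spectrogram"),
  function(model, stim, neuron, times = NULL, maxLag = 25L, stride = 1L, ...) {
    S <- applyInputNorm(model, specValues(stim))
    d <- model@dims
    T <- ncol(S); Fd <- unname(d["F"]); U <- as.integer(maxLag)
    K1 <- unname(d["K1"]); K2 <- unname(d["K2"]); C1 <- unname(d["C1"])
    stopifnotMsg(K1 + K2 - 1L <= U,
                 sprintf("maxLag %d shorter than architecture footprint %d",
                         U, K1 + K2 - 1L))
    times <- .resolveTimes(times, T, stride)
    nt <- length(times)
    cc <- cnnForwardCache(model, S)
    g4 <- if (model@identityOut) rep(1, nt) else {
      p <- model@outNL; i <- neuron
      r <- doubleExponential(cc$Z4[times, i],
                             doubleExpParams(p@b[i], p@a[i], p@s[i], p@k[i]),
                             deriv = TRUE)
      attr(r, "deriv")
    }
    W4i <- matrix(model@W4[, neuron], nt, d["D3"], byrow = TRUE)
    G3 <- W4i * reluGrad(cc$Z3[times, , drop = FALSE]) * g4
    G2 <- (G3 %*% t(model@W3)) * reluGrad(cc$Z2[times, , drop = FALSE])
    V <- G2 %*% t(model@W2)                       # nt x (C1*K2)
    D <- array(0, c(nt, Fd, U))
    for (k in seq_len(K2)) {
      tp <- times - (k - 1L)                       # conv1 output frame index
      valid <- tp >= 1L
      G1k <- matrix(0, nt, C1)
      if (any(valid))
        G1k[valid, ] <- V[valid, ((k - 1L) * C1 + 1L):(k * C1), drop = FALSE] *
          reluGrad(cc$Z1[tp[valid], , drop = FALSE])
      Ck <- G1k %*% t(model@W1)                    # nt x (F*K1)
      for (j in seq_len(K1)) {
        u <- (k - 1L) + (j - 1L) + 1L              # lag index (1-based)
        D[, , u] <- D[, , u] + Ck[, ((j - 1L) * Fd + 1L):(j * Fd), drop = FALSE]
      }
    }
    for (ti in seq_len(nt)) {                      # zero lags into padding
      tt <- times[ti]
      if (tt < U) D[ti, , (tt + 1L):U] <- 0
    }
    D <- .applyNormScale(D, model, neuron)
    new("DSTRFStack", filters = D, times = times, maxLag = U,
        stride = as.integer(stride), modelId = "PopulationCNN")
  })

#' Finite-difference dSTRF oracle
#'
#' Central differences [r(s + delta e) - r(s - delta e)] / (2 delta) over
#' every (frequency, lag) perturbation of the raw stimulus at one timepoint.
#' Slow but model-agnostic; serves as the independent check on
#' \code{\link{jacobianDSTRF}}.
#'
#' @param model any model with a \code{predictRate} method.
#' @param stim a \linkS4class{Spectrogram}.
#' @param neuron neuron index.
#' @param t frame index.
#' @param maxLag maximum lag U, frames.
#' @param delta perturbation step (raw stimulus units).
#' @return F x U matrix of derivative estimates.
#' @export
finiteDifferenceDSTRF <- function(model, stim, neuron, t, maxLag = 25L,
                                  delta = 1e-3) {
  stopifnotMsg(delta > 0, "delta must be positive")
  S <- specValues(stim)
  Fd <- nrow(S); U <- as.integer(maxLag)
  D <- matrix(0, Fd, U)
  for (u in 0:(U - 1L)) {
    tt <- t - u
    if (tt < 1L) next
    for (f in seq_len(Fd)) {
      Sp <- S; Sp[f, tt] <- Sp[f, tt] + delta
      Sm <- S; Sm[f, tt] <- Sm[f, tt] - delta
      rp <- predictRate(model, spectrogram(Sp, stim@frameRate, stim@centerFreqs))[neuron, t]
      rm <- predictRate(model, spectrogram(Sm, stim@frameRate, stim@centerFreqs))[neuron, t]
      D[f, u + 1L] <- (rp - rm) / (2 * delta)
    }
  }
  D
}

#' Shrinkage average of jackknife filter estimates
#'
#' Per coefficient, with m the mean over estimates and se its standard
#' error, returns m * max(0, 1 - (se/|m|)^2): coefficients whose standard
#' error exceeds their mean magnitude are shrunk to zero, attenuating noise
#' while never flipping a sign or increasing a magnitude. Coefficients with
#' mean exactly zero return zero.
#'
#' @param estimates list (length >= 2) of equal-shaped numeric arrays.
#' @return array of the common shape: the shrunk mean.
#' @export
shrinkageAverage <- function(estimates) {
  stopifnotMsg(length(estimates) >= 2L, "need at least 2 estimates")
  n <- length(estimates)
  m <- Reduce(`+`, estimates) / n
  ss <- Reduce(`+`, lapply(estimates, function(e) (e - m)^2))
  se <- sqrt(ss / (n - 1)) / sqrt(n)
  fac <- 1 - (se / abs(m))^2
  fac[!is.finite(fac)] <- 0                       # m == 0 -> zero
  out <- m * pmax(fac, 0)
  out[m == 0] <- 0
  out
}

#' Ensemble dSTRF with shrinkage averaging
#'
#' Computes the Jacobian dSTRF under each jackknife member and combines the
#' member estimates coefficient-wise with \code{\link{shrinkageAverage}}.
#'
#' @param ens a \linkS4class{JackknifeEnsemble}.
#' @param stim a \linkS4class{Spectrogram}.
#' @param neuron neuron index.
#' @param times,maxLag,stride as in \code{\link{jacobianDSTRF}}.
#' @return a \linkS4class{DSTRFStack} of the shrunk filters.
#' @export
ensembleDSTRF <- function(ens, stim, neuron, times = NULL, maxLag = 25L,
                          stride = 1L) {
  stacks <- lapply(members(ens), jacobianDSTRF, stim = stim, neuron = neuron,
                   times = times, maxLag = maxLag, stride = stride)
  shr <- shrinkageAverage(lapply(stacks, filters))
  new("DSTRFStack", filters = shr, times = stacks[[1]]@times,
      maxLag = as.integer(maxLag), stride = as.integer(stride),
      modelId = paste0("ensemble:", stacks[[1]]@modelId))
}
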