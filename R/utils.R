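#' @import methods
#' @importFrom stats fft rnorm runif rpois sd cor quantile coef lm predict
#' @importFrom utils head tail write.table read.table modifyList
NULL

## Deterministic per-stage substreams: every random draw in the package flows
## from one global seed through a named substream, so stages can be rerun or
## reordered without perturbing each other's draws.
substreamSeed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 0
  for (ch in utf8ToInt(as.character(name))) h <- (h * 31 + ch) %% 1000003L
  as.integer((abs(as.integer(seed)) %% 1000003L * 2017L + h) %% 2147483629L) + 1L
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Lag-stack a T x C matrix into T x (C*K): column block k holds the input
## delayed by k-1 frames, zero-padded at the left edge.  This turns a causal
## FIR convolution into a single matrix product.
lagStack <- function(x, K) {
  T <- nrow(x); C <- ncol(x)
  out <- matrix(0, T, C * K)
  for (k in seq_len(K)) {
    rows <- k:T
    out[rows, ((k - 1L) * C + 1L):(k * C)] <- x[seq_len(T - k + 1L), , drop = FALSE]
  }
  out
}

relu <- function(x) pmax(x, 0)

reluGrad <- function(z) (z > 0) * 1

## Principal angles (degrees) between the column spans of two matrices.
principalAngles <- function(A, B) {
  qa <- qr.Q(qr(A)); qb <- qr.Q(qr(B))
  s <- svd(crossprod(qa, qb))$d
  s <- pmin(pmax(s, -1), 1)
  sort(acos(s) * 180 / pi)
}

## Pearson correlation that tolerates zero variance (returns NA).
safeCor <- function(a, b) {
  if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
  cor(a, b)
}

dbToAmp <- function(db) 10^(db / 20)

vecnorm <- function(x) sqrt(sum(x^2))

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnotMsg <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
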