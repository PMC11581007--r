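test_that("double exponential matches its closed form and limits", {
  expect_equal(doubleExponential(0, doubleExpParams(0, 1, 0, 1)), exp(-1),
               tolerance = 1e-12)
  expect_equal(doubleExponential(1e6, doubleExpParams(0.5, 2, 0, 1)), 2.5,
               tolerance = 1e-9)
  expect_equal(doubleExponential(-1e6, doubleExpParams(0.3, 5, 0, 2)), 0.3,
               tolerance = 1e-9)
  ## strictly increasing for k > 0; constant b when a = 0
  x <- seq(-5, 5, by = 0.1)
  y <- doubleExponential(x, doubleExpParams(0, 1, 0.3, 2))
  expect_true(all(diff(y) >= 0))
  expect_true(all(diff(y[x > -2 & x < 4]) > 0))
  expect_true(all(doubleExponential(x, doubleExpParams(0.7, 0, 0, 1)) == 0.7))
})

test_that("LN forward equals the brute-force triple-loop evaluation", {
  set.seed(42)
  F <- 6L; U <- 4L; M <- 3L; N <- 2L; T <- 50L
  sp <- matrix(rnorm(F * M), F, M)
  tp <- matrix(rnorm(U * M), U, M)
  w <- matrix(rnorm(M * N), M, N)
  m <- lnModel(sp, tp, w); m@identityOut <- TRUE
  S <- matrix(rnorm(F * T), F, T)
  pred <- predictRate(m, spectrogram(S, 100))
  brute <- matrix(0, N, T)
  for (i in seq_len(N)) for (t in seq_len(T)) {
    acc <- 0
    for (mm in seq_len(M)) {
      rm <- 0
      for (f in seq_len(F)) for (u in 0:(U - 1))
        if (t - u >= 1) rm <- rm + sp[f, mm] * tp[u + 1, mm] * S[f, t - u]
      acc <- acc + w[mm, i] * rm
    }
    brute[i, t] <- acc
  }
  expect_lt(max(abs(pred - brute)) / max(abs(brute)), 1e-6)
})

test_that("LN impulse response traces the rank-1 filter and is linear pre-NL", {
  F <- 6L; U <- 4L; T <- 20L
  phi <- c(0.2, -1, 0.5, 2, 0, 1)
  tau <- c(1, 0.5, -0.3, 0.1)
  m <- lnModel(matrix(phi, F, 1), matrix(tau, U, 1), matrix(1, 1, 1))
  m@identityOut <- TRUE
  f0 <- 3L; t0 <- 8L
  S <- matrix(0, F, T); S[f0, t0] <- 1
  r <- predictRate(m, spectrogram(S, 100))[1, ]
  expect_equal(r[t0:(t0 + U - 1)], phi[f0] * tau, tolerance = 1e-12)
  expect_true(all(r[-(t0:(t0 + U - 1))] == 0))
  ## additivity of the linear stage
  set.seed(1)
  S1 <- matrix(rnorm(F * T), F, T); S2 <- matrix(rnorm(F * T), F, T)
  m2 <- tinyLN(F = F, U = U)
  z1 <- linearResponse(m2, spectrogram(S1, 100))
  z2 <- linearResponse(m2, spectrogram(S2, 100))
  z12 <- linearResponse(m2, spectrogram(S1 + S2, 100))
  expect_equal(z12, z1 + z2, tolerance = 1e-10)
})

test_that("LN model rejects a channel-count mismatch", {
  m <- tinyLN(F = 6L)
  expect_error(predictRate(m, tinySpectrogram(F = 5L)), "channels")
})

test_that("stored rank-1 structure matches materialized filters", {
  m <- tinyLN(F = 6L, U = 4L, M = 3L)
  h <- lnFilters(m, 2)
  expect_equal(h, outer(m@spectral[, 2], m@temporal[, 2]))
  expect_equal(qr(h)$rank, 1L)
})

test_that("CNN forward matches an explicit per-frame loop", {
  F <- 6L; T <- 30L
  cnn <- tinyCNN(N = 2L, F = F)
  st <- tinySpectrogram(F = F, T = T, seed = 2)
  S <- specValues(st)
  pred <- predictRate(cnn, st)
  d <- cnn@dims
  h1at <- function(tt) vapply(seq_len(d[["C1"]]), function(c1) {
    z <- cnn@b1[c1]
    for (k in seq_len(d[["K1"]])) if (tt - k + 1 >= 1)
      for (f in seq_len(F)) z <- z + cnn@W1[(k - 1) * F + f, c1] * S[f, tt - k + 1]
    max(z, 0)
  }, 0)
  loopOut <- matrix(0, 2, T)
  for (t in seq_len(T)) {
    h2 <- vapply(seq_len(d[["C2"]]), function(c2) {
      z <- cnn@b2[c2]
      for (k in seq_len(d[["K2"]])) if (t - k + 1 >= 1) {
        hh <- h1at(t - k + 1)
        for (c1 in seq_len(d[["C1"]]))
          z <- z + cnn@W2[(k - 1) * d[["C1"]] + c1, c2] * hh[c1]
      }
      max(z, 0)
    }, 0)
    h3 <- pmax(as.numeric(t(cnn@W3) %*% h2 + cnn@b3), 0)
    z4 <- as.numeric(t(cnn@W4) %*% h3 + cnn@b4)
    loopOut[, t] <- doubleExponential(matrix(z4, 1), cnn@outNL)
  }
  expect_lt(max(abs(pred - loopOut)) / max(abs(loopOut)), 1e-6)
})

test_that("CNN output is causal with footprint K1 + K2 - 1", {
  cnn <- tinyCNN(N = 1L, F = 6L, K1 = 3L, K2 = 2L)
  st <- tinySpectrogram(F = 6L, T = 40L, seed = 9)
  base <- predictRate(cnn, st)
  ## perturbing the final frame leaves all earlier outputs bit-identical
  S2 <- specValues(st); S2[, 40] <- S2[, 40] + 5
  pert <- predictRate(cnn, spectrogram(S2, 100))
  expect_identical(pert[, 1:39], base[, 1:39])
  ## perturbations older than the architecture footprint never propagate
  foot <- 3L + 2L - 1L
  S3 <- specValues(st); S3[, 10] <- S3[, 10] + 5
  pert2 <- predictRate(cnn, spectrogram(S3, 100))
  expect_identical(pert2[, (10 + foot):40], base[, (10 + foot):40])
  expect_false(identical(pert2[, 10:(10 + foot - 1)], base[, 10:(10 + foot - 1)]))
})

test_that("zero stimulus yields the constant nonlinearity output", {
  cnn <- tinyCNN(N = 2L, F = 6L)
  cnn@b1[] <- 0; cnn@b2[] <- 0; cnn@b3[] <- 0; cnn@b4[] <- 0
  st <- spectrogram(matrix(0, 6, 15), 100)
  pred <- predictRate(cnn, st)
  expect_equal(unname(pred[, 1]),
               as.numeric(doubleExponential(matrix(0, 1, 2), cnn@outNL)),
               tolerance = 1e-12)
  expect_true(all(abs(pred - pred[, 1]) < 1e-12))
})

test_that("polynomial readout equals the explicit double-loop sum", {
  set.seed(11)
  n <- 3L; T <- 25L
  v <- rnorm(n); W <- matrix(rnorm(n * n), n); W <- (W + t(W)) / 2
  X <- matrix(rnorm(n * T), n, T)
  pr <- polyReadout(2L, v, W, r0 = 0.5)
  r <- polyReadoutForward(pr, X)
  ref <- vapply(seq_len(T), function(t) {
    s <- 0.5
    for (i in seq_len(n)) {
      s <- s + v[i] * X[i, t]
      for (j in seq_len(n)) s <- s + W[i, j] * X[i, t] * X[j, t]
    }
    s
  }, 0)
  expect_lt(max(abs(r - ref)), 1e-10)
  ## order 1 is exactly affine; identity readout returns a projection row
  pid <- polyReadout(1L, v = c(1, 0, 0))
  expect_equal(polyReadoutForward(pid, X), X[1, ], tolerance = 1e-14)
  ## quadrature energy form
  pq <- polyReadout(2L, v = c(0, 0), W = diag(2))
  X2 <- X[1:2, ]
  expect_equal(polyReadoutForward(pq, X2), X2[1, ]^2 + X2[2, ]^2,
               tolerance = 1e-12)
  ## order-1 validity forbids nonzero W
  expect_error(polyReadout(1L, v = c(1, 0), W = diag(2)), "zero W")
})
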