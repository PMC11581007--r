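makeStack <- function(X, F, U) {
  new("DSTRFStack", filters = array(X, c(nrow(X), F, U)),
      times = seq_len(nrow(X)), maxLag = as.integer(U), stride = 1L,
      modelId = "test")
}

test_that("PCA subspace recovers rank-1 and rank-2 stacks exactly", {
  F <- 8L; U <- 5L; T <- 60L
  set.seed(10)
  g <- matrix(rnorm(F * U), F, U); g <- g / sqrt(sum(g^2))
  alpha <- rnorm(T)
  stack1 <- makeStack(alpha %o% as.vector(g), F, U)
  sub1 <- pcaSubspace(stack1, 0.9)
  expect_equal(ncol(filters(sub1)), 1L)
  expect_gt(abs(sum(filters(sub1)[, 1] * as.vector(g))), 1 - 1e-10)
  ev <- explainedVariance(sub1)
  expect_gt(ev[1], 1 - 1e-10)
  ## two orthogonal filters with random coefficients -> plane recovered
  g2 <- matrix(rnorm(F * U), F, U)
  g2v <- as.vector(g2) - sum(g2 * g) * as.vector(g)
  g2v <- g2v / sqrt(sum(g2v^2))
  A <- cbind(as.vector(g), g2v)
  coefs <- matrix(rnorm(2 * T), T, 2)
  stack2 <- makeStack(coefs %*% t(A), F, U)
  sub2 <- pcaSubspace(stack2, 0.99)
  expect_equal(ncol(filters(sub2)), 2L)
  ang <- subspaceRecoveryError(A, sub2)
  expect_lt(max(ang), 1e-6 * 180 / pi)
  ## explained variance is monotone nondecreasing and ends at 1
  set.seed(11)
  stack3 <- makeStack(matrix(rnorm(T * F * U), T), F, U)
  ev3 <- explainedVariance(pcaSubspace(stack3, 0.5))
  expect_true(all(diff(ev3) >= -1e-12))
  expect_equal(ev3[length(ev3)], 1, tolerance = 1e-9)
  ## orthonormality and energy capture at the threshold
  sub3 <- pcaSubspace(stack3, 0.9)
  G <- filters(sub3)
  expect_lt(max(abs(crossprod(G) - diag(ncol(G)))), 1e-8)
  X3 <- matrix(stack3@filters, T, F * U)
  recon <- X3 %*% G %*% t(G)
  expect_gte(sum(recon^2) / sum(X3^2), 0.9 - 1e-9)
  expect_error(pcaSubspace(makeStack(matrix(0, 5, F * U), F, U)),
               "degenerate")
})

test_that("sign convention puts the largest-magnitude coefficient positive", {
  F <- 4L; U <- 3L
  set.seed(12)
  stack <- makeStack(matrix(rnorm(40 * F * U), 40), F, U)
  G <- filters(pcaSubspace(stack, 0.99))
  for (j in seq_len(ncol(G))) expect_gt(G[which.max(abs(G[, j])), j], 0)
})

test_that("stimulus projection is the causal filter correlate", {
  F <- 6L; U <- 4L; T <- 30L
  set.seed(13)
  g <- matrix(rnorm(F * U), F, U); g <- g / sqrt(sum(g^2))
  sub <- new("TuningSubspace", filters = matrix(as.vector(g), ncol = 1),
             explainedVariance = 1, varThreshold = 0.9, F = F, U = U,
             id = "t")
  ## impulse at (f0, t0) traces g(f0, t - t0) over lags
  f0 <- 2L; t0 <- 10L
  S <- matrix(0, F, T); S[f0, t0] <- 1
  x <- projections(projectStimulus(sub, S))[1, ]
  expect_equal(x[t0:(t0 + U - 1)], g[f0, ], tolerance = 1e-12)
  expect_true(all(x[-(t0:(t0 + U - 1))] == 0))
  ## zero stimulus -> zero projections; additivity
  expect_true(all(projections(projectStimulus(sub, matrix(0, F, T))) == 0))
  S1 <- matrix(rnorm(F * T), F, T); S2 <- matrix(rnorm(F * T), F, T)
  p1 <- projections(projectStimulus(sub, S1))
  p2 <- projections(projectStimulus(sub, S2))
  p12 <- projections(projectStimulus(sub, S1 + S2))
  expect_equal(p12, p1 + p2, tolerance = 1e-10)
  ## brute-force oracle on a random stimulus
  xb <- vapply(seq_len(T), function(t) {
    acc <- 0
    for (f in seq_len(F)) for (u in 0:(U - 1))
      if (t - u >= 1) acc <- acc + g[f, u + 1] * S1[f, t - u]
    acc
  }, 0)
  expect_equal(projections(projectStimulus(sub, S1))[1, ], xb,
               tolerance = 1e-10)
  expect_error(projectStimulus(sub, matrix(0, F + 1, T)), "channels")
})

test_that("tuning surfaces respect marginalization and occupancy flags", {
  set.seed(14)
  T <- 20000L
  X <- matrix(rnorm(2 * T), 2, T)
  ## rate depends only on dim 1 -> surface constant along dim 2
  rate <- tanh(X[1, ])
  surf <- estimateTuningSurface(X, rate, dims = c(1, 2), nBins = 10,
                                minOccupancy = 10)
  mr <- surf@meanRate
  for (i in seq_len(10)) {
    row <- mr[i, !is.na(mr[i, ])]
    if (length(row) > 3) {
      se <- sd(rate) / sqrt(min(surf@occupancy[i, surf@occupancy[i, ] > 0]))
      expect_lt(max(row) - min(row), 6 * se + 1e-9)
    }
  }
  ## quadrature-energy rate -> radially symmetric surface
  rateE <- exp(-0.3 * (X[1, ]^2 + X[2, ]^2))
  surfE <- estimateTuningSurface(X, rateE, dims = c(1, 2), nBins = 15,
                                 minOccupancy = 20)
  ctr <- lapply(surfE@edges, function(e) (head(e, -1) + tail(e, -1)) / 2)
  rad <- sqrt(outer(ctr[[1]]^2, ctr[[2]]^2, "+"))
  occ <- !is.na(surfE@meanRate)
  rb <- cut(rad[occ], 6)
  withinVar <- mean(tapply(surfE@meanRate[occ], rb, var), na.rm = TRUE)
  totalVar <- var(surfE@meanRate[occ])
  expect_lt(withinVar / totalVar, 0.10)
  ## low-occupancy bins flagged empty
  Xs <- matrix(c(rep(0, 99), 5), 1, 100) + matrix(rnorm(100, sd = 0.1), 1)
  surf1 <- estimateTuningSurface(Xs, rnorm(100), dims = 1, nBins = 10,
                                 span = 1, minOccupancy = 5)
  expect_true(any(is.na(surf1@meanRate) & surf1@occupancy > 0 &
                    surf1@occupancy < 5) ||
                all(surf1@occupancy[is.na(surf1@meanRate)] < 5))
})

test_that("site-pooled subspaces combine stacks from several neurons", {
  F <- 6L; U <- 3L
  set.seed(15)
  g1 <- rnorm(F * U); g1 <- g1 / sqrt(sum(g1^2))
  g2v <- rnorm(F * U); g2v <- g2v - sum(g2v * g1) * g1
  g2v <- g2v / sqrt(sum(g2v^2))
  s1 <- makeStack(rnorm(30) %o% g1, F, U)
  s2 <- makeStack(rnorm(30) %o% g2v, F, U)
  sub <- siteSubspace(list(s1, s2), 0.99)
  expect_equal(sub@id, "site")
  expect_equal(ncol(filters(sub)), 2L)
  ang <- subspaceRecoveryError(cbind(g1, g2v), sub)
  expect_lt(max(ang), 1e-6)
})
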