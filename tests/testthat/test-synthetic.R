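test_that("stimulus generation is seeded and controls modulation content", {
  s1 <- generateStimulus("smoothed_noise", T = 300L, seed = 21)
  s2 <- generateStimulus("smoothed_noise", T = 300L, seed = 21)
  expect_identical(specValues(s1), specValues(s2))
  expect_false(identical(specValues(s1),
                         specValues(generateStimulus("smoothed_noise",
                                                     T = 300L, seed = 22))))
  ## zero-depth ripple -> constant spectrogram
  s0 <- generateStimulus("ripple_mixture", T = 200L,
                         params = list(depth = 0), seed = 1)
  expect_true(all(specValues(s0) == 0))
  ## stated ripple appears as the modulation power peak
  rip <- data.frame(wtHz = 8, wfCycPerOct = 1, amp = 1, phase = 0)
  sr <- generateStimulus("ripple_mixture", T = 240L,
                         params = list(ripples = rip), seed = 2)
  win <- specValues(sr)[, 1:32]          # F x U window as a "filter"
  mps <- modulationPowerSpectrum(win, frameRate = 100,
                                 octavesPerChannel = 6.64 / 31)
  nz <- mps$power
  nz[abs(mps$temporalHz) < 1e-9 & abs(mps$spectralCycPerOct) < 1e-9] <- 0
  peak <- which(nz == max(nz), arr.ind = TRUE)
  expect_lt(abs(abs(mps$temporalHz[peak[1, 2]]) - 8), 100 / 32)
  ## segment-sequence stimulus spans heterogeneous blocks
  ss <- generateStimulus("segment_sequence", T = 500L,
                         params = list(blockLen = 100L), seed = 3)
  blockSd <- vapply(1:5, function(b)
    sd(specValues(ss)[, (b - 1) * 100 + 1:100]), 0)
  expect_gt(max(blockSd) / min(blockSd), 1.5)
})

test_that("combination rules produce the stated responses", {
  qp <- quadraturePair(F = 32L, U = 25L)
  ## energy kind holds a unit-norm quadrature pair
  en <- groundTruthNeuron("energy", qp)
  expect_equal(sqrt(colSums(en@filters^2)), c(1, 1), tolerance = 1e-10)
  ## linear neuron on zero stimulus: constant dexp(0) * rateScale
  lin <- groundTruthNeuron("linear", qp[1])
  z <- spectrogram(matrix(0, 32, 60), 100)
  r0 <- trueRate(lin, z)
  expect_true(all(abs(r0 - r0[1]) < 1e-12))
  expect_equal(r0[1], 50 * doubleExponential(0, lin@outNL), tolerance = 1e-9)
  ## energy neuron with an exact quadrature pair is phase invariant: a
  ## quarter-cycle shift of a matched ripple leaves the rate unchanged
  F <- 32L; U <- 25L
  wf <- 2 / F; wt <- 5 / U
  fb <- matrix(seq_len(F), F, U); ub <- matrix(seq_len(U), F, U, byrow = TRUE)
  gC <- cos(2 * pi * (wf * fb + wt * ub)); gS <- sin(2 * pi * (wf * fb + wt * ub))
  enQ <- groundTruthNeuron("energy", list(gC, gS))
  f <- matrix(seq_len(F), F, 400)
  tt <- matrix(seq_len(400), F, 400, byrow = TRUE)
  mkrip <- function(ph) spectrogram(cos(2 * pi * (wf * f + wt * tt) + ph), 100)
  rA <- trueRate(enQ, mkrip(0)); rB <- trueRate(enQ, mkrip(pi / 2))
  mid <- 50:350
  expect_lt(max(abs(rA[mid] - rB[mid])) / max(rA[mid]), 1e-6)
  ## gain control: energy on the suppressive axis only ever reduces the rate
  ## relative to the same neuron's unsuppressed drive
  gc <- groundTruthNeuron("gain_control", qp)
  sN <- generateStimulus("smoothed_noise", T = 2000L, seed = 31)
  rGC <- trueRate(gc, sN)
  X <- tunespace:::.truthProjections(gc, specValues(sN))
  rDrive <- gc@rateScale * doubleExponential(X[, 1], gc@outNL)
  expect_true(all(rGC <= rDrive + 1e-9))
  expect_lt(min(rGC / pmax(rDrive, 1e-12)), 0.5)   # suppression does bite
  expect_error(groundTruthNeuron("blob", qp), "unknown neuron kind")
})

test_that("Poisson rasters converge to the true rates", {
  neu <- groundTruthNeuron("linear", quadraturePair()[1])
  stim <- generateStimulus("smoothed_noise", T = 150L, seed = 33)
  ds <- simulatePopulation(list(neu), stim, nTrials = 10000L, seed = 7)
  fr <- frameRate(stim)
  counts <- ds@responses@rasters[[1]]
  lam <- ds@trueRates[1, ] / fr
  se <- sqrt(lam / 10000)
  z <- abs(colMeans(counts) - lam) / pmax(se, 1e-9)
  expect_gt(mean(z <= 3), 0.99)
  ## regeneration from the seed is bit-identical
  ds2 <- simulatePopulation(list(neu), stim, nTrials = 10000L, seed = 7)
  expect_identical(ds@responses@rasters, ds2@responses@rasters)
})

test_that("principal-angle recovery matches an SVD oracle", {
  set.seed(40)
  A <- qr.Q(qr(matrix(rnorm(50 * 2), 50)))
  expect_equal(subspaceRecoveryError(A, A), c(0, 0), tolerance = 1e-6)
  ## orthogonal complement -> 90 degrees
  Q <- qr.Q(qr(cbind(A, matrix(rnorm(50 * 2), 50))))
  B <- Q[, 3:4]
  expect_equal(subspaceRecoveryError(A, B), c(90, 90), tolerance = 1e-6)
  ## random pair in high dimension: matches direct SVD computation
  C <- matrix(rnorm(50 * 2), 50)
  ang <- subspaceRecoveryError(A, C)
  qa <- qr.Q(qr(A)); qc <- qr.Q(qr(C))
  oracle <- sort(acos(pmin(pmax(svd(t(qa) %*% qc)$d, -1), 1)) * 180 / pi)
  expect_equal(ang, oracle, tolerance = 1e-8)
  expect_gt(min(ang), 45)
})
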