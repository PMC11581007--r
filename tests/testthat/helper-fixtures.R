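# Small deterministic fixtures built in code.

tinySpectrogram <- function(F = 6L, T = 40L, seed = 1L) {
  set.seed(seed)
  spectrogram(matrix(rnorm(F * T), F, T), frameRate = 100)
}

tinyCNN <- function(N = 2L, F = 6L, K1 = 3L, C1 = 4L, K2 = 2L, C2 = 3L,
                    D3 = 3L, seed = 7L) {
  m <- initPopulationCNN(populationCNN(N, F = F, K1 = K1, C1 = C1, K2 = K2,
                                       C2 = C2, D3 = D3), seed = seed)
  m@outNL <- doubleExpParams(b = seq(0.1, by = 0.1, length.out = N),
                             a = rep(1.5, N), s = rep(0.2, N),
                             k = rep(1.2, N))
  m
}

tinyLN <- function(N = 2L, F = 6L, U = 4L, M = 3L, seed = 3L) {
  set.seed(seed)
  lnModel(matrix(rnorm(F * M), F, M), matrix(rnorm(U * M), U, M),
          matrix(rnorm(M * N), M, N),
          outNL = doubleExpParams(b = rep(0.1, N), a = rep(1, N),
                                  s = rep(0, N), k = rep(0.8, N)))
}

# tone segment with crossfade margin
toneSegment <- function(freq, durationMs, rate = 16000, marginMs = 40,
                        amp = 0.5, sourceId = "tone", category = "") {
  n <- round((durationMs + marginMs) / 1000 * rate)
  w <- amp * sin(2 * pi * freq * seq_len(n) / rate)
  segmentRecord(sourceId, durationMs, w, rate, category = category)
}

noiseSegment <- function(durationMs, rate = 16000, marginMs = 40, amp = 0.3,
                         sourceId = "noise", category = "", seed = 1L) {
  set.seed(seed)
  n <- round((durationMs + marginMs) / 1000 * rate)
  segmentRecord(sourceId, durationMs, amp * rnorm(n) / 3, rate,
                category = category)
}

# orthonormal zero-mean 2-D Fourier filters on an F x U grid
fourierFilterSet <- function(n = 4L, F = 32L, U = 25L) {
  f <- matrix(seq_len(F), F, U)
  u <- matrix(seq_len(U), F, U, byrow = TRUE)
  specs <- list(c(1, 0), c(0, 1), c(1, 1), c(2, 1), c(1, 2), c(2, 2))
  lapply(seq_len(n), function(i) {
    kf <- specs[[i]][1]; ku <- specs[[i]][2]
    g <- cos(2 * pi * (kf * f / F + ku * u / U))
    g / sqrt(sum(g^2))
  })
}
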