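test_that("gammatone spectrogram honors the silence, tone and frame-count contracts", {
  p <- frontendParams(fHigh = 7000)
  rate <- 16000
  ## digital silence -> constant log(logFloor)
  s0 <- gammatoneSpectrogram(numeric(rate), rate, p)
  expect_true(all(abs(specValues(s0) - log(p@logFloor)) < 1e-12))
  ## 2.0 s at 100 Hz -> exactly 200 frames
  s2 <- gammatoneSpectrogram(numeric(2 * rate), rate, p)
  expect_identical(ncol(specValues(s2)), 200L)
  ## 1 kHz tone peaks in the channel nearest 1 kHz
  tone <- sin(2 * pi * 1000 * seq_len(rate) / rate)
  st <- gammatoneSpectrogram(tone, rate, p)
  nearest <- which.min(abs(centerFreqs(st) - 1000))
  peaks <- apply(specValues(st)[, 5:95], 2, which.max)
  expect_true(all(peaks == nearest))
  ## determinism: frames are a pure function of the waveform
  expect_identical(specValues(st),
                   specValues(gammatoneSpectrogram(tone, rate, p)))
})

test_that("gammatone frontend rejects sample rates below Nyquist for fHigh", {
  expect_error(gammatoneSpectrogram(numeric(1000), 16000, frontendParams()),
               "Nyquist")
})

test_that("excitation patterns are gain-invariant and separate tone from noise", {
  rate <- 16000
  set.seed(5)
  tone <- sin(2 * pi * 2000 * seq_len(3200) / rate)
  noise <- rnorm(3200)
  epT <- excitationPattern(tone, rate)
  epT2 <- excitationPattern(tone, rate)
  expect_equal(cor(epT, epT2), 1.0)
  ## scaling preserves pattern shape exactly
  epHalf <- excitationPattern(0.5 * tone, rate)
  expect_equal(cor(epT, epHalf), 1.0, tolerance = 1e-12)
  ## narrowband vs broadband dissimilar
  epN <- excitationPattern(noise, rate)
  expect_lt(cor(epT, epN), 0.8)
  ## all-zero segment -> zero vector, not an error
  expect_true(all(excitationPattern(numeric(100), rate) == 0))
})

test_that("segment pool filtering applies all four rejection rules", {
  rate <- 16000
  segs <- list(
    toneSegment(500, 50, rate, sourceId = "recA", category = "music"),
    toneSegment(505, 50, rate, sourceId = "recA", category = "music"),  # same rec, r ~ 1
    toneSegment(3000, 50, rate, sourceId = "recB", category = "speech"),
    noiseSegment(50, rate, sourceId = "recC", seed = 2)
  )
  ## quiet duplicate: 30 dB below recB's max-power frame
  quiet <- toneSegment(3000, 50, rate, amp = 0.5 * 10^(-30 / 20), sourceId = "recB")
  res <- filterSegmentPool(c(segs, list(quiet)), seed = 1)
  expect_equal(res$log$rule[res$log$sourceId == "recA"],
               "same-recording similarity")
  expect_gt(res$log$rValue[res$log$rule == "same-recording similarity"], 0.8)
  expect_true("power floor" %in% res$log$rule)
  ## power-floor rejects before any similarity bookkeeping: removing the
  ## quiet candidate changes nothing downstream
  res2 <- filterSegmentPool(segs, seed = 1)
  expect_identical(vapply(res2$accepted, function(x) x$sourceId, ""),
                   vapply(res$accepted, function(x) x$sourceId, ""))
  ## category cap: one of five accepted (20%) blocks the next of that category
  base <- lapply(1:5, function(i)
    toneSegment(400 * i + 100, 50, rate, sourceId = paste0("r", i),
                category = if (i == 1) "music" else paste0("c", i)))
  nxt <- toneSegment(5100, 50, rate, sourceId = "r9", category = "music")
  res3 <- filterSegmentPool(c(base, list(nxt)), seed = 1)
  expect_true(any(res3$log$rule == "category cap" & res3$log$sourceId == "r9"))
})

test_that("sequence assembly hits the target duration with unity-gain crossfades", {
  rate <- 16000
  spec <- sequenceSpec(composition = c(`50` = 3, `110` = 2), roveDb = 0)
  segs <- c(lapply(1:3, function(i) {
    n <- round(0.09 * rate)
    segmentRecord(paste0("c", i), 50, rep(0.25, n), rate,
                  excitation = numeric(32))
  }), lapply(1:2, function(i) {
    n <- round(0.15 * rate)
    segmentRecord(paste0("d", i), 110, rep(0.25, n), rate,
                  excitation = numeric(32))
  }))
  out <- assembleSequence(segs, spec, seed = 4)
  nominal <- (3 * 50 + 2 * 110 + 50 + 110) / 1000   # incl. one silence each
  expect_equal(length(out$wave) / rate, nominal + 0.010, tolerance = 1e-6)
  ## constant-amplitude material: no dip at interior crossfades between
  ## two sound segments (complementary ramps sum to 1)
  man <- out$manifest
  sound <- man[man$sourceId != "silence", ]
  sound <- sound[order(sound$position), ]
  pos <- man$position
  for (i in seq_len(nrow(man) - 1)) {
    a <- man[i, ]; b <- man[i + 1, ]
    if (a$sourceId == "silence" || b$sourceId == "silence") next
    ov <- b$startSample:(b$startSample + round(0.010 * rate) - 1)
    expect_true(max(abs(abs(out$wave[ov]) - 0.25)) < 1e-12)
  }
  ## seeded determinism: bit-identical waveform and manifest
  out2 <- assembleSequence(segs, spec, seed = 4)
  expect_identical(out$wave, out2$wave)
  expect_identical(out$manifest, out2$manifest)
  ## different seed, different order or gains
  out3 <- assembleSequence(segs, sequenceSpec(composition = c(`50` = 3, `110` = 2)),
                           seed = 5)
  expect_false(identical(out3$wave, out$wave))
})

test_that("sequence assembly reports shortfalls by duration", {
  rate <- 16000
  segs <- list(segmentRecord("a", 50, rep(0.1, round(0.09 * rate)), rate,
                             excitation = numeric(32)))
  expect_error(assembleSequence(segs, sequenceSpec(composition = c(`50` = 2)),
                                seed = 1),
               "insufficient segments")
})

test_that("default sequence spec reproduces the 17.79-s composition", {
  spec <- sequenceSpec()
  durs <- as.numeric(names(spec$composition))
  totalMs <- sum(durs * spec$composition) + sum(durs) * spec$silencePerDuration
  expect_equal(totalMs / 1000, spec$targetDurationS, tolerance = 1e-9)
})

test_that("WAV round trip preserves samples at 16-bit precision", {
  w <- sin(2 * pi * 440 * seq_len(1600) / 16000) * 0.8
  path <- tempfile(fileext = ".wav")
  writeWav(w, 16000, path)
  back <- readWav(path)
  expect_equal(back$rate, 16000)
  expect_lt(max(abs(back$samples - w)), 1 / 32767)
  expect_error(readWav(tempfile(fileext = ".wav")), "not found")
})
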