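## Natural-segment stimulus construction: candidate filtering by excitation
## pattern diversity and crossfaded sequence assembly with level roving.

segmentDurationsMs <- c(50, 110, 190, 420, 780)

#' Create a stimulus segment record
#'
#' @param sourceId identifier of the recording the segment came from.
#' @param durationMs nominal segment duration, one of 50/110/190/420/780 ms
#'   (the raw waveform carries an extra margin consumed by crossfading).
#' @param waveform audio samples.
#' @param rate sample rate, Hz.
#' @param category optional content-category label ("" when unlabeled).
#' @param excitation excitation pattern (computed from the waveform when
#'   omitted).
#' @param power mean-square power of the segment (computed when omitted).
#' @return a list of class \code{SegmentRecord}.
#' @export
segmentRecord <- function(sourceId, durationMs, waveform, rate,
                          category = "", excitation = NULL, power = NULL) {
  stopifnotMsg(durationMs %in% segmentDurationsMs,
               paste("durationMs must be one of", paste(segmentDurationsMs, collapse = "/")))
  if (is.null(excitation) && any(waveform != 0))
    excitation <- excitationPattern(waveform, rate)
  if (is.null(excitation)) excitation <- numeric(32)
  if (is.null(power)) power <- mean(waveform^2)
  structure(list(sourceId = sourceId, category = category,
                 durationMs = durationMs, waveform = waveform, rate = rate,
                 excitation = as.numeric(excitation), power = power),
            class = "SegmentRecord")
}

#' Filter a candidate segment stream for diversity
#'
#' Applies the four selection rules to an ordered stream of candidate
#' segments: (1) power floor: candidates whose power falls more than
#' \code{powerFloorDb} below the maximum power of any candidate from the same
#' recording are discarded before selection; (2) same-recording similarity:
#' a candidate whose excitation pattern correlates above
#' \code{maxSimilarity} with a previously accepted segment from the same
#' recording is rejected; (3) global similarity: a candidate similar
#' (r > \code{maxSimilarity}) to more than \code{maxSimilarFrac} of
#' previously accepted segments (measured on a seeded random sample of up to
#' \code{similaritySample} of them) is rejected; (4) category cap: a
#' candidate whose category already makes up at least \code{categoryCap} of
#' the accepted set is rejected.
#'
#' @param candidates list of \code{SegmentRecord}s, in stream order.
#' @param maxSimilarity excitation-pattern correlation threshold (default 0.8).
#' @param maxSimilarFrac maximum tolerated fraction of similar previously
#'   accepted segments (default 0.05).
#' @param similaritySample number of previously accepted segments sampled for
#'   the global similarity check (default 10000).
#' @param powerFloorDb power floor below the per-recording maximum, dB
#'   (default 25).
#' @param categoryCap maximum fraction of the accepted set a single category
#'   may occupy (default 0.2).
#' @param seed seed for the similarity subsampling.
#' @return list with \code{accepted} (list of records) and \code{log}
#'   (data.frame sourceId, category, rule, rValue for every rejected
#'   candidate).
#' @export
filterSegmentPool <- function(candidates, maxSimilarity = 0.8,
                              maxSimilarFrac = 0.05, similaritySample = 10000L,
                              powerFloorDb = 25, categoryCap = 0.2,
                              seed = 1L) {
  srcs <- vapply(candidates, function(x) x$sourceId, "")
  pows <- vapply(candidates, function(x) x$power, 0)
  maxPow <- tapply(pows, srcs, max)
  accepted <- list()
  accSrc <- character(); accCat <- character()
  excMat <- NULL   # accepted excitation patterns, one column each
  log <- list()
  reject <- function(cand, rule, r) {
    log[[length(log) + 1L]] <<- data.frame(
      sourceId = cand$sourceId, category = cand$category,
      rule = rule, rValue = r, stringsAsFactors = FALSE)
  }
  rng <- substreamSeed(seed, "segment-pool")
  withSeed(rng, {
    for (cand in candidates) {
      ## rule: power floor (pre-selection discard)
      if (10 * log10(cand$power / maxPow[[cand$sourceId]]) < -powerFloorDb) {
        reject(cand, "power floor", NA_real_)
        next
      }
      nAcc <- length(accepted)
      if (nAcc > 0L) {
        ## rule: same-recording similarity
        same <- which(accSrc == cand$sourceId)
        if (length(same)) {
          rs <- apply(excMat[, same, drop = FALSE], 2, safeCor, b = cand$excitation)
          if (any(rs > maxSimilarity, na.rm = TRUE)) {
            reject(cand, "same-recording similarity", max(rs, na.rm = TRUE))
            next
          }
        }
        ## rule: global similarity to sampled previously accepted segments
        idx <- if (nAcc > similaritySample)
          sample.int(nAcc, similaritySample) else seq_len(nAcc)
        rs <- apply(excMat[, idx, drop = FALSE], 2, safeCor, b = cand$excitation)
        frac <- mean(rs > maxSimilarity, na.rm = TRUE)
        if (is.finite(frac) && frac > maxSimilarFrac) {
          reject(cand, "global similarity", max(rs, na.rm = TRUE))
          next
        }
        ## rule: category cap
        if (nzchar(cand$category) &&
            sum(accCat == cand$category) / nAcc >= categoryCap) {
          reject(cand, "category cap", NA_real_)
          next
        }
      }
      accepted[[nAcc + 1L]] <- cand
      accSrc <- c(accSrc, cand$sourceId)
      accCat <- c(accCat, cand$category)
      excMat <- cbind(excMat, cand$excitation)
    }
  })
  log <- if (length(log)) do.call(rbind, log) else
    data.frame(sourceId = character(), category = character(),
               rule = character(), rValue = numeric())
  list(accepted = accepted, log = log)
}

#' Write a segment rejection log as TSV
#' @param log rejection log data.frame from \code{\link{filterSegmentPool}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeRejectionLog <- function(log, path) {
  write.table(log, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Sequence composition specification
#'
#' Defaults give the standard 17.79-s sequence: 64/32/16/8/4 segments of
#' 50/110/190/420/780 ms plus one silent segment per duration, random order,
#' per-segment level roved uniformly over a 20-dB range, 10-ms raised-cosine
#' crossfades.
#'
#' @param composition named count vector, names are durations in ms.
#' @param silencePerDuration silent segments per duration.
#' @param roveDb total level-rove range, dB (gains drawn uniformly on
#'   [-roveDb/2, +roveDb/2]).
#' @param crossfadeMs crossfade length, ms.
#' @param targetDurationS nominal sequence duration, s.
#' @return list of class \code{SequenceSpec}.
#' @export
sequenceSpec <- function(composition = c(`50` = 64, `110` = 32, `190` = 16,
                                         `420` = 8, `780` = 4),
                         silencePerDuration = 1L, roveDb = 20,
                         crossfadeMs = 10, targetDurationS = 17.79) {
  stopifnotMsg(all(composition > 0), "composition counts must be positive")
  durs <- as.numeric(names(composition))
  stopifnotMsg(crossfadeMs < min(durs), "crossfade must be shorter than the shortest segment")
  structure(list(composition = composition,
                 silencePerDuration = as.integer(silencePerDuration),
                 roveDb = roveDb, crossfadeMs = crossfadeMs,
                 targetDurationS = targetDurationS),
            class = "SequenceSpec")
}

#' Assemble a crossfaded stimulus sequence
#'
#' Draws the required number of segments per duration, appends one silent
#' segment per duration, shuffles the order, roves each segment's level
#' uniformly over the spec's dB range, and overlap-adds the segments with
#' complementary raised-cosine crossfade ramps (the rising and falling ramps
#' sum to exactly 1 at every overlap sample, so constant-amplitude material
#' crossfades without an envelope dip). Each segment contributes its nominal
#' duration; its waveform must carry at least one crossfade of extra margin.
#'
#' @param segments list of \code{SegmentRecord}s (all at one sample rate).
#' @param spec a \code{\link{sequenceSpec}}.
#' @param seed integer seed; the waveform and manifest are bit-identical
#'   across reruns with the same seed.
#' @return list with \code{wave} (numeric vector), \code{rate}, and
#'   \code{manifest} (data.frame: position, sourceId, durationMs, startSample,
#'   gainDb).
#' @export
assembleSequence <- function(segments, spec = sequenceSpec(), seed = 1L) {
  rate <- segments[[1]]$rate
  durTab <- vapply(segments, function(x) x$durationMs, 0)
  durs <- as.numeric(names(spec$composition))
  avail <- vapply(durs, function(d) sum(durTab == d), 0)
  short <- spec$composition - avail
  if (any(short > 0)) {
    bad <- which(short > 0)
    stop("insufficient segments: need ", paste(
      sprintf("%d more of %g ms", short[bad], durs[bad]), collapse = ", "))
  }
  cfN <- round(spec$crossfadeMs / 1000 * rate)
  withSeed(substreamSeed(seed, "assemble"), {
    chosen <- list()
    for (i in seq_along(durs)) {
      idx <- which(durTab == durs[i])[seq_len(spec$composition[i])]
      chosen <- c(chosen, segments[idx])
      for (k in seq_len(spec$silencePerDuration))
        chosen[[length(chosen) + 1L]] <- segmentRecord(
          "silence", durs[i], numeric(round(durs[i] / 1000 * rate) + cfN),
          rate, excitation = numeric(32), power = 0)
    }
    ord <- sample.int(length(chosen))
    chosen <- chosen[ord]
    gains <- runif(length(chosen), -spec$roveDb / 2, spec$roveDb / 2)
  })
  nomN <- vapply(chosen, function(x) as.integer(round(x$durationMs / 1000 * rate)), 0L)
  total <- sum(nomN) + cfN
  wave <- numeric(total)
  rise <- 0.5 * (1 - cos(pi * (seq_len(cfN) - 0.5) / cfN))
  start <- 0L
  manifest <- vector("list", length(chosen))
  for (i in seq_along(chosen)) {
    seg <- chosen[[i]]
    need <- nomN[i] + cfN
    if (length(seg$waveform) < need)
      stop("segment ", seg$sourceId, " lacks crossfade margin (",
           length(seg$waveform), " < ", need, " samples)")
    w <- seg$waveform[seq_len(need)] * dbToAmp(gains[i])
    w[seq_len(cfN)] <- w[seq_len(cfN)] * rise
    w[(need - cfN + 1L):need] <- w[(need - cfN + 1L):need] * rev(rise)
    wave[(start + 1L):(start + need)] <- wave[(start + 1L):(start + need)] + w
    manifest[[i]] <- data.frame(position = i, sourceId = seg$sourceId,
                                durationMs = seg$durationMs,
                                startSample = start + 1L, gainDb = gains[i],
                                stringsAsFactors = FALSE)
    start <- start + nomN[i]
  }
  list(wave = wave, rate = rate, manifest = do.call(rbind, manifest))
}
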