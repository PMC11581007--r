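## Model bundle serialization: one JSON file holding metadata and
## full-precision parameter arrays. load(save(m)) reproduces predictions
## exactly; a format-version mismatch is refused before any array is read.

bundleFormatVersion <- "1.0"

.arr <- function(a) {
  if (is.matrix(a) || is.array(a)) list(dim = dim(a), data = as.vector(a))
  else list(dim = length(a), data = as.vector(a))
}

.unarr <- function(l) {
  d <- unlist(l$dim)
  v <- as.numeric(unlist(l$data))
  if (length(d) > 1L) array(v, d) else v
}

.nl2list <- function(p) list(b = p@b, a = p@a, s = p@s, k = p@k)
.list2nl <- function(l) doubleExpParams(as.numeric(unlist(l$b)),
                                        as.numeric(unlist(l$a)),
                                        as.numeric(unlist(l$s)),
                                        as.numeric(unlist(l$k)))

.model2list <- function(model) {
  cls <- class(model)[1]
  out <- list(class = cls)
  if (cls == "LNModel") {
    out$arrays <- list(spectral = .arr(model@spectral),
                       temporal = .arr(model@temporal),
                       weights = .arr(model@weights))
  } else if (cls == "PopulationCNN") {
    out$dims <- as.list(model@dims)
    out$arrays <- list(W1 = .arr(model@W1), b1 = .arr(model@b1),
                       W2 = .arr(model@W2), b2 = .arr(model@b2),
                       W3 = .arr(model@W3), b3 = .arr(model@b3),
                       W4 = .arr(model@W4), b4 = .arr(model@b4))
  } else if (cls == "SubspaceReadout") {
    out$arrays <- list(W1 = .arr(model@W1), b1 = .arr(model@b1),
                       W2 = .arr(model@W2), b2 = .arr(model@b2),
                       W3 = .arr(model@W3), b3 = .arr(model@b3))
  } else if (cls == "PolyReadout") {
    out$order <- model@order
    out$arrays <- list(W = .arr(model@W), v = .arr(model@v), r0 = .arr(model@r0))
    out$outNL <- .nl2list(model@outNL)
    out$useOutNL <- model@useOutNL
    return(out)
  } else stop("cannot serialize class ", cls)
  out$outNL <- .nl2list(model@outNL)
  out$identityOut <- model@identityOut
  out$norm <- lapply(model@norm, function(x) if (is.numeric(x)) as.vector(x) else x)
  out
}

.list2model <- function(l) {
  cls <- l$class
  ar <- l$arrays
  if (cls == "PolyReadout") {
    m <- new("PolyReadout", order = as.integer(l$order),
             W = as.matrix(.unarr(ar$W)), v = .unarr(ar$v),
             r0 = as.numeric(.unarr(ar$r0)))
    if (!is.null(l$outNL)) m@outNL <- .list2nl(l$outNL)
    m@useOutNL <- isTRUE(l$useOutNL)
    return(m)
  }
  m <- if (cls == "LNModel") {
    lnModel(as.matrix(.unarr(ar$spectral)), as.matrix(.unarr(ar$temporal)),
            as.matrix(.unarr(ar$weights)))
  } else if (cls == "PopulationCNN") {
    d <- vapply(l$dims, as.integer, 0L)
    mm <- populationCNN(d[["N"]], d[["F"]], d[["K1"]], d[["C1"]], d[["K2"]],
                        d[["C2"]], d[["D3"]])
    mm@W1 <- as.matrix(.unarr(ar$W1)); mm@b1 <- .unarr(ar$b1)
    mm@W2 <- as.matrix(.unarr(ar$W2)); mm@b2 <- .unarr(ar$b2)
    mm@W3 <- as.matrix(.unarr(ar$W3)); mm@b3 <- .unarr(ar$b3)
    mm@W4 <- as.matrix(.unarr(ar$W4)); mm@b4 <- .unarr(ar$b4)
    mm
  } else if (cls == "SubspaceReadout") {
    mm <- subspaceReadout(nrow(as.matrix(.unarr(ar$W1))),
                          c(ncol(as.matrix(.unarr(ar$W1))),
                            ncol(as.matrix(.unarr(ar$W2)))))
    mm@W1 <- as.matrix(.unarr(ar$W1)); mm@b1 <- .unarr(ar$b1)
    mm@W2 <- as.matrix(.unarr(ar$W2)); mm@b2 <- .unarr(ar$b2)
    mm@W3 <- as.matrix(.unarr(ar$W3)); mm@b3 <- .unarr(ar$b3)
    mm
  } else stop("unknown model class in bundle: ", cls)
  m@outNL <- .list2nl(l$outNL)
  m@identityOut <- isTRUE(l$identityOut)
  m@norm <- lapply(l$norm, function(x)
    if (is.list(x) || is.numeric(x)) as.numeric(unlist(x)) else x)
  m
}

#' Save a model or jackknife ensemble as a bundle
#'
#' Writes a single JSON bundle with format version, class metadata and
#' full-precision parameter arrays.
#'
#' @param model an \linkS4class{EncodingModel}, \linkS4class{PolyReadout} or
#'   \linkS4class{JackknifeEnsemble}.
#' @param path output file path (.json).
#' @return \code{path}, invisibly.
#' @export
saveModelBundle <- function(model, path) {
  payload <- if (is(model, "JackknifeEnsemble")) {
    list(formatVersion = bundleFormatVersion, kind = "ensemble",
         foldMasks = model@foldMasks, cfg = model@cfg,
         members = lapply(model@members, .model2list))
  } else {
    list(formatVersion = bundleFormatVersion, kind = "model",
         model = .model2list(model))
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load a model bundle
#'
#' Checks the format version before reconstructing any parameter arrays and
#' refuses a mismatch explicitly.
#'
#' @param path bundle path from \code{\link{saveModelBundle}}.
#' @return the model or \linkS4class{JackknifeEnsemble}.
#' @export
loadModelBundle <- function(path) {
  if (!file.exists(path)) stop("bundle file not found: ", path)
  payload <- tryCatch(jsonlite::read_json(path),
                      error = function(e) stop("corrupt bundle at ", path, ": ",
                                               conditionMessage(e)))
  ver <- payload$formatVersion
  if (!identical(ver, bundleFormatVersion))
    stop("bundle format version mismatch: file has '", ver %||% "<missing>",
         "', this package reads '", bundleFormatVersion, "'")
  if (identical(payload$kind, "ensemble")) {
    membersL <- lapply(payload$members, .list2model)
    masks <- lapply(payload$foldMasks, function(m) as.integer(unlist(m)))
    new("JackknifeEnsemble", members = membersL, foldMasks = masks,
        diagnostics = data.frame(), cfg = payload$cfg %||% list())
  } else {
    .list2model(payload$model)
  }
}

#' Save a spectrogram as a plain-text bundle
#' @param s a \linkS4class{Spectrogram}.
#' @param path output file path (.json).
#' @return \code{path}, invisibly.
#' @export
saveSpectrogram <- function(s, path) {
  jsonlite::write_json(list(formatVersion = bundleFormatVersion,
                            kind = "spectrogram",
                            frameRate = s@frameRate,
                            centerFreqs = s@centerFreqs,
                            values = .arr(s@values)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a spectrogram bundle
#' @param path path from \code{\link{saveSpectrogram}}.
#' @return a \linkS4class{Spectrogram}.
#' @export
loadSpectrogram <- function(path) {
  if (!file.exists(path)) stop("spectrogram file not found: ", path)
  p <- jsonlite::read_json(path)
  if (!identical(p$formatVersion, bundleFormatVersion))
    stop("spectrogram bundle version mismatch")
  spectrogram(as.matrix(.unarr(p$values)),
              frameRate = as.numeric(p$frameRate),
              centerFreqs = as.numeric(unlist(p$centerFreqs)))
}
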