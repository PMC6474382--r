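#' @rdname EEGRecording-class
#' @export
setMethod("nSamples", "EEGRecording", function(x) nrow(x@signals))

#' @rdname EEGRecording-class
#' @export
setMethod("nChannels", "EEGRecording", function(x) ncol(x@signals))

#' @rdname EEGRecording-class
#' @export
setMethod("samplingRate", "EEGRecording", function(x) x@fs)

#' @rdname EEGRecording-class
#' @export
setMethod("channelNames", "EEGRecording", function(x) x@channels)

#' @rdname EEGRecording-class
#' @export
setMethod("signalMatrix", "EEGRecording", function(x) x@signals)

#' @rdname EEGRecording-class
#' @export
setMethod("artifactMask", "EEGRecording", function(x) x@mask)

#' @rdname EEGRecording-class
#' @export
setReplaceMethod("artifactMask", "EEGRecording", function(x, value) {
  x@mask <- value
  validObject(x)
  x
})

#' @rdname EEGRecording-class
#' @export
setMethod("duration", "EEGRecording",
          function(x) nrow(x@signals) / x@fs)

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf(
    "EEGRecording: %d channels x %d samples (%.1f s at %g Hz)\n",
    ncol(object@signals), nrow(object@signals),
    nrow(object@signals) / object@fs, object@fs))
  cat("  channels:", paste(object@channels, collapse = " "), "\n")
  cat(sprintf("  masked: %d samples (%.2f%%)\n",
              sum(object@mask),
              100 * mean(object@mask)))
})

#' Extract one channel as a numeric vector
#'
#' @param x an [EEGRecording-class].
#' @param channel channel label.
#' @return Numeric vector of samples (microvolt).
#' @export
channelSignal <- function(x, channel) {
  stopifnot(is(x, "EEGRecording"))
  if (!channel %in% x@channels)
    stop("channel '", channel, "' not present in recording")
  x@signals[, channel]
}
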