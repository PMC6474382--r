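#' @rdname Hypnogram-class
#' @export
setMethod("stages", "Hypnogram", function(x) x@stages)

#' @rdname Hypnogram-class
#' @export
setMethod("epochLength", "Hypnogram", function(x) x@epochLength)

#' @rdname Hypnogram-class
#' @export
setMethod("nEpochs", "Hypnogram", function(x) length(x@stages))

#' @rdname Hypnogram-class
#' @export
setMethod("duration", "Hypnogram",
          function(x) length(x@stages) * x@epochLength)

#' @rdname Hypnogram-class
#' @export
setMethod("stageAt", "Hypnogram", function(x, t) {
  idx <- pmin(pmax(floor(t / x@epochLength) + 1L, 1L), length(x@stages))
  out <- x@stages[idx]
  out[t < 0 | t >= length(x@stages) * x@epochLength] <- NA_character_
  out
})

setMethod("show", "Hypnogram", function(object) {
  tab <- table(factor(object@stages, levels = STAGE_LEVELS))
  cat(sprintf("Hypnogram: %d epochs of %g s (%.1f min)\n",
              length(object@stages), object@epochLength,
              length(object@stages) * object@epochLength / 60))
  cat("  ", paste(sprintf("%s:%d", names(tab), tab), collapse = " "), "\n")
})

#' Per-sample stage labels
#'
#' Expands a hypnogram to one stage label per EEG sample, for gating
#' analyses on the recording grid.
#'
#' @param hypnogram a [Hypnogram-class].
#' @param fs sampling rate in Hz.
#' @param nSamples number of samples to cover; defaults to the full
#'   hypnogram span. Samples beyond the hypnogram keep the last label.
#' @return Character vector of length \code{nSamples}.
#' @export
stagePerSample <- function(hypnogram, fs, nSamples = NULL) {
  stopifnot(is(hypnogram, "Hypnogram"))
  spe <- round(hypnogram@epochLength * fs)
  lab <- rep(hypnogram@stages, each = spe)
  if (is.null(nSamples)) nSamples <- length(lab)
  if (length(lab) < nSamples)
    lab <- c(lab, rep(lab[length(lab)], nSamples - length(lab)))
  lab[seq_len(nSamples)]
}

#' Logical sample selector for a set of stages
#'
#' @inheritParams stagePerSample
#' @param stageSet stages to select, e.g. \code{c("N2", "N3")}.
#' @return Logical vector marking samples whose epoch is in
#'   \code{stageSet}.
#' @export
samplesInStages <- function(hypnogram, fs, nSamples, stageSet) {
  stagePerSample(hypnogram, fs, nSamples) %in% stageSet
}
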