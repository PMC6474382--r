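#' @import methods
NULL

STAGE_LEVELS <- c("W", "N1", "N2", "N3", "R")
SLEEP_STAGES <- c("N1", "N2", "N3", "R")

#' Multichannel EEG recording
#'
#' Container for a multichannel EEG time series in physical units (microvolt),
#' together with the sampling rate, ordered channel labels and a per-sample
#' artifact mask. Masked samples (stimulation plus amplifier-recovery spans)
#' are excluded from every analysis in the package.
#'
#' @slot signals numeric matrix, samples x channels, in microvolt.
#' @slot fs sampling rate in Hz.
#' @slot channels character vector of channel labels (10-20 system), one per
#'   column of \code{signals}.
#' @slot mask logical vector, one element per sample; \code{TRUE} marks
#'   artifact samples excluded from analysis.
#'
#' @seealso [EEGRecording()] for the constructor,
#'   [applyArtifactMask()] for mask bookkeeping.
#' @export
setClass("EEGRecording",
  representation(
    signals = "matrix",
    fs = "numeric",
    channels = "character",
    mask = "logical"
  )
)

setValidity("EEGRecording", function(object) {
  msg <- character()
  if (!is.numeric(object@signals))
    msg <- c(msg, "signals must be a numeric matrix")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (ncol(object@signals) != length(object@channels))
    msg <- c(msg, "one channel label per signal column is required")
  if (anyDuplicated(object@channels))
    msg <- c(msg, "channel labels must be unique")
  if (length(object@mask) != nrow(object@signals))
    msg <- c(msg, "mask length must equal the number of samples")
  if (length(msg)) msg else TRUE
})

#' Construct an EEGRecording
#'
#' @param signals numeric matrix (samples x channels), microvolt.
#' @param fs sampling rate, Hz.
#' @param channels channel labels; defaults to \code{colnames(signals)}.
#' @param mask logical artifact mask, one entry per sample; defaults to all
#'   \code{FALSE} (no artifacts).
#' @return An [EEGRecording-class] object.
#' @examples
#' rec <- EEGRecording(matrix(rnorm(1000), 500, 2), fs = 500,
#'                     channels = c("Fz", "Pz"))
#' nSamples(rec)
#' @export
EEGRecording <- function(signals, fs, channels = colnames(signals),
                         mask = NULL) {
  signals <- as.matrix(signals)
  if (is.null(channels))
    stop("channel labels are required")
  if (is.null(mask)) mask <- rep(FALSE, nrow(signals))
  colnames(signals) <- channels
  new("EEGRecording", signals = signals, fs = as.numeric(fs),
      channels = as.character(channels), mask = mask)
}

#' Hypnogram of 30-s sleep-stage epochs
#'
#' Sequence of sleep-stage labels, one per scoring epoch, over the stage set
#' \{W, N1, N2, N3, R\} (AASM wake, NREM1-3, REM). The epoch length defaults
#' to the conventional 30 s.
#'
#' @slot stages character vector of per-epoch stage labels.
#' @slot epochLength epoch duration in seconds (default 30).
#'
#' @seealso [Hypnogram()], [sleepSummary()], [relabelStimEpochs()]
#' @export
setClass("Hypnogram",
  representation(stages = "character", epochLength = "numeric")
)

setValidity("Hypnogram", function(object) {
  msg <- character()
  if (length(object@stages) < 1L)
    msg <- c(msg, "at least one epoch is required")
  bad <- setdiff(unique(object@stages), STAGE_LEVELS)
  if (length(bad))
    msg <- c(msg, paste0("unknown stage label(s): ",
                         paste(bad, collapse = ", ")))
  if (length(object@epochLength) != 1L || object@epochLength <= 0)
    msg <- c(msg, "epochLength must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct a Hypnogram
#'
#' @param stages character vector of stage labels in \{W, N1, N2, N3, R\}.
#' @param epochLength epoch duration in seconds.
#' @return A [Hypnogram-class] object.
#' @examples
#' h <- Hypnogram(c("W", "N1", "N2", "N3", "N3"))
#' stageAt(h, 70)   # "N2"
#' @export
Hypnogram <- function(stages, epochLength = 30) {
  new("Hypnogram", stages = as.character(stages),
      epochLength = as.numeric(epochLength))
}
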