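#' @rdname EEGRecording-class
#' @param object,x an object.
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname EEGRecording-class
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname EEGRecording-class
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname EEGRecording-class
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname EEGRecording-class
#' @export
setGeneric("signalMatrix", function(x) standardGeneric("signalMatrix"))

#' @rdname EEGRecording-class
#' @export
setGeneric("artifactMask", function(x) standardGeneric("artifactMask"))

#' @rdname EEGRecording-class
#' @param value replacement value.
#' @export
setGeneric("artifactMask<-",
           function(x, value) standardGeneric("artifactMask<-"))

#' @rdname EEGRecording-class
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))

#' @rdname Hypnogram-class
#' @param x an object.
#' @export
setGeneric("stages", function(x) standardGeneric("stages"))

#' @rdname Hypnogram-class
#' @export
setGeneric("epochLength", function(x) standardGeneric("epochLength"))

#' @rdname Hypnogram-class
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))

#' @rdname Hypnogram-class
#' @param t time in seconds.
#' @export
setGeneric("stageAt", function(x, t) standardGeneric("stageAt"))
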