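#' @rdname ElectrodeLayout-class
#' @param object,x an object.
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @export
setMethod("nChannels", "ElectrodeLayout", function(x) nrow(x@map))

#' @export
setMethod("nChannels", "EmgRecording", function(x) nrow(x@signal))

#' @export
setMethod("nChannels", "SampleSet", function(x) dim(x@data)[1])

#' Signal matrix of a recording
#' @param x an [EmgRecording-class].
#' @return channels x samples numeric matrix.
#' @export
setGeneric("signalMatrix", function(x) standardGeneric("signalMatrix"))

#' @export
setMethod("signalMatrix", "EmgRecording", function(x) x@signal)

#' Sampling rate accessor
#' @param x an [EmgRecording-class].
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @export
setMethod("samplingRate", "EmgRecording", function(x) x@samplingRate)

#' Number of samples in a SampleSet
#' @param x a [SampleSet-class].
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @export
setMethod("nSamples", "SampleSet", function(x) dim(x@data)[3])

#' Sample labels accessor
#' @param x a [SampleSet-class].
#' @export
setGeneric("sampleLabels", function(x) standardGeneric("sampleLabels"))

#' @export
setMethod("sampleLabels", "SampleSet", function(x) x@labels)

#' Sample data accessor
#' @param x a [SampleSet-class].
#' @return channels x width x n array.
#' @export
setGeneric("sampleData", function(x) standardGeneric("sampleData"))

#' @export
setMethod("sampleData", "SampleSet", function(x) x@data)

#' Number of trainable parameters of a classifier
#' @param x a model object.
#' @export
setGeneric("countParameters", function(x) standardGeneric("countParameters"))

#' Total of a power report
#' @param x a [PowerReport-class].
#' @export
setGeneric("powerTotal", function(x) standardGeneric("powerTotal"))

#' @export
setMethod("powerTotal", "PowerReport", function(x) x@total)

#' Components of a power report
#' @param x a [PowerReport-class].
#' @export
setGeneric("powerComponents", function(x) standardGeneric("powerComponents"))

#' @export
setMethod("powerComponents", "PowerReport", function(x) x@components)

setMethod("show", "ElectrodeLayout", function(object) {
  cat(sprintf("ElectrodeLayout: %d channels in %d array(s)\n",
    nrow(object@map), nrow(object@arrays)))
  for (i in seq_len(nrow(object@arrays)))
    cat(sprintf("  array %d: %d x %d, %.1f mm spacing\n",
      object@arrays$array[i], object@arrays$rows[i],
      object@arrays$cols[i], object@arrays$spacing[i]))
})

setMethod("show", "EmgRecording", function(object) {
  cat(sprintf(
    "EmgRecording: %d ch x %d samples @ %g Hz (subject %d, trial %d, gesture %d, rep %d)\n",
    nrow(object@signal), ncol(object@signal), object@samplingRate,
    object@subject, object@trial, object@gesture, object@repetition))
})

setMethod("show", "SampleSet", function(object) {
  cat(sprintf("SampleSet: %d '%s' samples, %d ch x %d\n",
    nSamples(object), object@kind, dim(object@data)[1], dim(object@data)[2]))
  g <- table(object@labels$gesture)
  cat(sprintf("  gestures: %s\n",
    paste(sprintf("%s(%d)", names(g), g), collapse = " ")))
})

setMethod("show", "LifParams", function(object) {
  cat(sprintf(
    "LifParams (%s): tauMem %g, tauSyn %g, vThr2 %g, penalty %g, R %g\n",
    object@variant, object@tauMem, object@tauSyn, object@vThr2,
    object@penalty, object@r))
})

setMethod("show", "SnnNetwork", function(object) {
  cat(sprintf("SnnNetwork: %d -> %d -> %d, T = %d (%d parameters)\n",
    ncol(object@W1), nrow(object@W1), nrow(object@W2), object@timeSteps,
    countParameters(object)))
})

setMethod("show", "PowerReport", function(object) {
  cat("PowerReport (relative energy units):\n")
  for (nm in names(object@components))
    cat(sprintf("  %-12s %g\n", nm, object@components[[nm]]))
  cat(sprintf("  %-12s %g\n", "total", object@total))
})

setMethod("show", "LdaModel", function(object) {
  cat(sprintf("LdaModel: %d classes, %d features\n",
    nrow(object@means), ncol(object@means)))
})
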