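#' Accessors for AxonVelocity classes
#'
#' Accessor generics for the device/recording classes:
#' \code{deviceLayout} returns the \code{\linkS4class{DeviceLayout}} of an
#' object, \code{spikeTrains} the named list of per-electrode timestamp
#' vectors, \code{voltageTraces} the named list of raw traces,
#' \code{samplingRate} the sampling rate in Hz, \code{recordingDuration}
#' the duration in seconds, \code{recordingMetadata} the metadata list,
#' \code{nSpikes} the total (or per-electrode) spike count,
#' \code{pulseTimes} the stimulation pulse onsets in seconds and
#' \code{nTrials} the number of stimulation trials.
#'
#' @param x an object of one of the package's classes.
#' @param ... further arguments passed to methods.
#' @return See the individual descriptions above.
#' @name accessors
#' @aliases deviceLayout spikeTrains voltageTraces samplingRate
#'   recordingDuration recordingMetadata nSpikes pulseTimes nTrials
#' @examples
#' tab <- emptySpikeTable(buildDefaultLayout(), durationS = 10)
#' nSpikes(tab)
#' recordingDuration(tab)
NULL

#' @rdname accessors
#' @export
setGeneric("deviceLayout", function(x) standardGeneric("deviceLayout"))

#' @rdname accessors
#' @export
setGeneric("spikeTrains", function(x, ...) standardGeneric("spikeTrains"))

#' @rdname accessors
#' @export
setGeneric("voltageTraces", function(x) standardGeneric("voltageTraces"))

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("recordingDuration", function(x) standardGeneric("recordingDuration"))

#' @rdname accessors
#' @export
setGeneric("recordingMetadata", function(x) standardGeneric("recordingMetadata"))

#' @rdname accessors
#' @export
setGeneric("nSpikes", function(x, ...) standardGeneric("nSpikes"))

#' @rdname accessors
#' @export
setGeneric("pulseTimes", function(x) standardGeneric("pulseTimes"))

#' @rdname accessors
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))
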