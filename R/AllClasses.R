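#' @import methods
NULL

#' DeviceLayout: electrode geometry of a microchannel MEA device
#'
#' Describes how MEA electrodes map onto the compartments of a PDMS
#' microchannel device: each of \code{nModules} reservoir modules holds a
#' neuronal subpopulation recorded by two reservoir electrodes, and its axons
#' enter one microchannel recorded by five equally pitched channel electrodes.
#'
#' @slot nModules integer, number of reservoir modules (each paired with one
#'   microchannel).
#' @slot electrodes \code{data.frame} with one row per electrode and columns
#'   \code{electrode_id} (character, unique), \code{module_id} (integer),
#'   \code{role} (\code{"reservoir"} or \code{"channel"}),
#'   \code{channel_index} (integer 0..4 for channel electrodes, \code{NA}
#'   for reservoir electrodes; index 0 is nearest the reservoir, i.e. the
#'   stimulation-proximal electrode) and \code{position_um} (distance from
#'   the channel entrance in micrometres; \code{NA} for reservoir
#'   electrodes).
#' @slot pitchUm numeric, centre-to-centre spacing of channel electrodes in
#'   micrometres.
#' @slot channelLengthUm numeric, microchannel length in micrometres.
#'
#' @seealso \code{\link{buildDefaultLayout}}
#' @exportClass DeviceLayout
setClass("DeviceLayout",
  representation(
    nModules = "integer",
    electrodes = "data.frame",
    pitchUm = "numeric",
    channelLengthUm = "numeric"
  )
)

setValidity("DeviceLayout", function(object) {
  el <- object@electrodes
  msgs <- character(0)
  need <- c("electrode_id", "module_id", "role", "channel_index", "position_um")
  if (!all(need %in% names(el)))
    return(paste("electrodes must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(el$electrode_id))
    msgs <- c(msgs, "electrode_id values must be unique")
  if (!all(el$role %in% c("reservoir", "channel")))
    msgs <- c(msgs, "role must be 'reservoir' or 'channel'")
  if (object@pitchUm <= 0)
    msgs <- c(msgs, "pitchUm must be > 0")
  if (object@channelLengthUm < 4 * object@pitchUm)
    msgs <- c(msgs, "channelLengthUm must be >= 4 * pitchUm")
  for (m in seq_len(object@nModules)) {
    sub <- el[el$module_id == m, , drop = FALSE]
    nres <- sum(sub$role == "reservoir")
    ch <- sub[sub$role == "channel", , drop = FALSE]
    if (nres != 2L)
      msgs <- c(msgs, sprintf("module %d must have exactly 2 reservoir electrodes", m))
    if (nrow(ch) != 5L)
      msgs <- c(msgs, sprintf("module %d must have exactly 5 channel electrodes", m))
    else {
      pos <- ch$position_um[order(ch$channel_index)]
      d <- diff(pos)
      if (any(d <= 0))
        msgs <- c(msgs, sprintf("module %d channel positions must be strictly increasing", m))
      else if (any(abs(d - object@pitchUm) > 1e-9))
        msgs <- c(msgs, sprintf("module %d channel spacing must equal pitchUm", m))
      if (any(pos < 0 | pos > object@channelLengthUm))
        msgs <- c(msgs, sprintf("module %d channel positions must lie within the channel", m))
    }
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' SpikeTable: per-electrode spike timestamps
#'
#' Holds sorted spike timestamps (in seconds from recording onset) for each
#' electrode of a \code{\linkS4class{DeviceLayout}}, together with recording
#' metadata such as culture age (DIV) and condition label.
#'
#' @slot spikes named list, one sorted numeric vector of timestamps (s) per
#'   electrode; names are electrode ids of the layout.
#' @slot layout a \code{\linkS4class{DeviceLayout}}.
#' @slot durationS numeric, recording duration in seconds.
#' @slot metadata list of free-form recording metadata (e.g. \code{div},
#'   \code{condition}, \code{culture_id}, \code{seed}).
#'
#' @exportClass SpikeTable
setClass("SpikeTable",
  representation(
    spikes = "list",
    layout = "DeviceLayout",
    durationS = "numeric",
    metadata = "list"
  ),
  prototype(metadata = list())
)

setValidity("SpikeTable", function(object) {
  msgs <- character(0)
  ids <- object@layout@electrodes$electrode_id
  if (is.null(names(object@spikes)) || !all(names(object@spikes) %in% ids))
    msgs <- c(msgs, "spike list names must be electrode ids of the layout")
  if (length(object@durationS) != 1L || !is.finite(object@durationS) ||
      object@durationS <= 0)
    msgs <- c(msgs, "durationS must be a single positive number")
  for (id in names(object@spikes)) {
    ts <- object@spikes[[id]]
    if (length(ts) == 0L) next
    if (any(!is.finite(ts)))
      msgs <- c(msgs, sprintf("electrode %s has non-finite timestamps", id))
    else {
      if (is.unsorted(ts, strictly = TRUE))
        msgs <- c(msgs, sprintf("electrode %s timestamps must be strictly increasing", id))
      if (ts[1L] < 0 || ts[length(ts)] > object@durationS)
        msgs <- c(msgs, sprintf("electrode %s timestamps must lie in [0, durationS]", id))
    }
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Recording: raw multi-channel extracellular voltage traces
#'
#' @slot traces named list of numeric vectors, one voltage trace per
#'   electrode in microvolts; all traces have equal length.
#' @slot samplingRateHz numeric, samples per second per channel.
#' @slot layout a \code{\linkS4class{DeviceLayout}}.
#' @slot metadata list of recording metadata.
#'
#' @exportClass Recording
setClass("Recording",
  representation(
    traces = "list",
    samplingRateHz = "numeric",
    layout = "DeviceLayout",
    metadata = "list"
  ),
  prototype(metadata = list())
)

setValidity("Recording", function(object) {
  msgs <- character(0)
  ids <- object@layout@electrodes$electrode_id
  if (is.null(names(object@traces)) || !all(names(object@traces) %in% ids))
    msgs <- c(msgs, "trace names must be electrode ids of the layout")
  lens <- vapply(object@traces, length, integer(1))
  if (length(lens) && length(unique(lens)) != 1L)
    msgs <- c(msgs, "all traces must have equal length")
  if (length(object@samplingRateHz) != 1L || object@samplingRateHz <= 0)
    msgs <- c(msgs, "samplingRateHz must be a single positive number")
  if (any(vapply(object@traces, function(x) any(!is.finite(x)), logical(1))))
    msgs <- c(msgs, "trace samples must be finite")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' StimulationSession: biphasic pulse protocol applied to one electrode
#'
#' Describes a low-frequency electrical stimulation session: a train of
#' voltage-driven biphasic pulses (positive-then-negative, 100 us per phase)
#' delivered through one electrode, by default at 1 Hz for 180 trials.
#'
#' @slot pulseTimesS numeric, pulse onset times in seconds (sorted).
#' @slot amplitudeMv numeric, pulse amplitude in millivolts.
#' @slot phaseUs numeric, duration of each pulse phase in microseconds.
#' @slot polarity character, phase order (always
#'   \code{"positive-negative"}).
#' @slot blankingMs numeric, post-pulse period discarded as stimulation
#'   artifact (default 5 ms).
#' @slot stimElectrode character, id of the stimulated electrode.
#' @slot moduleId integer, module the stimulated electrode belongs to.
#'
#' @exportClass StimulationSession
setClass("StimulationSession",
  representation(
    pulseTimesS = "numeric",
    amplitudeMv = "numeric",
    phaseUs = "numeric",
    polarity = "character",
    blankingMs = "numeric",
    stimElectrode = "character",
    moduleId = "integer"
  ),
  prototype(phaseUs = 100, polarity = "positive-negative", blankingMs = 5)
)

setValidity("StimulationSession", function(object) {
  msgs <- character(0)
  if (length(object@pulseTimesS) < 1L)
    msgs <- c(msgs, "at least one pulse required")
  if (is.unsorted(object@pulseTimesS, strictly = TRUE))
    msgs <- c(msgs, "pulse times must be strictly increasing")
  if (object@amplitudeMv <= 0)
    msgs <- c(msgs, "amplitudeMv must be positive")
  if (object@blankingMs < 0)
    msgs <- c(msgs, "blankingMs must be >= 0")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})
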