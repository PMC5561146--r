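#' Build the default microchannel MEA device layout
#'
#' Constructs the electrode-to-compartment geometry of the standard device:
#' 8 interconnected reservoir modules, each recorded by 2 reservoir
#' electrodes, each feeding one 1 mm microchannel recorded by 5 electrodes at
#' 200 um pitch. Channel electrodes are centred in the channel, giving
#' positions 100, 300, 500, 700 and 900 um from the entrance; channel index 0
#' is the electrode nearest the reservoir (the stimulation-proximal site).
#'
#' @param nModules integer, number of reservoir modules (default 8).
#' @param pitchUm numeric, channel electrode pitch in micrometres
#'   (default 200).
#' @param channelLengthUm numeric, microchannel length in micrometres
#'   (default 1000).
#' @return A \code{\linkS4class{DeviceLayout}} with
#'   \code{nModules * 7} electrode records.
#' @examples
#' lay <- buildDefaultLayout()
#' table(lay@electrodes$role)
#' channelPositions(lay)
#' @export
buildDefaultLayout <- function(nModules = 8L, pitchUm = 200,
                               channelLengthUm = 1000) {
  nModules <- as.integer(nModules)
  stopifnot(nModules >= 1L, pitchUm > 0, channelLengthUm >= 4 * pitchUm)
  nCh <- 5L
  pos <- channelLengthUm / 2 + (seq_len(nCh) - (nCh + 1) / 2) * pitchUm
  rows <- lapply(seq_len(nModules), function(m) {
    rbind(
      data.frame(
        electrode_id = sprintf("m%02d_res%d", m, 1:2),
        module_id = m, role = "reservoir",
        channel_index = NA_integer_, position_um = NA_real_,
        stringsAsFactors = FALSE
      ),
      data.frame(
        electrode_id = sprintf("m%02d_ch%d", m, 0:(nCh - 1L)),
        module_id = m, role = "channel",
        channel_index = 0:(nCh - 1L), position_um = pos,
        stringsAsFactors = FALSE
      )
    )
  })
  new("DeviceLayout",
    nModules = nModules,
    electrodes = do.call(rbind, rows),
    pitchUm = pitchUm,
    channelLengthUm = channelLengthUm
  )
}

#' Electrode ids of one module, by role
#'
#' @param layout a \code{\linkS4class{DeviceLayout}}.
#' @param moduleId integer module number.
#' @return \code{channelElectrodes}: character vector of the module's channel
#'   electrode ids ordered by channel index (entrance to exit);
#'   \code{reservoirElectrodes}: character vector of its reservoir electrode
#'   ids (unordered — reservoir electrode order carries no meaning).
#' @examples
#' channelElectrodes(buildDefaultLayout(), 1)
#' @export
channelElectrodes <- function(layout, moduleId) {
  el <- layout@electrodes
  sub <- el[el$module_id == moduleId & el$role == "channel", , drop = FALSE]
  sub$electrode_id[order(sub$channel_index)]
}

#' @rdname channelElectrodes
#' @export
reservoirElectrodes <- function(layout, moduleId) {
  el <- layout@electrodes
  el$electrode_id[el$module_id == moduleId & el$role == "reservoir"]
}

#' Channel electrode positions (um from channel entrance)
#'
#' @param layout a \code{\linkS4class{DeviceLayout}}.
#' @param moduleId module number (positions are identical across modules of
#'   the default layout).
#' @return Numeric vector of positions in micrometres, ordered by channel
#'   index.
#' @export
channelPositions <- function(layout, moduleId = 1L) {
  el <- layout@electrodes
  sub <- el[el$module_id == moduleId & el$role == "channel", , drop = FALSE]
  sub$position_um[order(sub$channel_index)]
}

#' Seeding capacity of a device
#'
#' The reservoir modules confine the culture to the recording areas; each
#' module accommodates a bounded number of cells, so the per-device total is
#' the module count times the per-module seeding maximum (200 cells per
#' module, 1,600 cells for the default 8-module device).
#'
#' @param layout a \code{\linkS4class{DeviceLayout}}.
#' @param maxCellsPerModule integer, seeding maximum per reservoir module
#'   (default 200).
#' @return Integer, maximum number of cells per device.
#' @examples
#' deviceCellCapacity(buildDefaultLayout())
#' @export
deviceCellCapacity <- function(layout, maxCellsPerModule = 200L) {
  as.integer(layout@nModules) * as.integer(maxCellsPerModule)
}

#' Create an empty SpikeTable for a layout
#'
#' @param layout a \code{\linkS4class{DeviceLayout}}.
#' @param durationS recording duration in seconds.
#' @param metadata optional metadata list.
#' @return A \code{\linkS4class{SpikeTable}} with zero spikes on every
#'   electrode.
#' @export
emptySpikeTable <- function(layout, durationS, metadata = list()) {
  ids <- layout@electrodes$electrode_id
  spikes <- stats::setNames(rep(list(numeric(0)), length(ids)), ids)
  new("SpikeTable", spikes = spikes, layout = layout,
      durationS = durationS, metadata = metadata)
}

## ---- accessors -----------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("deviceLayout", "SpikeTable", function(x) x@layout)

#' @rdname accessors
#' @export
setMethod("deviceLayout", "Recording", function(x) x@layout)

#' @param electrodes optional character vector restricting
#'   \code{spikeTrains}/\code{nSpikes} to a subset of electrode ids.
#' @rdname accessors
#' @export
setMethod("spikeTrains", "SpikeTable", function(x, electrodes = NULL) {
  if (is.null(electrodes)) return(x@spikes)
  missing <- setdiff(electrodes, names(x@spikes))
  out <- x@spikes[intersect(electrodes, names(x@spikes))]
  if (length(missing))
    out <- c(out, stats::setNames(rep(list(numeric(0)), length(missing)), missing))
  out[electrodes]
})

#' @rdname accessors
#' @export
setMethod("voltageTraces", "Recording", function(x) x@traces)

#' @rdname accessors
#' @export
setMethod("samplingRate", "Recording", function(x) x@samplingRateHz)

#' @rdname accessors
#' @export
setMethod("recordingDuration", "SpikeTable", function(x) x@durationS)

#' @rdname accessors
#' @export
setMethod("recordingDuration", "Recording", function(x) {
  n <- if (length(x@traces)) length(x@traces[[1L]]) else 0L
  n / x@samplingRateHz
})

#' @rdname accessors
#' @export
setMethod("recordingMetadata", "SpikeTable", function(x) x@metadata)

#' @rdname accessors
#' @export
setMethod("recordingMetadata", "Recording", function(x) x@metadata)

#' @param perElectrode logical; if \code{TRUE}, return a named vector of
#'   per-electrode spike counts instead of the total.
#' @rdname accessors
#' @export
setMethod("nSpikes", "SpikeTable", function(x, perElectrode = FALSE) {
  counts <- vapply(x@spikes, length, integer(1))
  if (perElectrode) counts else sum(counts)
})

#' @rdname accessors
#' @export
setMethod("pulseTimes", "StimulationSession", function(x) x@pulseTimesS)

#' @rdname accessors
#' @export
setMethod("nTrials", "StimulationSession", function(x) length(x@pulseTimesS))

## ---- show methods --------------------------------------------------------

setMethod("show", "DeviceLayout", function(object) {
  cat(sprintf(
    "DeviceLayout: %d modules, %d electrodes (%d reservoir + %d channel)\n",
    object@nModules, nrow(object@electrodes),
    sum(object@electrodes$role == "reservoir"),
    sum(object@electrodes$role == "channel")
  ))
  cat(sprintf("  channel length %g um, electrode pitch %g um\n",
              object@channelLengthUm, object@pitchUm))
})

setMethod("show", "SpikeTable", function(object) {
  cat(sprintf("SpikeTable: %d spikes on %d electrodes over %.1f s\n",
              nSpikes(object), length(object@spikes), object@durationS))
  md <- object@metadata
  if (length(md))
    cat("  metadata:", paste(names(md), unlist(lapply(md, format)),
                             sep = "=", collapse = ", "), "\n")
})

setMethod("show", "Recording", function(object) {
  n <- if (length(object@traces)) length(object@traces[[1L]]) else 0L
  cat(sprintf(
    "Recording: %d electrodes x %d samples @ %g kHz (%.2f s)\n",
    length(object@traces), n, object@samplingRateHz / 1000,
    n / object@samplingRateHz
  ))
})

setMethod("show", "StimulationSession", function(object) {
  cat(sprintf(
    "StimulationSession: %d biphasic pulses @ %g mV on %s (blanking %g ms)\n",
    length(object@pulseTimesS), object@amplitudeMv,
    object@stimElectrode, object@blankingMs
  ))
})
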