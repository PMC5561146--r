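## Peri-stimulus analysis: artifact blanking by timestamp exclusion,
## trial-aligned rasters, windowed evoked rates, per-bin response fidelity
## over trials, and evoked vs baseline propagation velocity.

#' Construct a stimulation session
#'
#' @param pulseTimesS sorted pulse onset times, seconds.
#' @param amplitudeMv pulse amplitude, mV.
#' @param stimElectrode id of the stimulated electrode.
#' @param moduleId module of the stimulated electrode.
#' @param blankingMs post-pulse blanking period, ms (default 5).
#' @param phaseUs phase duration of the biphasic pulse, us (default 100).
#' @return A \code{\linkS4class{StimulationSession}}.
#' @export
stimulationSession <- function(pulseTimesS, amplitudeMv, stimElectrode,
                               moduleId, blankingMs = 5, phaseUs = 100) {
  new("StimulationSession",
      pulseTimesS = as.numeric(pulseTimesS), amplitudeMv = amplitudeMv,
      phaseUs = phaseUs, blankingMs = blankingMs,
      stimElectrode = stimElectrode, moduleId = as.integer(moduleId))
}

#' Peri-stimulus window scheme
#'
#' Post-stimulus analysis windows (ms). The defaults
#' \{5-15, 15-35, 35-100, 100-300, 300-950\} cover the direct (5-35 ms)
#' and polysynaptic (35-950 ms) response epochs; the fidelity bins are the
#' three 10 ms bins partitioning 5-35 ms.
#'
#' @param windowsMs named list of length-2 windows (ms post-stimulus),
#'   non-overlapping, all within \code{(blankingMs, trialSpanMs]}.
#' @param fidelityBinsMs list of length-2 bins partitioning 5-35 ms.
#' @param blankingMs artifact blanking, ms (default 5).
#' @param trialSpanMs analysed span per trial, ms (default 1000).
#' @return A validated list of class \code{"WindowScheme"}.
#' @export
windowScheme <- function(windowsMs = list(direct_early = c(5, 15),
                                          direct_late = c(15, 35),
                                          late_1 = c(35, 100),
                                          late_2 = c(100, 300),
                                          late_3 = c(300, 950)),
                         fidelityBinsMs = list(c(5, 15), c(15, 25),
                                               c(25, 35)),
                         blankingMs = 5, trialSpanMs = 1000) {
  win <- do.call(rbind, windowsMs)
  if (any(win[, 2] <= win[, 1]))
    stop("windows must have positive length")
  if (any(win[, 1] < blankingMs) || any(win[, 2] > trialSpanMs))
    stop("windows must lie within (blankingMs, trialSpanMs]")
  ord <- order(win[, 1])
  if (any(win[ord, 1][-1] < win[ord, 2][-nrow(win)]))
    stop("windows must not overlap")
  fb <- do.call(rbind, fidelityBinsMs)
  fb <- fb[order(fb[, 1]), , drop = FALSE]
  if (any(fb[-1, 1] != fb[-nrow(fb), 2]))
    stop("fidelity bins must be contiguous")
  structure(list(windowsMs = windowsMs, fidelityBinsMs = fidelityBinsMs,
                 blankingMs = blankingMs, trialSpanMs = trialSpanMs),
            class = "WindowScheme")
}

#' Align spikes to stimulation pulses
#'
#' Extracts, for every trial and electrode, the spike timestamps relative
#' to the corresponding pulse, within \code{(blankingMs, trialSpanMs]} ms
#' post-stimulus. Spikes inside the blanking period are discarded
#' (stimulation-artifact exclusion) and counted separately.
#'
#' @param table a \code{\linkS4class{SpikeTable}}.
#' @param session a \code{\linkS4class{StimulationSession}}.
#' @param scheme a \code{\link{windowScheme}}; its \code{blankingMs} is
#'   overridden by the session's if larger.
#' @param electrodes electrode ids to align (default: the channel
#'   electrodes of the stimulated module, excluding the stimulation site).
#' @return A list of class \code{"periStimRaster"}: \code{raster}
#'   (\code{data.frame} with \code{trial}, \code{electrode_id},
#'   \code{t_ms}), \code{nTrials}, \code{blankedCount},
#'   \code{electrodes} and the \code{scheme}.
#' @export
alignPeristimulus <- function(table, session, scheme = windowScheme(),
                              electrodes = NULL) {
  stopifnot(is(table, "SpikeTable"), is(session, "StimulationSession"))
  blankMs <- max(scheme$blankingMs, session@blankingMs)
  spanS <- scheme$trialSpanMs / 1000
  pulses <- session@pulseTimesS
  if (length(pulses) > 1L && min(diff(pulses)) < spanS)
    stop("pulse spacing (", min(diff(pulses)) * 1000,
         " ms) shorter than the trial span; shorten trialSpanMs")
  if (max(pulses) > table@durationS)
    stop("pulse times exceed the recording duration")
  if (is.null(electrodes)) {
    electrodes <- setdiff(
      channelElectrodes(table@layout, session@moduleId),
      session@stimElectrode)
  }
  rows <- list()
  blanked <- 0L
  for (id in electrodes) {
    ts <- table@spikes[[id]]
    if (is.null(ts) || !length(ts)) next
    trial <- findInterval(ts, pulses)
    inTrial <- trial >= 1L
    rel <- (ts - pulses[pmax(trial, 1L)]) * 1000
    use <- inTrial & rel > blankMs & rel <= scheme$trialSpanMs
    blanked <- blanked + sum(inTrial & rel >= 0 & rel <= blankMs)
    if (any(use))
      rows[[id]] <- data.frame(trial = trial[use], electrode_id = id,
                               t_ms = rel[use], stringsAsFactors = FALSE)
  }
  raster <- if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE)))
            else data.frame(trial = integer(0), electrode_id = character(0),
                            t_ms = numeric(0))
  structure(list(raster = raster, nTrials = length(pulses),
                 blankedCount = blanked, electrodes = electrodes,
                 scheme = scheme),
            class = "periStimRaster")
}

#' @export
print.periStimRaster <- function(x, ...) {
  cat(sprintf("periStimRaster: %d spikes, %d trials, %d electrodes (%d blanked)\n",
              nrow(x$raster), x$nTrials, length(x$electrodes),
              x$blankedCount))
  invisible(x)
}

#' Evoked firing rates per post-stimulus window
#'
#' For each window w: rate = total spikes in w across trials /
#' (nTrials x window length in seconds), pooled over the raster's
#' electrodes, with the across-trial standard deviation of the per-trial
#' rates. Baseline comparisons use identically computed rates on
#' non-stimulated recordings.
#'
#' @param raster a \code{"periStimRaster"} from
#'   \code{\link{alignPeristimulus}}.
#' @param scheme a \code{\link{windowScheme}} (default: the raster's).
#' @return \code{data.frame} with \code{window}, \code{start_ms},
#'   \code{end_ms}, \code{n_spikes}, \code{rate_hz}, \code{sd_hz}.
#' @export
windowRates <- function(raster, scheme = raster$scheme) {
  win <- scheme$windowsMs
  t <- raster$raster$t_ms
  trial <- raster$raster$trial
  nT <- raster$nTrials
  rows <- lapply(names(win), function(nm) {
    w <- win[[nm]]
    if (w[2] <= w[1]) stop("zero-length window: ", nm)
    lenS <- (w[2] - w[1]) / 1000
    inW <- t > w[1] & t <= w[2]
    perTrial <- tabulate(trial[inW], nbins = nT) / lenS
    data.frame(window = nm, start_ms = w[1], end_ms = w[2],
               n_spikes = sum(inW),
               rate_hz = sum(inW) / (nT * lenS),
               sd_hz = stats::sd(perTrial),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Response fidelity per 10 ms bin
#'
#' The presence of at least one spike (on any raster electrode) in a bin is
#' a positive response for that trial; fidelity is the percentage of
#' positive trials.
#'
#' @param raster a \code{"periStimRaster"}.
#' @param scheme a \code{\link{windowScheme}} supplying
#'   \code{fidelityBinsMs}.
#' @return \code{data.frame} with \code{start_ms}, \code{end_ms},
#'   \code{n_positive} and \code{fidelity_pct}.
#' @export
responseFidelity <- function(raster, scheme = raster$scheme) {
  if (raster$nTrials == 0L) stop("no trials in raster")
  t <- raster$raster$t_ms
  trial <- raster$raster$trial
  rows <- lapply(scheme$fidelityBinsMs, function(b) {
    pos <- unique(trial[t > b[1] & t <= b[2]])
    data.frame(start_ms = b[1], end_ms = b[2],
               n_positive = length(pos),
               fidelity_pct = 100 * length(pos) / raster$nTrials)
  })
  do.call(rbind, rows)
}

#' Evoked propagation velocity per peri-stimulus window
#'
#' Matches propagating spikes over the four electrodes distal to the
#' stimulation site (three 200 um pairs), assigns each event to the
#' post-stimulus window containing its first arrival, and summarizes event
#' velocities per window. Baseline velocity is computed identically on
#' non-stimulated recordings with \code{\link{propagationEvents}}.
#'
#' @param table a \code{\linkS4class{SpikeTable}}.
#' @param session a \code{\linkS4class{StimulationSession}} (stimulation at
#'   the first channel electrode).
#' @param params a \code{\link{matchParams}}.
#' @param scheme a \code{\link{windowScheme}}; events are classified by the
#'   windows \code{direct} = 5-35 ms and \code{late} = 35-950 ms derived
#'   from its blanking and span unless \code{windows} is given.
#' @param windows named list of classification windows (ms); default
#'   \code{list(direct = c(5, 35), late = c(35, 950))}.
#' @param velocityMethod see \code{\link{matchPropagatingSpikes}}.
#' @return \code{data.frame} with one row per window: \code{window},
#'   \code{start_ms}, \code{end_ms}, \code{mean_velocity} (\code{NA} when
#'   the window holds no events), \code{sd_velocity}, \code{n_events}.
#' @export
evokedVelocity <- function(table, session, params = matchParams(),
                           scheme = windowScheme(),
                           windows = list(direct = c(5, 35),
                                          late = c(35, 950)),
                           velocityMethod = c("arithmetic", "harmonic")) {
  velocityMethod <- match.arg(velocityMethod)
  recIds <- setdiff(channelElectrodes(table@layout, session@moduleId),
                    session@stimElectrode)
  trains <- spikeTrains(table, recIds)
  ev <- matchPropagatingSpikes(trains, params, velocityMethod,
                               nElectrodes = length(recIds))
  pulses <- session@pulseTimesS
  relMs <- if (nrow(ev)) {
    tr <- findInterval(ev$t1, pulses)
    (ev$t1 - pulses[pmax(tr, 1L)]) * 1000
  } else numeric(0)
  rows <- lapply(names(windows), function(nm) {
    w <- windows[[nm]]
    sel <- nrow(ev) > 0 & relMs > w[1] & relMs <= w[2]
    vs <- ev$mean_velocity[sel]
    data.frame(window = nm, start_ms = w[1], end_ms = w[2],
               mean_velocity = if (length(vs)) mean(vs) else NA_real_,
               sd_velocity = if (length(vs) > 1) stats::sd(vs) else NA_real_,
               n_events = length(vs), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
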