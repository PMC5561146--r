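## Synthetic device emulation: spontaneous tonic + burst firing of a few
## axons per microchannel, propagation to the five channel electrodes with
## per-electrode timing jitter and imperfect detection, reservoir electrodes
## observing a fraction of the axons, 1 Hz biphasic stimulation sessions, and
## optional raw-trace rendering. Hidden parameters are returned as ground
## truth for parameter-recovery tests.

#' Configuration of the spontaneous-activity simulator
#'
#' Bundles the parameters of the synthetic device emulation and validates
#' them. Defaults emulate a mature low-density culture in the device:
#' velocities drawn uniformly from 0.3-0.8 m/s (the bulk of observed
#' conduction speeds), spike amplitudes spanning 40-1000 uV, and
#' MaxInterval-compatible bursts (intra-burst ISI 7 ms, at least 4 spikes, so
#' burst durations start at 21 ms).
#'
#' @param durationS recording duration in seconds.
#' @param tonicRateHz per-axon tonic (Poisson) firing rate, Hz.
#' @param burstRateHz per-axon burst onset rate (Poisson), bursts/s.
#' @param spikesPerBurst mean spikes per burst (Poisson, floored at
#'   \code{minSpikesPerBurst}).
#' @param minSpikesPerBurst minimum spikes per generated burst (default 4).
#' @param intraBurstIsiMs nominal intra-burst inter-spike interval, ms
#'   (each ISI is perturbed by +/-15 percent but stays below the 10 ms
#'   burst-extension criterion).
#' @param nAxonsPerChannel number of simulated axons per microchannel.
#' @param trueVelocityMS per-axon conduction velocity in m/s: a scalar, a
#'   vector recycled across axons, or \code{NULL} to draw each axon's
#'   velocity uniformly from 0.3-0.8 m/s.
#' @param jitterMs standard deviation of per-electrode arrival-time noise,
#'   ms; jitter draws are redrawn where they would invert arrival order
#'   along the channel (truncation preserving monotone arrival).
#' @param detectionProb probability that a propagating spike is observed on
#'   any given channel electrode.
#' @param reservoirFraction probability that a given axon's emission train
#'   is visible on a given reservoir electrode.
#' @param refractoryMs dead time imposed on each axon's emission train, ms.
#' @param amplitudeUv length-2 range of spike amplitudes, uV.
#' @param noiseSigmaUv Gaussian noise s.d. for rendered traces, uV.
#' @param samplingRateHz sampling rate for rendered traces, Hz.
#' @param seed integer seed making the simulation deterministic, or
#'   \code{NULL} to use the current RNG state.
#' @return A validated list of class \code{"SimulationConfig"}.
#' @examples
#' cfg <- simulationConfig(durationS = 60, seed = 1)
#' sim <- simulateSpontaneous(cfg)
#' sim$spikes
#' @export
simulationConfig <- function(durationS = 300, tonicRateHz = 0.5,
                             burstRateHz = 0.1, spikesPerBurst = 8,
                             minSpikesPerBurst = 4, intraBurstIsiMs = 7,
                             nAxonsPerChannel = 3, trueVelocityMS = NULL,
                             jitterMs = 0.05, detectionProb = 0.9,
                             reservoirFraction = 0.5, refractoryMs = 2,
                             amplitudeUv = c(40, 1000), noiseSigmaUv = 10,
                             samplingRateHz = 25000, seed = NULL) {
  cfg <- list(
    durationS = durationS, tonicRateHz = tonicRateHz,
    burstRateHz = burstRateHz, spikesPerBurst = spikesPerBurst,
    minSpikesPerBurst = minSpikesPerBurst, intraBurstIsiMs = intraBurstIsiMs,
    nAxonsPerChannel = nAxonsPerChannel, trueVelocityMS = trueVelocityMS,
    jitterMs = jitterMs, detectionProb = detectionProb,
    reservoirFraction = reservoirFraction, refractoryMs = refractoryMs,
    amplitudeUv = amplitudeUv, noiseSigmaUv = noiseSigmaUv,
    samplingRateHz = samplingRateHz, seed = seed
  )
  checkField <- function(ok, field, what) {
    if (!ok) stop("invalid SimulationConfig field '", field, "': ", what,
                  call. = FALSE)
  }
  checkField(durationS > 0, "durationS", "must be > 0")
  checkField(tonicRateHz >= 0, "tonicRateHz", "must be >= 0")
  checkField(burstRateHz >= 0, "burstRateHz", "must be >= 0")
  checkField(minSpikesPerBurst >= 1, "minSpikesPerBurst", "must be >= 1")
  checkField(intraBurstIsiMs > 0, "intraBurstIsiMs", "must be > 0")
  checkField(nAxonsPerChannel >= 1, "nAxonsPerChannel", "must be >= 1")
  checkField(is.null(trueVelocityMS) || all(trueVelocityMS >= 0.1),
             "trueVelocityMS", "velocities must be >= 0.1 m/s")
  checkField(jitterMs >= 0, "jitterMs", "must be >= 0")
  checkField(detectionProb >= 0 && detectionProb <= 1,
             "detectionProb", "must be in [0, 1]")
  checkField(reservoirFraction >= 0 && reservoirFraction <= 1,
             "reservoirFraction", "must be in [0, 1]")
  checkField(refractoryMs >= 0, "refractoryMs", "must be >= 0")
  checkField(length(amplitudeUv) == 2 && all(amplitudeUv > 0) &&
               amplitudeUv[1] <= amplitudeUv[2],
             "amplitudeUv", "must be an increasing positive range")
  checkField(noiseSigmaUv >= 0, "noiseSigmaUv", "must be >= 0")
  checkField(samplingRateHz > 0, "samplingRateHz", "must be > 0")
  class(cfg) <- "SimulationConfig"
  cfg
}

## Poisson process on [0, duration]
poissonTimes <- function(rateHz, durationS) {
  n <- stats::rpois(1L, rateHz * durationS)
  sort(stats::runif(n, 0, durationS))
}

## one axon's emission train + burst windows
emitAxonTrain <- function(cfg) {
  tonic <- poissonTimes(cfg$tonicRateHz, cfg$durationS)
  onsets <- poissonTimes(cfg$burstRateHz, cfg$durationS)
  burstSpikes <- numeric(0)
  bursts <- NULL
  if (length(onsets)) {
    bl <- lapply(onsets, function(t0) {
      n <- max(cfg$minSpikesPerBurst,
               stats::rpois(1L, cfg$spikesPerBurst))
      isis <- cfg$intraBurstIsiMs * stats::runif(n - 1L, 0.85, 1.15) / 1000
      t0 + c(0, cumsum(isis))
    })
    burstSpikes <- unlist(bl)
    bursts <- data.frame(
      start_s = onsets,
      end_s = vapply(bl, max, numeric(1)),
      n_spikes = vapply(bl, length, integer(1))
    )
  }
  train <- sort(c(tonic, burstSpikes))
  train <- train[train <= cfg$durationS]
  ## refractoriness: drop spikes closer than refractoryMs to the last kept
  if (length(train) > 1L && cfg$refractoryMs > 0) {
    keep <- logical(length(train))
    last <- -Inf
    dead <- cfg$refractoryMs / 1000
    for (i in seq_along(train)) {
      if (train[i] - last >= dead) {
        keep[i] <- TRUE
        last <- train[i]
      }
    }
    train <- train[keep]
  }
  list(train = train, bursts = bursts)
}

## project emissions onto channel electrodes; jitter redrawn where it would
## invert arrival order
projectArrivals <- function(train, velocity, positionsUm, jitterMs) {
  n <- length(train)
  k <- length(positionsUm)
  base <- outer(train, positionsUm * 1e-6 / velocity, `+`)
  if (n == 0L) return(base)
  if (jitterMs > 0) {
    sd <- jitterMs / 1000
    arr <- base + matrix(stats::rnorm(n * k, 0, sd), n, k)
    for (try in 1:50) {
      bad <- which(apply(arr, 1L, function(r) any(diff(r) <= 0)))
      if (!length(bad)) break
      arr[bad, ] <- base[bad, , drop = FALSE] +
        matrix(stats::rnorm(length(bad) * k, 0, sd), length(bad), k)
    }
    bad <- which(apply(arr, 1L, function(r) any(diff(r) <= 0)))
    if (length(bad))  # pathological jitter/velocity combination: sort rows
      arr[bad, ] <- t(apply(arr[bad, , drop = FALSE], 1L, sort))
    arr
  } else base
}

strictlyIncreasing <- function(x) {
  x <- sort(x)
  if (length(x) > 1L) {
    d <- diff(x)
    while (any(d <= 0)) {
      x[which(d <= 0) + 1L] <- x[which(d <= 0) + 1L] + 1e-9
      x <- sort(x)
      d <- diff(x)
    }
  }
  x
}

#' Simulate spontaneous activity in the synthetic device
#'
#' Generates per-axon spike trains as a superposition of Poisson tonic
#' spikes and Poisson-onset bursts, imposes a refractory dead time, projects
#' each emitted spike onto the five channel electrodes (arrival at electrode
#' \eqn{k} = emission time + position\eqn{_k}/velocity + jitter), thins each
#' arrival with the per-electrode detection probability, and exposes a
#' fraction of axon emission trains on the reservoir electrodes.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param layout a \code{\linkS4class{DeviceLayout}} (default
#'   \code{\link{buildDefaultLayout}()}).
#' @param metadata metadata list stored in the returned table.
#' @return A list with elements \code{spikes}
#'   (\code{\linkS4class{SpikeTable}}) and \code{truth}, a
#'   \code{"GroundTruth"} list with per-axon velocities, emission times,
#'   burst windows, pre-thinning arrival matrices and kept masks.
#' @export
simulateSpontaneous <- function(config, layout = buildDefaultLayout(),
                                metadata = list()) {
  stopifnot(inherits(config, "SimulationConfig"))
  run <- function() .simulateSpontaneous(config, layout, metadata)
  if (!is.null(config$seed)) withr::with_seed(config$seed, run()) else run()
}

.simulateSpontaneous <- function(cfg, layout, metadata) {
  tab <- emptySpikeTable(layout, cfg$durationS,
                         c(metadata, list(seed = cfg$seed)))
  nAx <- cfg$nAxonsPerChannel
  axRows <- list(); emissions <- list(); burstsL <- list()
  arrivalsL <- list(); keptL <- list()
  for (m in seq_len(layout@nModules)) {
    chIds <- channelElectrodes(layout, m)
    resIds <- reservoirElectrodes(layout, m)
    pos <- channelPositions(layout, m)
    chTrains <- stats::setNames(rep(list(numeric(0)), length(chIds)), chIds)
    resTrains <- stats::setNames(rep(list(numeric(0)), length(resIds)), resIds)
    for (j in seq_len(nAx)) {
      axId <- sprintf("m%02d_ax%d", m, j)
      v <- if (is.null(cfg$trueVelocityMS)) stats::runif(1, 0.3, 0.8)
           else cfg$trueVelocityMS[(((m - 1) * nAx + j - 1) %%
                                      length(cfg$trueVelocityMS)) + 1L]
      ax <- emitAxonTrain(cfg)
      arr <- projectArrivals(ax$train, v, pos, cfg$jitterMs)
      kept <- matrix(stats::runif(length(arr)) <= cfg$detectionProb,
                     nrow = nrow(arr), ncol = ncol(arr))
      for (k in seq_along(chIds)) {
        a <- arr[kept[, k], k]
        chTrains[[chIds[k]]] <- c(chTrains[[chIds[k]]],
                                  a[a <= cfg$durationS & a >= 0])
      }
      for (r in seq_along(resIds)) {
        if (stats::runif(1) <= cfg$reservoirFraction)
          resTrains[[resIds[r]]] <- c(resTrains[[resIds[r]]], ax$train)
      }
      axRows[[axId]] <- data.frame(
        axon_id = axId, module_id = m, velocity_m_s = v,
        n_emitted = length(ax$train),
        n_bursts = if (is.null(ax$bursts)) 0L else nrow(ax$bursts),
        stringsAsFactors = FALSE
      )
      emissions[[axId]] <- ax$train
      burstsL[[axId]] <- ax$bursts
      arrivalsL[[axId]] <- arr
      keptL[[axId]] <- kept
    }
    for (id in chIds) tab@spikes[[id]] <- strictlyIncreasing(chTrains[[id]])
    for (id in resIds) tab@spikes[[id]] <- strictlyIncreasing(resTrains[[id]])
  }
  validObject(tab)
  truth <- list(
    axons = do.call(rbind, c(axRows, list(make.row.names = FALSE))),
    emissions = emissions, bursts = burstsL,
    arrivals = arrivalsL, kept = keptL,
    config = cfg
  )
  class(truth) <- "GroundTruth"
  list(spikes = tab, truth = truth)
}

#' Configuration of a simulated stimulation session
#'
#' Describes a biphasic 1 Hz stimulation session applied to the first
#' (reservoir-proximal) microchannel electrode: per trial, a direct response
#' chain is inserted with probability \code{pDirect} at a latency drawn
#' uniformly from \code{directLatencyMs} and propagated down the four distal
#' electrodes at \code{evokedVelocityMS}; polysynaptic spikes appear in each
#' late window with probability \code{pLate} and propagate at
#' \code{lateVelocityMS}. When \code{pDirect}/\code{pLate} are \code{NULL}
#' they default to an amplitude-dependent map (larger pulses recruit
#' responses more reliably and engage polysynaptic activity).
#'
#' @param nTrials number of stimulation pulses (default 180).
#' @param pulseRateHz pulse rate, Hz (default 1).
#' @param amplitudeMv pulse amplitude, mV (protocol uses 250, 500 or 1000).
#' @param pDirect probability of a direct response per trial, or
#'   \code{NULL} for the amplitude default.
#' @param pLate probability of a polysynaptic response per late window, or
#'   \code{NULL} for the amplitude default.
#' @param directLatencyMs length-2 range of direct-response latencies at
#'   the first recording electrode, ms post-stimulus.
#' @param evokedVelocityMS propagation velocity of direct-response chains,
#'   m/s.
#' @param lateVelocityMS propagation velocity of polysynaptic chains, m/s.
#' @param lateWindowsMs list of length-2 post-stimulus windows (ms) in which
#'   polysynaptic responses may occur.
#' @param artifactDurationMs duration of the rendered stimulation artifact
#'   (and default blanking), ms.
#' @param moduleId module whose channel is stimulated.
#' @return A validated list of class \code{"StimulationSimConfig"}.
#' @export
stimulationConfig <- function(nTrials = 180L, pulseRateHz = 1,
                              amplitudeMv = 500, pDirect = NULL,
                              pLate = NULL, directLatencyMs = c(5, 15),
                              evokedVelocityMS = 0.6, lateVelocityMS = 0.5,
                              lateWindowsMs = list(c(35, 100), c(100, 300)),
                              artifactDurationMs = 5, moduleId = 1L) {
  if (is.null(pDirect)) pDirect <- defaultResponseProb(amplitudeMv, "direct")
  if (is.null(pLate)) pLate <- defaultResponseProb(amplitudeMv, "late")
  cfg <- list(
    nTrials = as.integer(nTrials), pulseRateHz = pulseRateHz,
    amplitudeMv = amplitudeMv, pDirect = pDirect, pLate = pLate,
    directLatencyMs = directLatencyMs, evokedVelocityMS = evokedVelocityMS,
    lateVelocityMS = lateVelocityMS, lateWindowsMs = lateWindowsMs,
    artifactDurationMs = artifactDurationMs, moduleId = as.integer(moduleId)
  )
  checkField <- function(ok, field, what) {
    if (!ok) stop("invalid StimulationSimConfig field '", field, "': ", what,
                  call. = FALSE)
  }
  checkField(cfg$nTrials >= 1L, "nTrials", "must be >= 1")
  checkField(pulseRateHz > 0, "pulseRateHz", "must be > 0")
  checkField(pDirect >= 0 && pDirect <= 1, "pDirect", "must be in [0, 1]")
  checkField(all(pLate >= 0 & pLate <= 1), "pLate", "must be in [0, 1]")
  checkField(length(directLatencyMs) == 2 && directLatencyMs[1] > 0 &&
               directLatencyMs[1] <= directLatencyMs[2],
             "directLatencyMs", "must be a positive increasing range")
  checkField(evokedVelocityMS >= 0.1 && lateVelocityMS >= 0.1,
             "evokedVelocityMS", "velocities must be >= 0.1 m/s")
  checkField(artifactDurationMs >= 0, "artifactDurationMs", "must be >= 0")
  class(cfg) <- "StimulationSimConfig"
  cfg
}

## amplitude-dependent response probabilities: calibration knobs emulating
## the qualitative amplitude dependence of evoked responses (stronger pulses
## respond more reliably and recruit polysynaptic activity; 250 mV barely
## engages the network beyond the direct window)
defaultResponseProb <- function(amplitudeMv, kind = c("direct", "late")) {
  kind <- match.arg(kind)
  amps <- c(250, 500, 1000)
  p <- if (kind == "direct") c(0.75, 0.90, 0.95) else c(0.05, 0.25, 0.35)
  stats::approx(amps, p, xout = amplitudeMv, rule = 2)$y
}

#' Simulate a stimulation session with known per-trial responses
#'
#' Places \code{nTrials} biphasic pulses at fixed \code{1/pulseRateHz}
#' intervals on the first (proximal) channel electrode of the chosen module,
#' inserts direct and polysynaptic response chains on the four distal
#' channel electrodes per \code{\link{stimulationConfig}}, superimposes
#' spontaneous background activity per \code{\link{simulationConfig}}
#' (set its rates to 0 for a clean session), and records per-trial ground
#' truth flags.
#'
#' @param config a \code{\link{simulationConfig}} for background activity,
#'   jitter and seed.
#' @param stim a \code{\link{stimulationConfig}}.
#' @param layout a \code{\linkS4class{DeviceLayout}}.
#' @return A list with \code{spikes} (\code{\linkS4class{SpikeTable}}),
#'   \code{session} (\code{\linkS4class{StimulationSession}}) and
#'   \code{truth} (per-trial flags and latencies plus the background ground
#'   truth, if any).
#' @export
simulateStimulationSession <- function(config, stim,
                                       layout = buildDefaultLayout()) {
  stopifnot(inherits(config, "SimulationConfig"),
            inherits(stim, "StimulationSimConfig"))
  durationNeeded <- stim$nTrials / stim$pulseRateHz
  if (config$durationS < durationNeeded)
    stop("config durationS (", config$durationS,
         " s) shorter than session length (", durationNeeded, " s)")
  run <- function() .simulateStimulation(config, stim, layout)
  if (!is.null(config$seed)) withr::with_seed(config$seed, run()) else run()
}

.simulateStimulation <- function(cfg, stim, layout) {
  pulses <- (seq_len(stim$nTrials) - 1L) / stim$pulseRateHz
  chIds <- channelElectrodes(layout, stim$moduleId)
  pos <- channelPositions(layout, stim$moduleId)
  stimEl <- chIds[1L]
  recIds <- chIds[-1L]
  recPos <- pos[-1L]

  background <- if (cfg$tonicRateHz > 0 || cfg$burstRateHz > 0)
    .simulateSpontaneous(cfg, layout, list(condition = "background"))
  else NULL

  nLate <- length(stim$lateWindowsMs)
  pLate <- rep(stim$pLate, length.out = nLate)
  trials <- data.frame(trial = seq_len(stim$nTrials),
                       direct = FALSE, direct_latency_ms = NA_real_)
  for (w in seq_len(nLate)) trials[[paste0("late_", w)]] <- FALSE
  ins <- stats::setNames(rep(list(numeric(0)), length(recIds)), recIds)
  jitterS <- cfg$jitterMs / 1000

  insertChain <- function(t0, v) {
    ## t0: arrival at first recording electrode; propagate to the rest
    base <- t0 + (recPos - recPos[1L]) * 1e-6 / v
    arr <- base + stats::rnorm(length(base), 0, jitterS)
    for (try in 1:50) {
      if (all(diff(arr) > 0)) break
      arr <- base + stats::rnorm(length(base), 0, jitterS)
    }
    if (any(diff(arr) <= 0)) arr <- sort(arr)
    arr
  }

  for (i in seq_len(stim$nTrials)) {
    tp <- pulses[i]
    if (stats::runif(1) <= stim$pDirect) {
      lat <- stats::runif(1, stim$directLatencyMs[1], stim$directLatencyMs[2])
      arr <- insertChain(tp + lat / 1000, stim$evokedVelocityMS)
      for (k in seq_along(recIds))
        ins[[recIds[k]]] <- c(ins[[recIds[k]]], arr[k])
      trials$direct[i] <- TRUE
      trials$direct_latency_ms[i] <- lat
    }
    for (w in seq_len(nLate)) {
      if (stats::runif(1) <= pLate[w]) {
        win <- stim$lateWindowsMs[[w]]
        t0 <- tp + stats::runif(1, win[1], win[2]) / 1000
        arr <- insertChain(t0, stim$lateVelocityMS)
        for (k in seq_along(recIds))
          ins[[recIds[k]]] <- c(ins[[recIds[k]]], arr[k])
        trials[[paste0("late_", w)]][i] <- TRUE
      }
    }
  }

  durationS <- stim$nTrials / stim$pulseRateHz
  tab <- emptySpikeTable(layout, durationS,
                         list(condition = "stimulation",
                              amplitude_mv = stim$amplitudeMv,
                              seed = cfg$seed))
  if (!is.null(background)) {
    bg <- background$spikes@spikes
    for (id in names(bg)) tab@spikes[[id]] <- bg[[id]][bg[[id]] <= durationS]
  }
  for (id in recIds) {
    merged <- c(tab@spikes[[id]], ins[[id]])
    tab@spikes[[id]] <- strictlyIncreasing(merged[merged >= 0 &
                                                    merged <= durationS])
  }
  validObject(tab)
  session <- new("StimulationSession",
    pulseTimesS = pulses, amplitudeMv = stim$amplitudeMv,
    blankingMs = stim$artifactDurationMs,
    stimElectrode = stimEl, moduleId = stim$moduleId
  )
  truth <- list(trials = trials, stim = stim,
                background = if (is.null(background)) NULL
                             else background$truth)
  class(truth) <- "GroundTruth"
  list(spikes = tab, session = session, truth = truth)
}

#' Render raw voltage traces from a spike table
#'
#' Renders each timestamp as a negative-leading biphasic template of about
#' 1 ms support whose trough equals minus the spike amplitude, summed into
#' Gaussian noise of \code{noiseSigmaUv}; stimulation pulses, when a session
#' is supplied, become saturating biphasic artifacts of
#' \code{artifactDurationMs}.
#'
#' @param table a \code{\linkS4class{SpikeTable}}.
#' @param config a \code{\link{simulationConfig}} supplying sampling rate,
#'   noise s.d. and amplitude range.
#' @param session optional \code{\linkS4class{StimulationSession}} whose
#'   pulses are rendered as artifacts on all electrodes of the stimulated
#'   module.
#' @param amplitudesUv spike amplitude in uV: a scalar, a named per-electrode
#'   vector, or \code{NULL} to draw one amplitude per electrode uniformly
#'   from \code{config$amplitudeUv}.
#' @param railUv saturation rail of the stimulation artifact, uV.
#' @return A \code{\linkS4class{Recording}}.
#' @export
renderRawTraces <- function(table, config, session = NULL,
                            amplitudesUv = NULL, railUv = 2000) {
  stopifnot(is(table, "SpikeTable"), inherits(config, "SimulationConfig"))
  fs <- config$samplingRateHz
  if (fs < 10000)
    stop("sampling rate ", fs, " Hz < 10 kHz: spike template unresolvable")
  nS <- ceiling(table@durationS * fs)
  tmpl <- spikeTemplate(fs)
  ids <- table@layout@electrodes$electrode_id
  if (is.null(amplitudesUv)) {
    amplitudesUv <- stats::setNames(
      stats::runif(length(ids), config$amplitudeUv[1], config$amplitudeUv[2]),
      ids)
  } else if (is.null(names(amplitudesUv))) {
    amplitudesUv <- stats::setNames(rep(amplitudesUv[1], length(ids)), ids)
  }
  traces <- stats::setNames(vector("list", length(ids)), ids)
  half <- tmpl$troughIdx - 1L
  for (id in ids) {
    x <- stats::rnorm(nS, 0, config$noiseSigmaUv)
    ts <- table@spikes[[id]]
    amp <- amplitudesUv[[id]]
    for (t0 in ts) {
      s0 <- round(t0 * fs) + 1L
      lo <- s0 - half
      hi <- lo + length(tmpl$shape) - 1L
      ti <- max(lo, 1L):min(hi, nS)
      if (length(ti))
        x[ti] <- x[ti] + amp * tmpl$shape[ti - lo + 1L]
    }
    traces[[id]] <- x
  }
  if (!is.null(session)) {
    elArtifact <- c(channelElectrodes(table@layout, session@moduleId),
                    reservoirElectrodes(table@layout, session@moduleId))
    art <- artifactTemplate(fs, session@phaseUs,
                            durMs = session@blankingMs, railUv = railUv)
    for (tp in session@pulseTimesS) {
      s0 <- round(tp * fs) + 1L
      ti <- s0:min(s0 + length(art) - 1L, nS)
      for (id in intersect(elArtifact, ids))
        traces[[id]][ti] <- art[seq_along(ti)]
    }
  }
  new("Recording", traces = traces, samplingRateHz = fs,
      layout = table@layout, metadata = table@metadata)
}

## negative-leading biphasic template, ~1 ms support, trough normalized to -1
spikeTemplate <- function(fs) {
  tt <- seq(0, 1e-3, by = 1 / fs)
  shape <- -exp(-((tt - 3e-4) / 1e-4)^2) +
    0.45 * exp(-((tt - 6.5e-4) / 1.8e-4)^2)
  shape <- shape / abs(min(shape))
  list(shape = shape, troughIdx = which.min(shape))
}

## saturating biphasic artifact with exponential tail, clipped at the rails
artifactTemplate <- function(fs, phaseUs, durMs, railUv) {
  n <- max(1L, round(durMs * 1e-3 * fs))
  tt <- (seq_len(n) - 1L) / fs
  phase <- phaseUs * 1e-6
  x <- numeric(n)
  x[tt < phase] <- railUv
  x[tt >= phase & tt < 2 * phase] <- -railUv
  tail <- tt >= 2 * phase
  x[tail] <- -railUv * exp(-(tt[tail] - 2 * phase) / 1e-3)
  x
}
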