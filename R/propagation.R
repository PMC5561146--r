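## Propagating-spike extraction and velocity analysis: greedy earliest-first
## chaining of spikes across the pitched channel electrodes, per-spike and
## per-channel velocities, proximal/distal comparison and the 11
## velocity-domain histogram.

#' Matching parameters for propagating spikes
#'
#' A spike is considered to propagate when it appears on every channel
#' electrode with a pairwise delay between \code{minDelayS} and
#' \code{maxDelayS} for each 200 um-pitched electrode pair. The 2 ms
#' maximum delay over the 200 um pitch implies the minimum admissible
#' propagation speed \code{pitch / maxDelay} = 0.1 m/s; zero delays would
#' imply infinite speed, so the minimum delay defaults to one sample period
#' at 25 kHz (0.04 ms).
#'
#' @param minDelayS minimum pairwise delay, s (default 4e-5).
#' @param maxDelayS maximum pairwise delay, s (default 2e-3).
#' @param pitchUm electrode pitch, um (default 200).
#' @return A validated list of class \code{"MatchParams"} with the derived
#'   \code{minVelocityMS} (= \code{pitchUm / (maxDelayS * 1e6)}).
#' @export
matchParams <- function(minDelayS = 4e-5, maxDelayS = 2e-3, pitchUm = 200) {
  if (!(minDelayS > 0 && minDelayS < maxDelayS))
    stop("need 0 < minDelayS < maxDelayS")
  if (pitchUm <= 0) stop("pitchUm must be > 0")
  structure(list(minDelayS = minDelayS, maxDelayS = maxDelayS,
                 pitchUm = pitchUm,
                 minVelocityMS = pitchUm / (maxDelayS * 1e6)),
            class = "MatchParams")
}

## velocity (m/s) for a pairwise delay (s) over pitch (um)
pairVelocity <- function(delayS, pitchUm) pitchUm / (delayS * 1e6)

#' Match spikes propagating across a whole microchannel
#'
#' Earliest-first chaining with augmenting repair: electrode-0 spikes are
#' scanned in time order; for each, the earliest unconsumed spike on
#' electrode 1 with a pairwise delay in \code{[minDelayS, maxDelayS]} is
#' taken, then likewise for the remaining electrodes. When the earliest
#' choice would strand a later spike whose only partner it consumed, the
#' conflict is resolved by re-routing the earlier chain to an alternative
#' partner (a unit-capacity augmenting path), so the emitted set always
#' attains the maximum possible number of disjoint complete chains;
#' earliest-first remains the tie-break among maximal solutions. A chain
#' is emitted only when complete across all electrodes (the spike
#' travelled the whole channel); consumed spikes are never reused, and
#' matching is anterograde only (channel entrance toward exit).
#'
#' @param trains list of sorted timestamp vectors, one per channel
#'   electrode, ordered by position along the channel (default expects 5).
#' @param params a \code{\link{matchParams}}.
#' @param velocityMethod how the per-spike \code{mean_velocity} summarizes
#'   the pairwise velocities: \code{"arithmetic"} (mean of the pairwise
#'   velocities; the conventional per-pair averaging rule) or
#'   \code{"harmonic"} (total path length over total transit time, which is
#'   far less biased by timing jitter because it avoids averaging
#'   reciprocals of short delays).
#' @param nElectrodes expected number of trains (default 5; the evoked
#'   analysis uses 4).
#' @return \code{data.frame} with one row per propagation event:
#'   arrival times \code{t1..tk}, pairwise delays \code{delay_1..},
#'   pairwise velocities \code{v_1..} (m/s) and \code{mean_velocity}.
#' @examples
#' trains <- lapply(0:4 * 4e-4, function(d) 0.1 + d)
#' matchPropagatingSpikes(trains, matchParams())
#' @export
matchPropagatingSpikes <- function(trains, params = matchParams(),
                                   velocityMethod = c("arithmetic",
                                                      "harmonic"),
                                   nElectrodes = 5L) {
  velocityMethod <- match.arg(velocityMethod)
  if (length(trains) != nElectrodes)
    stop("expected ", nElectrodes, " electrode trains, got ", length(trains))
  for (k in seq_along(trains)) {
    if (is.unsorted(trains[[k]]))
      stop("train ", k, " is not sorted")
  }
  k <- length(trains)
  ## unit-capacity layered matching: nxt[[e]][i] = partner index on layer
  ## e+1; prv[[e]][j] = feeder index on layer e-1
  nxt <- lapply(trains, function(tr) rep(NA_integer_, length(tr)))
  prv <- lapply(trains, function(tr) rep(NA_integer_, length(tr)))
  vis <- lapply(trains, function(tr) logical(length(tr)))

  candidates <- function(e, i) {
    tr <- trains[[e + 1L]]
    cur <- trains[[e]][i]
    lo <- cur + params$minDelayS
    hi <- cur + params$maxDelayS
    j0 <- findInterval(lo, tr, left.open = TRUE) + 1L
    if (j0 > length(tr) || tr[j0] > hi) return(integer(0))
    j1 <- j0
    while (j1 < length(tr) && tr[j1 + 1L] <= hi) j1 <- j1 + 1L
    j0:j1
  }

  ## DFS for a continuation of node (e, i) to the last electrode, earliest
  ## candidate first; occupied partners may be taken over if their current
  ## feeder can be re-routed (augmenting path)
  findCont <- function(e, i) {
    if (e == k) return(TRUE)
    for (j in candidates(e, i)) {
      if (vis[[e + 1L]][j]) next
      vis[[e + 1L]][j] <<- TRUE
      if (is.na(prv[[e + 1L]][j])) {
        if (findCont(e + 1L, j)) {
          nxt[[e]][i] <<- j
          prv[[e + 1L]][j] <<- i
          return(TRUE)
        }
      } else if (findCont(e, prv[[e + 1L]][j])) {
        ## the old feeder found an alternative partner; take over j,
        ## keeping j's own downstream continuation
        nxt[[e]][i] <<- j
        prv[[e + 1L]][j] <<- i
        return(TRUE)
      }
    }
    FALSE
  }

  for (i0 in seq_along(trains[[1L]])) {
    for (e in seq_len(k)) vis[[e]][] <- FALSE
    findCont(1L, i0)
  }

  events <- vector("list", 0L)
  for (i0 in seq_along(trains[[1L]])) {
    if (is.na(nxt[[1L]][i0])) next
    chain <- integer(k)
    chain[1L] <- i0
    for (e in 2:k) chain[e] <- nxt[[e - 1L]][chain[e - 1L]]
    events[[length(events) + 1L]] <-
      vapply(seq_len(k), function(e) trains[[e]][chain[e]], numeric(1))
  }
  arrivalsToEvents(events, params, velocityMethod)
}

arrivalsToEvents <- function(events, params, velocityMethod) {
  k <- if (length(events)) length(events[[1L]]) else 5L
  cn <- c(paste0("t", seq_len(k)),
          paste0("delay_", seq_len(k - 1L)),
          paste0("v_", seq_len(k - 1L)), "mean_velocity")
  if (!length(events)) {
    out <- as.data.frame(stats::setNames(
      rep(list(numeric(0)), length(cn)), cn))
    return(out)
  }
  mat <- do.call(rbind, events)
  delays <- mat[, -1L, drop = FALSE] - mat[, -k, drop = FALSE]
  vels <- pairVelocity(delays, params$pitchUm)
  mv <- if (velocityMethod == "arithmetic") rowMeans(vels)
        else (k - 1L) * params$pitchUm / (rowSums(delays) * 1e6)
  out <- data.frame(mat, delays, vels, mv)
  names(out) <- cn
  out
}

#' Propagation events for every microchannel of a spike table
#'
#' @param table a \code{\linkS4class{SpikeTable}}.
#' @param params a \code{\link{matchParams}}.
#' @param velocityMethod see \code{\link{matchPropagatingSpikes}}.
#' @return \code{data.frame} of events with a leading \code{module_id}
#'   column.
#' @export
propagationEvents <- function(table, params = matchParams(),
                              velocityMethod = c("arithmetic", "harmonic")) {
  stopifnot(is(table, "SpikeTable"))
  velocityMethod <- match.arg(velocityMethod)
  out <- lapply(seq_len(table@layout@nModules), function(m) {
    trains <- spikeTrains(table, channelElectrodes(table@layout, m))
    ev <- matchPropagatingSpikes(trains, params, velocityMethod,
                                 nElectrodes = length(trains))
    if (nrow(ev)) cbind(module_id = m, ev) else NULL
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    ev <- arrivalsToEvents(list(), params, velocityMethod)
    return(cbind(module_id = integer(0), ev))
  }
  do.call(rbind, out)
}

#' Per-channel velocity summary
#'
#' Mean and standard deviation of the per-spike mean velocities of a
#' channel's propagation events.
#'
#' @param events \code{data.frame} of events (rows of
#'   \code{\link{matchPropagatingSpikes}} output).
#' @return List with \code{mean}, \code{sd} (m/s; \code{NA} when there are
#'   no events — missing, not zero) and \code{n}.
#' @export
channelVelocitySummary <- function(events) {
  n <- nrow(events)
  if (n == 0L) return(list(mean = NA_real_, sd = NA_real_, n = 0L))
  list(mean = mean(events$mean_velocity),
       sd = if (n > 1L) stats::sd(events$mean_velocity) else NA_real_,
       n = n)
}

#' Proximal vs distal segment velocities
#'
#' Splits the channel at \code{boundaryUm}: pairwise velocities of
#' electrode pairs whose midpoint lies before the boundary (the first half
#' of the channel) are proximal, those beyond are distal.
#'
#' @param events event \code{data.frame} with \code{v_*} columns.
#' @param positionsUm channel electrode positions, um (default
#'   \code{c(100, 300, 500, 700, 900)}).
#' @param boundaryUm proximal/distal boundary, um (default 500, half the
#'   channel).
#' @return List with \code{proximal} and \code{distal} mean pairwise
#'   velocities (m/s).
#' @export
proximalDistalVelocities <- function(events,
                                     positionsUm = c(100, 300, 500, 700, 900),
                                     boundaryUm = 500) {
  mid <- (positionsUm[-1L] + positionsUm[-length(positionsUm)]) / 2
  vcols <- grep("^v_", names(events), value = TRUE)
  stopifnot(length(vcols) == length(mid))
  prox <- unlist(events[vcols[mid < boundaryUm]])
  dist <- unlist(events[vcols[mid > boundaryUm]])
  list(proximal = if (length(prox)) mean(prox) else NA_real_,
       distal = if (length(dist)) mean(dist) else NA_real_)
}

#' Velocity-domain histogram
#'
#' Counts propagation velocities in the 11 domains dividing 0.1-1.2 m/s
#' into 0.1 m/s intervals; the last bin is closed at 1.2. Velocities
#' outside the range go to an overflow count and are excluded from the
#' percentages.
#'
#' @param velocities numeric velocities (m/s), or an event
#'   \code{data.frame} whose \code{mean_velocity} column is used.
#' @param rangeMS length-2 velocity range, m/s (default \code{c(0.1, 1.2)}).
#' @param binWidthMS bin width, m/s (default 0.1).
#' @return List of class \code{"velocityHistogram"} with \code{bin_edges},
#'   \code{counts}, \code{percentages} (NA when no in-range velocities),
#'   \code{overflow} and \code{n}.
#' @export
velocityHistogram <- function(velocities, rangeMS = c(0.1, 1.2),
                              binWidthMS = 0.1) {
  if (is.data.frame(velocities)) velocities <- velocities$mean_velocity
  edges <- seq(rangeMS[1], rangeMS[2], by = binWidthMS)
  nb <- length(edges) - 1L
  inRange <- velocities >= rangeMS[1] & velocities <= rangeMS[2]
  v <- velocities[inRange]
  ## half-open [lo, hi) bins, last bin closed
  idx <- pmin(floor((v - rangeMS[1]) / binWidthMS) + 1L, nb)
  counts <- tabulate(idx, nbins = nb)
  structure(list(
    bin_edges = edges,
    counts = counts,
    percentages = if (sum(counts)) 100 * counts / sum(counts)
                  else rep(NA_real_, nb),
    overflow = sum(!inRange),
    n = length(velocities)
  ), class = "velocityHistogram")
}

#' @export
print.velocityHistogram <- function(x, ...) {
  nb <- length(x$counts)
  cat(sprintf("velocityHistogram: %d domains over [%g, %g] m/s, %d spikes (%d outside range)\n",
              nb, x$bin_edges[1], x$bin_edges[nb + 1L], x$n, x$overflow))
  lab <- sprintf("[%.1f,%.1f)", x$bin_edges[-(nb + 1L)], x$bin_edges[-1L])
  lab[nb] <- sub("\\)$", "]", lab[nb])
  df <- data.frame(domain = lab, count = x$counts,
                   pct = round(x$percentages, 1))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Correlation between channel activity and propagating-spike counts
#'
#' Pearson correlation between per-channel normalized spike counts and
#' propagating-event counts across channels (and days).
#'
#' @param spikeCounts numeric per-channel spike counts (or rates).
#' @param eventCounts numeric per-channel propagating-event counts,
#'   aligned with \code{spikeCounts}.
#' @return List with \code{r}, \code{p}, \code{n} and \code{degenerate}
#'   (TRUE with \code{r = 0} when either variable has zero variance).
#' @export
propagationCountCorrelation <- function(spikeCounts, eventCounts) {
  if (length(spikeCounts) != length(eventCounts))
    stop("spikeCounts and eventCounts must be aligned")
  if (length(spikeCounts) < 3L)
    stop("need at least 3 channel observations")
  norm <- spikeCounts / mean(spikeCounts)
  res <- pearsonCorrelation(norm, eventCounts)
  if (isTRUE(res$degenerate)) res$r <- 0
  res
}
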