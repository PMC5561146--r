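## MaxInterval-style burst detection and the eight burst features used in
## the activity-velocity correlation analysis.

#' Burst detection criteria
#'
#' The five MaxInterval-style criteria: a burst opens at the first
#' inter-spike interval (ISI) not exceeding \code{maxIsiStartMs}, extends
#' while ISIs stay within \code{maxIsiEndMs}, candidate bursts closer than
#' \code{minIbiMs} are merged, and candidates shorter than
#' \code{minDurationMs} or with fewer than \code{minSpikes} spikes are
#' discarded.
#'
#' @param maxIsiStartMs maximum ISI to start a burst, ms (default 20).
#' @param maxIsiEndMs maximum ISI to extend a burst, ms (default 10).
#' @param minIbiMs minimum inter-burst interval, ms (default 10).
#' @param minDurationMs minimum burst duration, ms (default 20).
#' @param minSpikes minimum spikes per burst (default 4).
#' @return A validated list of class \code{"BurstCriteria"}.
#' @export
burstCriteria <- function(maxIsiStartMs = 20, maxIsiEndMs = 10,
                          minIbiMs = 10, minDurationMs = 20,
                          minSpikes = 4L) {
  vals <- c(maxIsiStartMs, maxIsiEndMs, minIbiMs, minDurationMs, minSpikes)
  if (any(vals <= 0))
    stop("all BurstCriteria fields must be positive")
  if (maxIsiEndMs > maxIsiStartMs)
    stop("maxIsiEndMs must not exceed maxIsiStartMs")
  structure(list(maxIsiStartMs = maxIsiStartMs, maxIsiEndMs = maxIsiEndMs,
                 minIbiMs = minIbiMs, minDurationMs = minDurationMs,
                 minSpikes = as.integer(minSpikes)),
            class = "BurstCriteria")
}

#' Detect bursts in a spike train
#'
#' MaxInterval semantics: scan the sorted train; a candidate burst opens at
#' the first spike of an ISI at or below \code{maxIsiStartMs} and extends
#' while ISIs stay at or below \code{maxIsiEndMs}. Candidates separated by
#' less than \code{minIbiMs} are merged (so the stated minimum inter-burst
#' interval is meaningful), and only then are candidates failing
#' \code{minDurationMs} or \code{minSpikes} discarded. Burst duration is
#' last spike time minus first spike time. A burst cannot open on the final
#' spike (an ISI is required to open one).
#'
#' @param train sorted numeric spike timestamps, seconds.
#' @param criteria a \code{\link{burstCriteria}}.
#' @return \code{data.frame} with one row per burst: \code{start_s},
#'   \code{end_s}, \code{n_spikes}, \code{i_start}, \code{i_end} (spike
#'   indices into \code{train}). Bursts are disjoint and ordered.
#' @examples
#' detectBursts(c(0, 7, 14, 21) / 1000, burstCriteria())
#' @export
detectBursts <- function(train, criteria = burstCriteria()) {
  if (is.unsorted(train))
    stop("spike train must be sorted")
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      n_spikes = integer(0), i_start = integer(0),
                      i_end = integer(0))
  n <- length(train)
  if (n < 2L) return(empty)
  isi <- diff(train) * 1000  # ms
  startMax <- criteria$maxIsiStartMs
  endMax <- criteria$maxIsiEndMs
  ## phase 1: candidate bursts
  cand <- list()
  i <- 1L
  while (i < n) {
    if (isi[i] <= startMax) {
      j <- i + 1L
      while (j < n && isi[j] <= endMax) j <- j + 1L
      cand[[length(cand) + 1L]] <- c(i, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(cand)) return(empty)
  ## phase 2: merge candidates separated by < minIbiMs
  merged <- list(cand[[1L]])
  if (length(cand) > 1L) {
    for (k in 2:length(cand)) {
      prev <- merged[[length(merged)]]
      gapMs <- (train[cand[[k]][1L]] - train[prev[2L]]) * 1000
      if (gapMs < criteria$minIbiMs)
        merged[[length(merged)]] <- c(prev[1L], cand[[k]][2L])
      else
        merged[[length(merged) + 1L]] <- cand[[k]]
    }
  }
  ## phase 3: duration / spike-count filters
  keep <- vapply(merged, function(b) {
    durMs <- (train[b[2L]] - train[b[1L]]) * 1000
    nSp <- b[2L] - b[1L] + 1L
    durMs >= criteria$minDurationMs && nSp >= criteria$minSpikes
  }, logical(1))
  merged <- merged[keep]
  if (!length(merged)) return(empty)
  data.frame(
    start_s = vapply(merged, function(b) train[b[1L]], numeric(1)),
    end_s = vapply(merged, function(b) train[b[2L]], numeric(1)),
    n_spikes = vapply(merged, function(b) b[2L] - b[1L] + 1L, integer(1)),
    i_start = vapply(merged, `[`, integer(1), 1L),
    i_end = vapply(merged, `[`, integer(1), 2L)
  )
}

#' The eight burst features of a spike train
#'
#' Computes, from a train and its detected bursts: spike rate (spikes/s),
#' burst rate (bursts/s), percentage of spikes in bursts, mean burst
#' duration (s), mean spikes per burst, mean intra-burst spike frequency
#' (spikes/s), mean intra-burst ISI (s) and mean inter-burst interval (s,
#' gap from one burst's end to the next one's start). Features undefined in
#' the absence of bursts are \code{NA} (missing, never zero-filled).
#'
#' @param train sorted numeric spike timestamps, seconds.
#' @param bursts result of \code{\link{detectBursts}} on the same train.
#' @param durationS recording duration, seconds (> 0).
#' @return One-row \code{data.frame} with the eight features.
#' @export
burstFeatures <- function(train, bursts, durationS) {
  if (durationS <= 0) stop("durationS must be > 0")
  nB <- nrow(bursts)
  out <- data.frame(
    spike_rate = length(train) / durationS,
    burst_rate = nB / durationS,
    pct_spikes_in_bursts = if (length(train))
      100 * sum(bursts$n_spikes) / length(train) else NA_real_,
    mean_burst_duration_s = NA_real_,
    mean_spikes_per_burst = NA_real_,
    mean_sf_in_burst = NA_real_,
    mean_isi_in_burst_s = NA_real_,
    mean_ibi_s = NA_real_
  )
  if (nB > 0) {
    dur <- bursts$end_s - bursts$start_s
    out$mean_burst_duration_s <- mean(dur)
    out$mean_spikes_per_burst <- mean(bursts$n_spikes)
    out$mean_sf_in_burst <- mean(bursts$n_spikes / dur)
    out$mean_isi_in_burst_s <- mean(vapply(seq_len(nB), function(k) {
      mean(diff(train[bursts$i_start[k]:bursts$i_end[k]]))
    }, numeric(1)))
    if (nB > 1)
      out$mean_ibi_s <- mean(bursts$start_s[-1L] - bursts$end_s[-nB])
  }
  out
}

#' Per-electrode burst feature table
#'
#' Runs \code{\link{detectBursts}} and \code{\link{burstFeatures}} on every
#' electrode of a spike table.
#'
#' @param table a \code{\linkS4class{SpikeTable}}.
#' @param criteria a \code{\link{burstCriteria}}.
#' @param electrodes optional subset of electrode ids.
#' @return \code{data.frame} with columns \code{electrode_id},
#'   \code{module_id}, \code{role}, \code{n_bursts} and the eight features.
#' @export
burstFeatureTable <- function(table, criteria = burstCriteria(),
                              electrodes = NULL) {
  stopifnot(is(table, "SpikeTable"))
  el <- table@layout@electrodes
  if (!is.null(electrodes)) el <- el[el$electrode_id %in% electrodes, ]
  rows <- lapply(seq_len(nrow(el)), function(i) {
    id <- el$electrode_id[i]
    train <- table@spikes[[id]]
    if (is.null(train)) train <- numeric(0)
    b <- detectBursts(train, criteria)
    cbind(
      data.frame(electrode_id = id, module_id = el$module_id[i],
                 role = el$role[i], n_bursts = nrow(b),
                 stringsAsFactors = FALSE),
      burstFeatures(train, b, table@durationS)
    )
  })
  do.call(rbind, rows)
}
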