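## Independent reference implementations used as oracles. These deliberately
## take different algorithmic routes than the package code they check.

## MaxInterval burst reference: explicit state machine over spikes, then
## pairwise merging, then filtering.
refBursts <- function(train, maxIsiStart = 20, maxIsiEnd = 10,
                      minIbi = 10, minDur = 20, minSpikes = 4) {
  n <- length(train)
  ms <- train * 1000
  cand <- list()
  state <- "out"
  first <- NA_integer_
  i <- 1L
  while (i < n) {
    isi <- ms[i + 1L] - ms[i]
    if (state == "out") {
      if (isi <= maxIsiStart) {
        state <- "in"
        first <- i
      }
    } else {
      if (isi > maxIsiEnd) {
        cand[[length(cand) + 1L]] <- c(first, i)
        state <- "out"
      }
    }
    i <- i + 1L
  }
  if (state == "in") cand[[length(cand) + 1L]] <- c(first, n)
  ## merge candidates closer than minIbi
  if (length(cand) > 1L) {
    out <- list(cand[[1L]])
    for (k in 2:length(cand)) {
      last <- out[[length(out)]]
      if (ms[cand[[k]][1L]] - ms[last[2L]] < minIbi)
        out[[length(out)]] <- c(last[1L], cand[[k]][2L])
      else out[[length(out) + 1L]] <- cand[[k]]
    }
    cand <- out
  }
  ## filter
  keep <- Filter(function(b) {
    (ms[b[2L]] - ms[b[1L]]) >= minDur && (b[2L] - b[1L] + 1L) >= minSpikes
  }, cand)
  if (!length(keep))
    return(data.frame(i_start = integer(0), i_end = integer(0)))
  data.frame(i_start = vapply(keep, `[`, integer(1), 1L),
             i_end = vapply(keep, `[`, integer(1), 2L))
}

## random spike train with bursty clumps for the burst-equivalence property
randomBurstyTrain <- function() {
  n_tonic <- sample(0:8, 1)
  train <- sort(runif(n_tonic, 0, 1))
  for (b in seq_len(sample(0:3, 1))) {
    t0 <- runif(1, 0, 0.9)
    k <- sample(2:7, 1)
    train <- c(train, t0 + cumsum(c(0, runif(k - 1, 0.002, 0.025))))
  }
  ts <- sort(train)
  ts[c(TRUE, diff(ts) > 1e-6)]
}

## Exhaustive maximum-disjoint-chain oracle: enumerate every complete chain
## satisfying the delay window, then branch-and-bound over chain subsets to
## maximize the number of pairwise spike-disjoint chains.
enumerateChains <- function(trains, minD, maxD) {
  k <- length(trains)
  chains <- list()
  extend <- function(chain, e) {
    if (e > k) {
      chains[[length(chains) + 1L]] <<- chain
      return(invisible())
    }
    cur <- trains[[e - 1L]][chain[e - 1L]]
    cand <- which(trains[[e]] >= cur + minD & trains[[e]] <= cur + maxD)
    for (j in cand) extend(c(chain, j), e + 1L)
  }
  for (i in seq_along(trains[[1L]])) extend(i, 2L)
  chains
}

maxDisjointChains <- function(trains, params) {
  chains <- enumerateChains(trains, params$minDelayS, params$maxDelayS)
  nc <- length(chains)
  if (nc == 0L) return(0L)
  k <- length(trains)
  best <- 0L
  used <- lapply(trains, function(tr) logical(length(tr)))
  recurse <- function(pos, count) {
    if (count + (nc - pos + 1L) <= best) return(invisible())
    if (pos > nc) {
      best <<- max(best, count)
      return(invisible())
    }
    ch <- chains[[pos]]
    free <- all(vapply(seq_len(k), function(e) !used[[e]][ch[e]],
                       logical(1)))
    if (free) {
      for (e in seq_len(k)) used[[e]][ch[e]] <<- TRUE
      recurse(pos + 1L, count + 1L)
      for (e in seq_len(k)) used[[e]][ch[e]] <<- FALSE
    }
    recurse(pos + 1L, count)
  }
  recurse(1L, 0L)
  best
}

## random matching instance: a few true propagation chains plus noise
## spikes, capped at maxPerElectrode spikes per electrode
randomChainInstance <- function(maxPerElectrode = 12L, nElectrodes = 5L,
                                pitchUm = 200) {
  trains <- rep(list(numeric(0)), nElectrodes)
  for (ch in seq_len(sample(0:4, 1))) {
    v <- runif(1, 0.15, 1.1)
    t0 <- runif(1, 0, 0.2)
    base <- t0 + (seq_len(nElectrodes) - 1L) * pitchUm * 1e-6 / v
    arr <- base + rnorm(nElectrodes, 0, 2e-5)
    arr <- sort(arr)
    for (e in seq_len(nElectrodes))
      trains[[e]] <- c(trains[[e]], arr[e])
  }
  for (e in seq_len(nElectrodes)) {
    extra <- sample(0:4, 1)
    trains[[e]] <- c(trains[[e]], runif(extra, 0, 0.21))
    trains[[e]] <- sort(unique(trains[[e]]))
    if (length(trains[[e]]) > maxPerElectrode)
      trains[[e]] <- sort(sample(trains[[e]], maxPerElectrode))
  }
  trains
}

## brute-force velocity binning: explicit per-bin comparisons
refBinCounts <- function(v, edges) {
  nb <- length(edges) - 1L
  counts <- integer(nb)
  for (x in v) {
    for (b in seq_len(nb)) {
      hi_ok <- if (b == nb) x <= edges[b + 1L] else x < edges[b + 1L]
      if (x >= edges[b] && hi_ok) {
        counts[b] <- counts[b] + 1L
        break
      }
    }
  }
  counts
}

## analytic gain of the order-2 Bessel high-pass, via complex evaluation of
## the analog transfer function (independent of the package formula)
refBesselGain <- function(freqHz, cutoffHz) {
  wN <- sqrt((-3 + sqrt(45)) / 2)
  s <- 1i * 2 * pi * freqHz
  a1 <- wN * 2 * pi * cutoffHz
  Mod(s^2 / (s^2 + a1 * s + a1^2 / 3))
}

## steady-state amplitude of a filtered sinusoid (discard the transient)
measureGain <- function(freqHz, fs, durS = 0.5, params = detectionParams()) {
  t <- seq(0, durS, by = 1 / fs)
  y <- highpassFilter(sin(2 * pi * freqHz * t), fs, params)
  tail <- y[round(length(y) / 2):length(y)]
  (max(tail) - min(tail)) / 2
}

## small two-module layout for cheap tests
smallLayout <- function() buildDefaultLayout(nModules = 2L)
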