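test_that("matching parameters imply the 0.1 m/s velocity floor", {
  p <- matchParams()
  expect_identical(p$minVelocityMS, 0.1)
  expect_identical(p$pitchUm / (p$maxDelayS * 1e6), 0.1)
  expect_error(matchParams(minDelayS = 0), "minDelayS")
})

test_that("a clean chain yields one event with the right velocity", {
  trains <- lapply(0:4 * 4e-4, function(d) 0.1 + d)
  ev <- matchPropagatingSpikes(trains)
  expect_identical(nrow(ev), 1L)
  expect_equal(unlist(ev[paste0("v_", 1:4)]), rep(0.5, 4),
               ignore_attr = TRUE)
  expect_equal(ev$mean_velocity, 0.5)

  ## incomplete traversal (electrode 5 silent): no event
  trains[[5]] <- numeric(0)
  expect_identical(nrow(matchPropagatingSpikes(trains)), 0L)

  expect_error(matchPropagatingSpikes(trains[1:4]), "5 electrode")
  expect_error(matchPropagatingSpikes(list(c(2, 1), 1, 1, 1, 1)), "sorted")
})

test_that("events satisfy their invariants on random instances", {
  withr::with_seed(77, {
    p <- matchParams()
    for (i in 1:100) {
      trains <- randomChainInstance()
      ev <- matchPropagatingSpikes(trains, p)
      if (!nrow(ev)) next
      arr <- as.matrix(ev[paste0("t", 1:5)])
      expect_true(all(apply(arr, 1, function(r) all(diff(r) > 0))))
      d <- as.matrix(ev[paste0("delay_", 1:4)])
      expect_true(all(d >= p$minDelayS & d <= p$maxDelayS))
      v <- as.matrix(ev[paste0("v_", 1:4)])
      expect_true(all(v >= p$minVelocityMS))
      expect_equal(ev$mean_velocity, rowMeans(v), ignore_attr = TRUE)
    }
  })
})

test_that("greedy matching attains the exhaustive maximum-chain count", {
  withr::with_seed(88, {
    p <- matchParams()
    for (i in 1:200) {
      trains <- randomChainInstance()
      greedy <- nrow(matchPropagatingSpikes(trains, p))
      expect_identical(greedy, maxDisjointChains(trains, p))
    }
  })
})

test_that("interleaved chains from two axons are separated at their velocities", {
  cfg <- simulationConfig(durationS = 60, tonicRateHz = 2, burstRateHz = 0,
                          nAxonsPerChannel = 2, trueVelocityMS = c(0.4, 0.8),
                          jitterMs = 0.02, detectionProb = 1, seed = 13)
  sim <- simulateSpontaneous(cfg, buildDefaultLayout(nModules = 1))
  ev <- propagationEvents(sim$spikes, velocityMethod = "harmonic")
  nEmitted <- sum(sim$truth$axons$n_emitted)
  expect_gte(nrow(ev) / nEmitted, 0.98)
  ## nearly all events sit at one of the two true velocities (time-of-flight
  ## estimate); the few others are cross-axon mismatches from
  ## near-coincident spikes
  near <- abs(ev$mean_velocity - 0.4) / 0.4 < 0.1 |
    abs(ev$mean_velocity - 0.8) / 0.8 < 0.1
  expect_gte(mean(near), 0.95)
  ## and the two classes average to the true velocities
  cls <- ifelse(abs(ev$mean_velocity - 0.4) < abs(ev$mean_velocity - 0.8),
                0.4, 0.8)
  for (v in c(0.4, 0.8))
    expect_equal(mean(ev$mean_velocity[cls == v]), v, tolerance = 0.03)
})

test_that("channel velocity summary and proximal/distal split behave", {
  expect_identical(channelVelocitySummary(
    matchPropagatingSpikes(rep(list(numeric(0)), 5)))$n, 0L)

  trains <- lapply(0:4 * 4e-4, function(d) c(0.1, 2) + d)
  ev <- matchPropagatingSpikes(trains)
  ev$mean_velocity <- c(0.4, 0.6)
  s <- channelVelocitySummary(ev)
  expect_equal(s$mean, 0.5); expect_identical(s$n, 2L)

  ## symmetric event: proximal == distal
  ev1 <- matchPropagatingSpikes(lapply(0:4 * 4e-4, function(d) 0.1 + d))
  pd <- proximalDistalVelocities(ev1)
  expect_equal(pd$proximal, 0.5); expect_equal(pd$distal, 0.5)

  ## hand-set pair velocities {0.6, 0.6, 0.4, 0.4}
  ev1[paste0("v_", 1:4)] <- as.list(c(0.6, 0.6, 0.4, 0.4))
  pd <- proximalDistalVelocities(ev1)
  expect_equal(pd$proximal, 0.6); expect_equal(pd$distal, 0.4)
})

test_that("segment-dependent velocities are recovered from simulation", {
  ## proximal 0.6 m/s, distal 0.45 m/s: build arrivals directly
  pos <- c(100, 300, 500, 700, 900)
  vProx <- 0.6; vDist <- 0.45
  emit <- seq(0.1, 50, by = 0.25)
  arr <- sapply(pos, function(x) {
    tProx <- pmin(x, 500) * 1e-6 / vProx
    tDist <- pmax(x - 500, 0) * 1e-6 / vDist
    emit + tProx + tDist
  })
  withr::with_seed(3, arr <- arr + matrix(rnorm(length(arr), 0, 2e-5),
                                          nrow(arr)))
  trains <- lapply(1:5, function(k) sort(arr[, k]))
  ev <- matchPropagatingSpikes(trains)
  pd <- proximalDistalVelocities(ev)
  expect_equal(pd$proximal, 0.6, tolerance = 0.05)
  expect_equal(pd$distal, 0.45, tolerance = 0.05)
})

test_that("velocity histogram matches brute-force binning", {
  h <- velocityHistogram(rep(0.55, 7))
  expect_identical(length(h$counts), 11L)
  expect_equal(h$percentages[5], 100)
  expect_identical(sum(h$counts), 7L)

  h0 <- velocityHistogram(numeric(0))
  expect_identical(sum(h0$counts), 0L)
  expect_true(all(is.na(h0$percentages)))

  withr::with_seed(12, {
    v <- c(rnorm(600, 0.5, 0.15), rnorm(400, 0.9, 0.2))
    h <- velocityHistogram(v)
    edges <- seq(0.1, 1.2, by = 0.1)
    expect_identical(h$counts, refBinCounts(v, edges))
    expect_identical(h$overflow, sum(v < 0.1 | v > 1.2))
    expect_equal(sum(h$percentages), 100)
  })
})

test_that("shuffling spike insertion order does not change matching output", {
  withr::with_seed(5, {
    trains <- randomChainInstance()
    ev1 <- matchPropagatingSpikes(trains)
    ## rebuild each train from a shuffled copy (sorted input required)
    trains2 <- lapply(trains, function(tr) sort(sample(tr)))
    ev2 <- matchPropagatingSpikes(trains2)
    expect_equal(ev1, ev2)
  })
})

test_that("propagation-count correlation behaves on degenerate and clean input", {
  expect_error(propagationCountCorrelation(1:2, 1:2), "at least 3")
  r <- propagationCountCorrelation(c(10, 20, 30, 40), c(1, 2, 3, 4))
  expect_equal(r$r, 1)
  r0 <- propagationCountCorrelation(c(10, 20, 30, 40), c(2, 2, 2, 2))
  expect_identical(r0$r, 0)
  expect_true(r0$degenerate)

  ## coupled simulation with known correlation ~0.5
  withr::with_seed(19, {
    z <- rnorm(200); e <- rnorm(200)
    x <- 50 + 10 * z
    y <- 20 + 5 * (0.5 * z + sqrt(0.75) * e)
    res <- propagationCountCorrelation(x, y)
    expect_lt(abs(res$r - 0.5), 3 / sqrt(200))
  })
})
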