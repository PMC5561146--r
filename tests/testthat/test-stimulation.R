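mkSession <- function(nTrials = 20, moduleId = 1L) {
  stimulationSession(seq_len(nTrials) - 1, 500, "m01_ch0", moduleId)
}

## table with one spike per trial at a fixed latency on one electrode
mkTable <- function(latMs, nTrials = 20, id = "m01_ch1", extra = NULL) {
  tab <- emptySpikeTable(smallLayout(), nTrials)
  ts <- sort(unlist(lapply(latMs, function(l) (seq_len(nTrials) - 1) + l / 1000)))
  if (!is.null(extra)) ts <- sort(c(ts, extra))
  tab@spikes[[id]] <- ts
  tab
}

test_that("alignment blanks the artifact period and keeps 1 s trials", {
  ses <- mkSession()
  ras <- alignPeristimulus(emptySpikeTable(smallLayout(), 20), ses)
  expect_identical(nrow(ras$raster), 0L)
  expect_identical(ras$nTrials, 20L)

  ## spike at pulse + 3 ms is inside the 5 ms blanking: discarded, counted
  ras3 <- alignPeristimulus(mkTable(3), ses)
  expect_identical(nrow(ras3$raster), 0L)
  expect_identical(ras3$blankedCount, 20L)

  ras10 <- alignPeristimulus(mkTable(10), ses)
  expect_identical(nrow(ras10$raster), 20L)
  expect_equal(ras10$raster$t_ms, rep(10, 20), tolerance = 1e-9)

  ## overlapping trials rejected unless the span is shortened
  fast <- stimulationSession(seq(0, 9.5, by = 0.5), 500, "m01_ch0", 1L)
  expect_error(alignPeristimulus(mkTable(10), fast), "spacing")
  short <- windowScheme(windowsMs = list(direct = c(5, 35)),
                        trialSpanMs = 400)
  expect_silent(alignPeristimulus(mkTable(10, nTrials = 10), fast, short))
})

test_that("simulator ground truth reappears exactly in the raster", {
  cfg <- simulationConfig(durationS = 30, tonicRateHz = 0, burstRateHz = 0,
                          jitterMs = 0, seed = 8)
  stim <- stimulationConfig(nTrials = 30, pDirect = 0.7, pLate = 0,
                            evokedVelocityMS = 0.5)
  ses <- simulateStimulationSession(cfg, stim, smallLayout())
  ras <- alignPeristimulus(ses$spikes, ses$session)
  tr <- ses$truth$trials
  respTrials <- sort(unique(ras$raster$trial))
  expect_identical(respTrials, tr$trial[tr$direct])
  ## first-electrode latency equals the drawn latency exactly (jitter 0)
  first <- ras$raster[ras$raster$electrode_id == "m01_ch1", ]
  expect_equal(sort(first$t_ms), sort(tr$direct_latency_ms[tr$direct]),
               tolerance = 1e-9)
})

test_that("window rates match hand-computed values and are additive", {
  ras <- alignPeristimulus(mkTable(10, nTrials = 180,
                                   extra = NULL),
                           mkSession(180))
  wr <- windowRates(ras)
  expect_equal(wr$rate_hz[wr$window == "direct_early"], 100)  # 180/(180*0.01)
  expect_equal(sum(wr$n_spikes), 180L)

  ## additivity: rate over 5-35 equals length-weighted mean of 5-15, 15-35
  sch <- windowScheme(windowsMs = list(a = c(5, 15), b = c(15, 35)))
  schU <- windowScheme(windowsMs = list(u = c(5, 35)))
  ras2 <- alignPeristimulus(mkTable(c(8, 20, 30), nTrials = 10), mkSession(10))
  wr2 <- windowRates(ras2, sch)
  wrU <- windowRates(ras2, schU)
  expect_equal(wrU$rate_hz,
               (10 * wr2$rate_hz[1] + 20 * wr2$rate_hz[2]) / 30)

  empty <- alignPeristimulus(emptySpikeTable(smallLayout(), 20), mkSession())
  expect_true(all(windowRates(empty)$rate_hz == 0))
})

test_that("fidelity counts trials, not spikes, and handles forced cases", {
  ## every trial responds once in 5-15 ms
  ras <- alignPeristimulus(mkTable(10), mkSession())
  fid <- responseFidelity(ras)
  expect_equal(fid$fidelity_pct[1], 100)
  expect_equal(fid$fidelity_pct[2:3], c(0, 0))

  ## spike multiplicity within a bin does not change fidelity
  ras2 <- alignPeristimulus(mkTable(c(8, 10, 12)), mkSession())
  expect_equal(responseFidelity(ras2)$fidelity_pct[1], 100)

  ## half the trials respond -> 50%
  tab <- emptySpikeTable(smallLayout(), 20)
  tab@spikes[["m01_ch1"]] <- (0:9) * 2 + 0.010
  ras3 <- alignPeristimulus(tab, mkSession())
  expect_equal(responseFidelity(ras3)$fidelity_pct[1], 50)
})

test_that("increasing blanking never increases any window's spike count", {
  cfg <- simulationConfig(durationS = 40, tonicRateHz = 5, burstRateHz = 0.2,
                          seed = 14)
  stim <- stimulationConfig(nTrials = 40, pDirect = 0.9)
  ses <- simulateStimulationSession(cfg, stim, smallLayout())
  counts <- sapply(c(5, 8, 12), function(bl) {
    ses$session@blankingMs <- bl
    sch <- windowScheme(windowsMs = list(w1 = c(12, 35), w2 = c(35, 950)))
    ras <- alignPeristimulus(ses$spikes, ses$session, sch)
    c(nrow(ras$raster), windowRates(ras, sch)$n_spikes)
  })
  expect_true(all(diff(t(counts)) <= 0))
})

test_that("evoked velocities are recovered per peri-stimulus window", {
  cfg <- simulationConfig(durationS = 120, tonicRateHz = 0, burstRateHz = 0,
                          jitterMs = 0.02, seed = 23)
  stim <- stimulationConfig(nTrials = 120, pDirect = 0.9, pLate = 0.5,
                            evokedVelocityMS = 0.6, lateVelocityMS = 0.5,
                            lateWindowsMs = list(c(35, 300)))
  ses <- simulateStimulationSession(cfg, stim, smallLayout())
  ev <- evokedVelocity(ses$spikes, ses$session)
  direct <- ev[ev$window == "direct", ]
  late <- ev[ev$window == "late", ]
  expect_gt(direct$n_events, 50)
  expect_equal(direct$mean_velocity, 0.6, tolerance = 0.05 * 0.6)
  expect_equal(late$mean_velocity, 0.5, tolerance = 0.05 * 0.5)

  ## no direct chains -> direct window flagged missing
  stim0 <- stimulationConfig(nTrials = 20, pDirect = 0, pLate = 0)
  cfg0 <- simulationConfig(durationS = 20, tonicRateHz = 0, burstRateHz = 0,
                           seed = 3)
  ses0 <- simulateStimulationSession(cfg0, stim0, smallLayout())
  ev0 <- evokedVelocity(ses0$spikes, ses0$session)
  expect_true(all(is.na(ev0$mean_velocity)))
  expect_true(all(ev0$n_events == 0))
})
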