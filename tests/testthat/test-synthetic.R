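test_that("zero firing rates yield an empty table", {
  cfg <- simulationConfig(durationS = 10, tonicRateHz = 0, burstRateHz = 0,
                          seed = 1)
  sim <- simulateSpontaneous(cfg, smallLayout())
  expect_identical(nSpikes(sim$spikes), 0L)
})

test_that("invalid config fields are rejected by name", {
  expect_error(simulationConfig(durationS = -1), "durationS")
  expect_error(simulationConfig(detectionProb = 1.5), "detectionProb")
  expect_error(simulationConfig(jitterMs = -0.1), "jitterMs")
  expect_error(stimulationConfig(nTrials = 0), "nTrials")
})

test_that("noise-free propagation gives exact 0.4 ms pairwise delays at 0.5 m/s", {
  cfg <- simulationConfig(durationS = 30, tonicRateHz = 2, burstRateHz = 0,
                          nAxonsPerChannel = 1, trueVelocityMS = 0.5,
                          jitterMs = 0, detectionProb = 1, seed = 3)
  sim <- simulateSpontaneous(cfg, smallLayout())
  lay <- deviceLayout(sim$spikes)
  for (m in 1:2) {
    trains <- spikeTrains(sim$spikes, channelElectrodes(lay, m))
    lens <- lengths(trains)
    expect_true(all(lens == lens[1]))  # every spike on all 5 electrodes
    for (k in 2:5)
      expect_equal(trains[[k]] - trains[[k - 1]],
                   rep(4e-4, lens[1]), tolerance = 1e-8)
  }
})

test_that("tonic emission counts follow the Poisson expectation", {
  counts <- sapply(1:20, function(s) {
    cfg <- simulationConfig(durationS = 100, tonicRateHz = 5, burstRateHz = 0,
                            nAxonsPerChannel = 1, refractoryMs = 0, seed = s)
    sim <- simulateSpontaneous(cfg, buildDefaultLayout(nModules = 1))
    sim$truth$axons$n_emitted
  })
  ## mean of 20 Poisson(500) counts: 3 sigma of the mean = 3*sqrt(500/20)
  expect_lt(abs(mean(counts) - 500), 3 * sqrt(500 / 20))
})

test_that("simulation is deterministic given a seed", {
  cfg <- simulationConfig(durationS = 20, seed = 11)
  a <- simulateSpontaneous(cfg, smallLayout())
  b <- simulateSpontaneous(cfg, smallLayout())
  expect_identical(spikeTrains(a$spikes), spikeTrains(b$spikes))
  expect_identical(a$truth$axons, b$truth$axons)
  cfg2 <- simulationConfig(durationS = 20, seed = 12)
  c <- simulateSpontaneous(cfg2, smallLayout())
  expect_false(identical(spikeTrains(a$spikes), spikeTrains(c$spikes)))
})

test_that("ground-truth arrivals follow the position/velocity rule and are monotone", {
  cfg <- simulationConfig(durationS = 20, tonicRateHz = 3, nAxonsPerChannel = 2,
                          jitterMs = 0.05, seed = 5)
  sim <- simulateSpontaneous(cfg, smallLayout())
  pos <- channelPositions(smallLayout(), 1)
  for (ax in sim$truth$axons$axon_id) {
    arr <- sim$truth$arrivals[[ax]]
    if (!nrow(arr)) next
    expect_true(all(apply(arr, 1, function(r) all(diff(r) > 0))))
    v <- sim$truth$axons$velocity_m_s[sim$truth$axons$axon_id == ax]
    base <- outer(sim$truth$emissions[[ax]], pos * 1e-6 / v, `+`)
    expect_lt(max(abs(arr - base)), 6 * cfg$jitterMs / 1000)
  }
})

test_that("forced stimulation responses land in the direct window only", {
  cfg <- simulationConfig(durationS = 20, tonicRateHz = 0, burstRateHz = 0,
                          jitterMs = 0.02, seed = 2)
  stim <- stimulationConfig(nTrials = 20, pDirect = 1, pLate = 0)
  ses <- simulateStimulationSession(cfg, stim, smallLayout())
  ras <- alignPeristimulus(ses$spikes, ses$session)
  perTrial <- table(factor(ras$raster$trial[ras$raster$t_ms > 5 &
                                              ras$raster$t_ms <= 15],
                           levels = 1:20))
  expect_true(all(perTrial >= 1))
  expect_identical(sum(ras$raster$t_ms > 35), 0L)

  stim0 <- stimulationConfig(nTrials = 20, pDirect = 0, pLate = 0)
  ses0 <- simulateStimulationSession(cfg, stim0, smallLayout())
  expect_identical(nSpikes(ses0$spikes), 0L)
})

test_that("rendered traces have the configured noise floor and spike trough", {
  lay <- smallLayout()
  withr::with_seed(9, {
    cfg <- simulationConfig(durationS = 1, noiseSigmaUv = 10, seed = NULL)
    empty <- emptySpikeTable(lay, 1)
    rec <- renderRawTraces(empty, cfg)
    expect_equal(sd(voltageTraces(rec)[[1]]), 10, tolerance = 0.05)

    one <- emptySpikeTable(lay, 1)
    one@spikes[["m01_ch0"]] <- 0.5
    rec2 <- renderRawTraces(one, cfg, amplitudesUv = 450)
    tr <- voltageTraces(rec2)[["m01_ch0"]]
    expect_equal(min(tr), -450, tolerance = 0.15)
    expect_lt(abs(which.min(tr) / 25000 - 0.5), 2e-4)

    ## 45 uV spikes over 10 uV noise: SNR 4.5, inside the observed 2-35 band
    rec3 <- renderRawTraces(one, cfg, amplitudesUv = 45)
    snr <- 45 / sd(voltageTraces(rec3)[["m02_ch0"]])
    expect_gt(snr, 2); expect_lt(snr, 35)
  })
  expect_error(renderRawTraces(emptySpikeTable(lay, 1),
                               simulationConfig(samplingRateHz = 5000)),
               "10 kHz")
})

test_that("measured response fidelity matches the configured probability", {
  ## jitter 0 so the measured fidelity is exactly the simulator's Bernoulli
  ## draw (jitter can push an edge-of-bin latency across the bin boundary)
  fid <- sapply(1:50, function(s) {
    cfg <- simulationConfig(durationS = 180, tonicRateHz = 0, burstRateHz = 0,
                            jitterMs = 0, seed = s)
    stim <- stimulationConfig(nTrials = 180, pDirect = 0.8, pLate = 0)
    ses <- simulateStimulationSession(cfg, stim, smallLayout())
    ras <- alignPeristimulus(ses$spikes, ses$session)
    responseFidelity(ras)$fidelity_pct[1]
  })
  ## 99% binomial CI for the mean of 50 x 180 Bernoulli(0.8) trials
  se <- sqrt(0.8 * 0.2 / (50 * 180))
  expect_lt(abs(mean(fid) / 100 - 0.8), qnorm(0.995) * se)
})
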