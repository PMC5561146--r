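test_that("series normalization divides by the grand mean and is idempotent", {
  expect_equal(normalizeSeries(c(5, 5, 5)), c(1, 1, 1))
  expect_equal(normalizeSeries(c(2, 4, 6)), c(0.5, 1.0, 1.5))
  withr::with_seed(2, {
    x <- runif(50, 1, 10)
    nx <- normalizeSeries(x)
    expect_equal(mean(nx), 1, tolerance = 1e-12)
    expect_equal(normalizeSeries(nx), nx)
  })
  x <- c(3, NA, 9)
  expect_equal(normalizeSeries(x), c(0.5, NA, 1.5))
  expect_error(normalizeSeries(c(-1, 1)), "zero")
})

test_that("Pearson correlation matches the closed form and flags degeneracy", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearsonCorrelation(x, 2 * x + 1)$r, 1)
  expect_equal(pearsonCorrelation(x, -x)$r, -1)
  expect_error(pearsonCorrelation(1:2, 1:2), "at least 3")
  expect_true(pearsonCorrelation(x, rep(2, 4))$degenerate)

  xx <- c(1, 2, 3); yy <- c(2, 4, 5)
  direct <- sum((xx - mean(xx)) * (yy - mean(yy))) /
    sqrt(sum((xx - mean(xx))^2) * sum((yy - mean(yy))^2))
  expect_equal(pearsonCorrelation(xx, yy)$r, direct)

  ## invariance under positive affine transforms
  withr::with_seed(30, {
    a <- rnorm(20); b <- rnorm(20)
    r0 <- pearsonCorrelation(a, b)$r
    expect_equal(pearsonCorrelation(3 * a + 7, b)$r, r0)
    expect_equal(pearsonCorrelation(a, 0.2 * b - 4)$r, r0)
  })

  ## missing pairs dropped
  expect_identical(pearsonCorrelation(c(1, 2, 3, NA), c(2, 4, 5, 9))$n, 3L)
})

test_that("activity-velocity table correlates each feature with velocity", {
  feats <- data.frame(module_id = rep(1:5, 3), div = rep(c(10, 20, 30), each = 5))
  withr::with_seed(41, {
    feats$burst_rate <- runif(15, 0.1, 1)
    feats$spike_rate <- runif(15, 1, 5)
  })
  vel <- data.frame(module_id = feats$module_id, div = feats$div,
                    velocity = feats$burst_rate)  # velocity copies a feature
  tab <- activityVelocityTable(feats, vel, mode = "pooled")
  expect_equal(tab$r[tab$feature == "burst_rate"], 1)
  expect_identical(nrow(tab), 2L)

  perDay <- activityVelocityTable(feats, vel, mode = "per-day")
  expect_identical(nrow(perDay), 6L)
  expect_equal(perDay$r[perDay$feature == "burst_rate"], rep(1, 3))

  expect_error(activityVelocityTable(feats[-1], vel), "module_id")
  expect_error(activityVelocityTable(feats, vel[c("module_id", "div")]),
               "velocity")

  ## independent feature and velocity: |r| small at n = 500
  withr::with_seed(43, {
    f2 <- data.frame(module_id = 1:500, div = 1, x = rnorm(500))
    v2 <- data.frame(module_id = 1:500, div = 1, velocity = rnorm(500))
    expect_lt(abs(activityVelocityTable(f2, v2)$r), 0.12)
  })
})

test_that("condition comparison reports paired differences", {
  base <- data.frame(electrode_id = sprintf("e%d", 1:10),
                     spike_rate = seq(1, 10))
  same <- compareConditions(base, base)
  expect_equal(same$mean_difference, 0)
  expect_equal(same$t, 0)

  up <- base; up$spike_rate <- up$spike_rate + 2.5
  shift <- compareConditions(base, up)
  expect_equal(shift$mean_difference, 2.5)
  expect_identical(shift$n_pairs, 10L)

  extra <- rbind(up, data.frame(electrode_id = "e99", spike_rate = 5))
  expect_warning(res <- compareConditions(base, extra), "unpaired")
  expect_identical(res$n_pairs, 10L)
})

test_that("age-driven common trends pool into correlation but vanish per day", {
  pooled_r <- numeric(20); perday_r <- numeric(20); vshift <- numeric(20)
  for (s in 1:20) {
    study <- simulateAgingStudy(seed = s)
    ## normalization to each module's study-long mean removes between-module
    ## level differences, isolating the within-day association
    pooled <- activityVelocityTable(study$features, study$velocities,
                                    mode = "pooled", normalize = TRUE)
    perday <- activityVelocityTable(study$features, study$velocities,
                                    mode = "per-day", normalize = TRUE)
    pooled_r[s] <- pooled$r[pooled$feature == "burst_rate"]
    perday_r[s] <- mean(perday$r[perday$feature == "burst_rate"])
    ## disinhibition at fixed age: activity up 3x, velocity unchanged
    lastDiv <- max(study$features$div)
    fb <- study$features[study$features$div == lastDiv, ]
    vb <- study$velocities[study$velocities$div == lastDiv, ]
    treated <- simulateDisinhibition(fb, vb, seed = s + 1000)
    cmpV <- compareConditions(cbind(vb, id = vb$module_id),
                              cbind(treated$velocities, id = vb$module_id),
                              by = "id", features = "velocity")
    cmpR <- compareConditions(cbind(fb, id = fb$module_id),
                              cbind(treated$features, id = fb$module_id),
                              by = "id", features = "spike_rate")
    vshift[s] <- cmpV$mean_difference / cmpV$mean_baseline
    expect_lt(cmpR$p, 0.001)  # rate increase is unambiguous
    expect_gt(cmpR$mean_treated / cmpR$mean_baseline, 2)
  }
  expect_true(all(pooled_r > 0.3))
  expect_lt(abs(mean(perday_r)), 0.1)
  expect_lt(max(abs(vshift)), 0.05)
})

test_that("ISI and IBI trends correlate negatively with velocity when pooled", {
  study <- simulateAgingStudy(seed = 7)
  pooled <- activityVelocityTable(study$features, study$velocities)
  expect_gt(pooled$r[pooled$feature == "pct_spikes_in_bursts"], 0.2)
  expect_lt(pooled$r[pooled$feature == "mean_isi_in_burst_s"], -0.2)
  expect_lt(pooled$r[pooled$feature == "mean_ibi_s"], -0.2)
})
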