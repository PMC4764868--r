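test_that("simConfig validates its fields", {
  expect_s4_class(simConfig(), "SimConfig")
  expect_error(simConfig(nTimepoints = 1L), "nTimepoints")
  expect_error(simConfig(lossProb = 1.5), "lossProb")
  expect_error(simConfig(gainRate = -1), "rates")
  expect_error(simConfig(voxelSize = c(-0.1, 0.1, 1)), "voxelSize")
  expect_error(simConfig(volumeShape = c(64L, 64L)), "volumeShape")
})

test_that("generateSeries is deterministic in the seed and leaves the RNG
           stream alone", {
  cfg <- tinyConfig(seed = 5L)
  set.seed(123); before <- runif(1)
  s1 <- generateSeries(cfg)
  s2 <- generateSeries(cfg)
  expect_identical(imageSeries(s1)@data, imageSeries(s2)@data)
  expect_identical(groundTruth(s1), groundTruth(s2))
  s3 <- generateSeries(tinyConfig(seed = 6L))
  expect_false(identical(imageSeries(s1)@data, imageSeries(s3)@data))
  set.seed(123)
  expect_identical(before, runif(1)) # with_seed restored global RNG
})

test_that("series geometry matches the config", {
  cfg <- tinyConfig(seed = 2L)
  ss <- generateSeries(cfg)
  s <- imageSeries(ss)
  expect_identical(dim(s@data)[1:3], cfg@volumeShape)
  expect_identical(nTimepoints(s), cfg@nTimepoints)
  expect_identical(channelNames(s), c("puncta", "reference"))
  expect_identical(timepointsMin(s), (seq_len(cfg@nTimepoints) - 1) * 30)
})

test_that("applied drift is zero at t1 and bounded by driftMax", {
  ss <- generateSeries(tinyConfig(seed = 3L))
  dr <- appliedDrift(ss)
  expect_equal(unname(dr[1, ]), c(0, 0, 0))
  expect_true(all(abs(t(dr)) <= c(3, 3, 1)))
})

test_that("ground truth counts are conserved and transport packets live one
           timepoint", {
  for (seed in 1:5) {
    tr <- groundTruth(generateSeries(tinyConfig(seed = seed)))
    cnt <- punctaTurnover:::truthSessionCounts(tr, 7L)
    expect_equal(cnt[["n_t3h"]],
                 cnt[["n_t0"]] + cnt[["n_gain"]] - cnt[["n_lost"]])
    pk <- tr[tr$is_transport_packet, ]
    expect_true(all(pk$birth_tp == pk$death_tp))
  }
})

test_that("coexisting puncta respect the minimum lateral-equivalent
           separation", {
  cfg <- tinyConfig(seed = 9L)
  tr <- groundTruth(generateSeries(cfg))
  tr <- tr[!tr$is_transport_packet, ]
  zScale <- cfg@psfFwhmXY / cfg@psfFwhmZ
  p <- cbind(tr$x_um, tr$y_um, tr$z_um * zScale)
  for (i in seq_len(nrow(tr) - 1L)) for (j in seq(i + 1L, nrow(tr))) {
    overlap <- tr$birth_tp[i] <= tr$death_tp[j] &&
      tr$birth_tp[j] <= tr$death_tp[i]
    if (overlap)
      expect_gte(sqrt(sum((p[i, ] - p[j, ])^2)),
                 cfg@minSeparationUm - 1e-9)
  }
})

test_that("noiseless render peaks at the configured amplitude near truth", {
  cfg <- tinyConfig(seed = 4L, readNoiseSD = 0, shotNoise = FALSE,
                    driftMax = c(0L, 0L, 0L), gainRate = 0, lossProb = 0,
                    transportPacketRate = 0)
  ss <- generateSeries(cfg)
  v <- getVolume(imageSeries(ss), 1L, "puncta")
  tr <- groundTruth(ss)
  for (i in seq_len(nrow(tr))) {
    ix <- round(c(tr$x_um[i], tr$y_um[i], tr$z_um[i]) / cfg@voxelSize) + 1L
    expect_gte(v[ix[1], ix[2], ix[3]],
               cfg@backgroundLevel + 0.4 * cfg@punctumAmplitude)
  }
})

test_that("expectedSessionCounts is seeded and reports Monte-Carlo error", {
  cfg <- tinyConfig(seed = 1L)
  a <- expectedSessionCounts(cfg, nReps = 120L, seed = 77L)
  b <- expectedSessionCounts(cfg, nReps = 120L, seed = 77L)
  expect_identical(a$mean, b$mean)
  expect_true(all(a$se[c("n_gain", "n_lost", "turnover_pct")] > 0))
  expect_error(expectedSessionCounts(cfg, nReps = 10L), "100")
})

test_that("generateSpikeTrials produces trials with roughly the requested
           rates", {
  ts <- generateSpikeTrials(baselineRate = 5, stimRate = 20, nTrials = 200L,
                            seed = 2L)
  expect_identical(nTrials(ts), 200L)
  d <- deltaFR(ts)
  expect_lt(abs(mean(d$baseline_rate_hz) - 5), 0.5)
  expect_lt(abs(mean(d$stim_rate_hz) - 20), 1)
  expect_true(all(vapply(spikeTrials(ts),
                         function(s) !is.unsorted(s) && all(s >= 0 & s <= 6),
                         logical(1))))
})
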