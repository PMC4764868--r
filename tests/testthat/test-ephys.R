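test_that("high-pass filter removes slow components and keeps fast ones", {
  fs <- 20000
  t <- seq(0, 1, by = 1 / fs)
  slow <- sin(2 * pi * 10 * t)          # 10 Hz, far below 500 Hz cutoff
  fast <- sin(2 * pi * 3000 * t)        # 3 kHz, passband
  f <- highpassFilter(slow + fast + 5, fs)
  mid <- seq(round(fs * 0.2), round(fs * 0.8)) # ignore filter edges
  expect_lt(sd(f[mid] - fast[mid]), 0.1 * sd(fast[mid]))
  expect_lt(abs(mean(f[mid])), 0.05)
  expect_error(highpassFilter(fast, samplingRate = 900), "Nyquist")
})

test_that("robust RMS implements median(|x|)/0.6745 and resists spikes", {
  x <- c(-2, -1, 0, 1, 2)
  expect_equal(noiseRMS(x, method = "robust"), median(abs(x)) / 0.6745)
  expect_equal(noiseRMS(x, method = "raw"), sqrt(mean(x^2)))
  set.seed(81)
  noise <- rnorm(20000)
  spiky <- noise
  spiky[seq(1, 20000, by = 200)] <- 50 # 0.5% huge spikes
  expect_lt(abs(noiseRMS(spiky) - noiseRMS(noise)), 0.05)
  expect_gt(noiseRMS(spiky, method = "raw"), 2)
})

test_that("detectSpikes recovers seeded spike times with a refractory
           period", {
  fs <- 20000
  n <- fs # 1 s
  set.seed(82)
  x <- rnorm(n, 0, 1)
  trueIdx <- c(2000, 6000, 6010, 12000) # 6010 within 1 ms of 6000
  x[trueIdx] <- c(-20, 18, 19, -25)     # suprathreshold deflections
  sp <- detectSpikes(x, fs)
  expect_gt(attr(sp, "threshold"), 4) # about 5 * robust RMS of unit noise
  # 6000/6010 collapse under the 1 ms refractory period
  expect_identical(length(sp), 3L)
  expect_equal(sp, (trueIdx[c(1, 2, 4)] - 1) / fs, ignore_attr = TRUE)
})

test_that("deltaFR implements (stim - baseline) / duration on 3 s windows", {
  # 30 baseline vs 12 stimulus spikes -> (12 - 30)/3 would be negative;
  # use the canonical direction: baseline 12, stimulus 30 -> +6 Hz
  base <- seq(0, 2.9, length.out = 12)
  stim <- seq(3.05, 5.95, length.out = 30)
  ts <- SpikeTrialSet(list(c(base, stim)))
  d <- deltaFR(ts)
  expect_equal(d$mean_delta_fr, (30 - 12) / 3)
  expect_equal(d$baseline_rate_hz, 4)
  expect_equal(d$stim_rate_hz, 10)
})

test_that("frSignificance applies the Bonferroni-corrected cutoff", {
  strong <- generateSpikeTrials(baselineRate = 5, stimRate = 25,
                                nTrials = 12L, seed = 83L)
  res <- generateSpikeTrials(baselineRate = 5, stimRate = 5,
                             nTrials = 12L, seed = 84L)
  s <- frSignificance(strong)
  expect_equal(s$alpha_corrected, 0.05 / 8)
  expect_true(s$significant)
  n <- frSignificance(res)
  expect_false(n$significant)
})

test_that("frSignificance degrades gracefully with zero variance", {
  # identical spike trains in every trial: zero variance in both windows
  tr <- replicate(6, c(0.5, 1.5, 4.0, 4.5), simplify = FALSE)
  res <- frSignificance(SpikeTrialSet(tr))
  expect_false(res$significant)
  expect_match(res$reason, "variance")
})

test_that("psth bins are half-open and account for every spike", {
  # windows are onset-relative; stim onset is at 3 s
  ts <- SpikeTrialSet(list(c(0, 0.02, 0.039, 3.0), c(0.02, 5.99)))
  h <- psth(ts, binWidthS = 0.020, windowS = c(-3, 3))
  expect_equal(sum(h$count), 6)
  expect_equal(h$count[1], 1) # only the spike at 0 s (rel -3) in [-3, -2.98)
  # 0.02 s (x2, exactly on the edge, half-open) and 0.039 s in [-2.98, -2.96)
  expect_equal(h$count[2], 3)
  expect_identical(nrow(attr(h, "raster")), 6L)
})
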