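test_that("phase correlation recovers a pure integer translation exactly", {
  set.seed(11)
  for (rep in 1:5) {
    ref <- array(rnorm(32 * 32 * 8), c(32, 32, 8))
    # smooth a little so the volume has structure
    ref <- punctaTurnover:::convB3Axis(ref, 1L, 1L)
    sh <- c(sample(-5:5, 1), sample(-5:5, 1), sample(-2:2, 1))
    mov <- punctaTurnover:::shiftVolume(ref, sh, fill = 0)
    est <- punctaTurnover:::phaseCorrelation(ref, mov)
    expect_identical(est$shift, as.numeric(sh))
  }
})

test_that("estimateDrift recovers the applied drift exactly on noiseless
           series", {
  cfg <- tinyConfig(seed = 21L, readNoiseSD = 0, shotNoise = FALSE)
  ss <- generateSeries(cfg)
  dr <- estimateDrift(imageSeries(ss))
  expect_equal(as.matrix(dr[, c("dx", "dy", "dz")]),
               unname(appliedDrift(ss)), ignore_attr = TRUE)
})

test_that("applyCorrection cancels the estimated drift", {
  cfg <- tinyConfig(seed = 22L)
  ss <- generateSeries(cfg)
  s <- imageSeries(ss)
  dr <- estimateDrift(s)
  corr <- applyCorrection(s, dr)
  dr2 <- estimateDrift(corr)
  expect_true(all(abs(as.matrix(dr2[, c("dx", "dy", "dz")])) <= 1))
  # voxels shifted out of view are flagged invalid
  expect_true(length(corr@valid) > 0 && !all(corr@valid))
})

test_that("estimateDrift rejects a series without the reference channel", {
  cfg <- tinyConfig(seed = 23L)
  s <- imageSeries(generateSeries(cfg))
  expect_error(estimateDrift(s, referenceChannel = "nope"), "channel")
})

test_that("median filter matches the brute-force Fiji-semantics oracle", {
  set.seed(31)
  for (rep in 1:3) {
    v <- array(sample(0:50, 10 * 9 * 3, replace = TRUE), c(10, 9, 3))
    expect_equal(medianFilterVolume(v, 2L), oracleMedianFilter(v, 2L))
  }
  # radius 1 and NA handling
  v <- array(runif(8 * 8 * 2), c(8, 8, 2))
  v[3, 4, 1] <- NA
  expect_equal(medianFilterVolume(v, 1L), oracleMedianFilter(v, 1L))
})

test_that("median filter removes isolated hot pixels and preserves constant
           volumes", {
  v <- array(10, c(9, 9, 2))
  v[5, 5, 1] <- 1000
  f <- medianFilterVolume(v, 2L)
  expect_equal(f, array(10, c(9, 9, 2)))
})

test_that("medianFilterSeries accepts channel names and only touches the
           requested channel", {
  cfg <- tinyConfig(seed = 24L)
  s <- imageSeries(generateSeries(cfg))
  f <- medianFilterSeries(s, channels = "puncta")
  expect_identical(getVolume(f, 1L, "reference"), getVolume(s, 1L, "reference"))
  expect_false(identical(getVolume(f, 1L, "puncta"), getVolume(s, 1L, "puncta")))
  expect_error(medianFilterSeries(s, channels = "bogus"), "channel")
})
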