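# Hand-built detection tables for deterministic linking scenarios.
detRow <- function(tp, x, y = 0, z = 0) {
  data.frame(timepoint = tp, x_um = x, y_um = y, z_um = z,
             n_voxels = 10L, peak_intensity = 1, total_intensity = 10)
}

test_that("stable detections are linked into one full-length track", {
  det <- do.call(rbind, lapply(1:7, function(tp) detRow(tp, 5 + 0.1 * tp)))
  tr <- linkDetections(det, nTimepoints = 7L)
  expect_identical(nrow(tr$tracks), 1L)
  expect_true(all(tr$presence[1, ]))
  expect_identical(tr$tracks$birth_tp, 1L)
  expect_identical(tr$tracks$death_tp, 7L)
  expect_true(tr$tracks$censored)
})

test_that("displacements beyond the gate break a track into loss + gain", {
  det <- rbind(detRow(1, 5), detRow(2, 5.8)) # 0.8 um > 0.5 um gate
  tr <- linkDetections(det, nTimepoints = 2L)
  expect_identical(nrow(tr$tracks), 2L)
  ev <- punctaTurnover:::intervalEvents(tr$presence)
  expect_identical(ev$n_gain, 1L)
  expect_identical(ev$n_lost, 1L)
})

test_that("mutual nearest neighbour breaks one-sided matches", {
  # a2 is nearest to b, but b's nearest is a1: only a1-b may link
  det <- rbind(detRow(1, 5.00), detRow(1, 5.40), detRow(2, 5.10))
  tr <- linkDetections(det, nTimepoints = 2L)
  d <- tr$detections
  linked <- d$track_id[d$timepoint == 2L]
  a1 <- d$track_id[d$timepoint == 1L & d$x_um == 5.00]
  expect_identical(linked, a1)
})

test_that("a missed detection yields loss + gain when gaps are disallowed,
           one track when bridged", {
  det <- rbind(detRow(1, 5), detRow(3, 5), detRow(4, 5))
  noGap <- linkDetections(det, nTimepoints = 4L)
  expect_identical(nrow(noGap$tracks), 2L)
  gap <- linkDetections(det, nTimepoints = 4L, allowGaps = TRUE)
  expect_identical(nrow(gap$tracks), 1L)
  expect_true(all(gap$presence[1, ]))
})

test_that("duplicate coordinates within a timepoint are rejected", {
  det <- rbind(detRow(1, 5), detRow(1, 5))
  expect_error(linkDetections(det, nTimepoints = 2L), "duplicate")
})

test_that("filterTransients drops single-timepoint blips only", {
  det <- rbind(detRow(1, 5), detRow(2, 5),          # stable pair
               detRow(2, 9))                        # one-timepoint transient
  tr <- linkDetections(det, nTimepoints = 3L)
  expect_identical(nrow(tr$tracks), 2L)
  f <- filterTransients(tr)
  expect_identical(nrow(f$tracks), 1L)
  expect_identical(attr(f, "n_removed"), 1L)
  expect_identical(nrow(f$detections), 2L)
})

test_that("survivalTimes summarises newly formed puncta born within the
           appearance window", {
  det <- rbind(detRow(1, 1), detRow(2, 1), detRow(3, 1),  # pre-existing
               detRow(2, 5), detRow(3, 5), detRow(4, 5),  # born 30, lives 60
               detRow(3, 9), detRow(4, 9), detRow(5, 9),
               detRow(6, 9), detRow(7, 9),                # born 60, lives 120
               detRow(5, 3), detRow(6, 3))                # born 120: too late
  tr <- linkDetections(det, nTimepoints = 7L)
  sv <- survivalTimes(tr, appearanceWindowMin = 60)
  # the pre-existing track and the late birth are excluded
  expect_identical(nrow(sv), 2L)
  expect_setequal(sv$survival_min, c(60, 120))
  expect_equal(attr(sv, "frac_surviving_60"), 1)
  expect_equal(attr(sv, "frac_surviving_120"), 0.5)
})

test_that("linking the pipeline's own detections conserves counts on a real
           series", {
  cfg <- tinyConfig(seed = 51L)
  s <- imageSeries(generateSeries(cfg))
  s <- applyCorrection(s, estimateDrift(s))
  s <- medianFilterSeries(s, channels = "puncta")
  det <- detectSeries(s)
  tr <- filterTransients(linkDetections(det, nTimepoints = 7L))
  sm <- summarizeTurnover(tr)
  expect_equal(sm$n_t3h, sm$n_t0 + sm$n_gain - sm$n_lost)
})
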