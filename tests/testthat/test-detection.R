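test_that("a trous decomposition reconstructs its input exactly", {
  set.seed(41)
  for (rep in 1:5) {
    v <- array(rnorm(16 * 16 * 8, 100, 20), c(16, 16, 8))
    dec <- atrousDecompose(v, nScales = 3L)
    rec <- Reduce(`+`, dec$details) + dec$smooth
    expect_lt(max(abs(rec - v)) / max(abs(v)), 1e-9)
  }
})

test_that("a trous details vanish on a constant volume", {
  v <- array(7, c(12, 12, 6))
  dec <- atrousDecompose(v)
  for (w in dec$details) expect_lt(max(abs(w)), 1e-10)
  expect_equal(dec$smooth, v)
})

test_that("decomposition refuses volumes smaller than the kernel support", {
  expect_error(atrousDecompose(array(0, c(3, 16, 8)), nScales = 3L), "scale")
})

test_that("universal threshold implements sigma * sqrt(2 log N)", {
  set.seed(42)
  x <- rnorm(1000)
  expect_equal(universalThreshold(x, sigmaMethod = "sd"),
               sd(x) * sqrt(2 * log(length(x))))
  expect_equal(universalThreshold(x, sigmaMethod = "mad"),
               mad(x) * sqrt(2 * log(length(x))))
  expect_identical(universalThreshold(rep(1, 50)), 0)
})

test_that("connected-component labeling matches the flood-fill oracle", {
  set.seed(43)
  for (conn in c(6L, 18L, 26L)) {
    m <- randomSparseMask(c(10L, 10L, 5L), pFg = 0.15)
    lab <- labelComponents(m, connectivity = conn)
    expect_true(samePartition(lab$labels, oracleFloodFill(m, conn)))
  }
})

test_that("labelComponents reports one row and the right size per component", {
  m <- array(FALSE, c(10, 10, 3))
  m[2:3, 2:3, 1] <- TRUE        # 4 voxels
  m[7:9, 7, 2] <- TRUE          # 3 voxels
  lab <- labelComponents(m)
  expect_identical(nrow(lab$table), 2L)
  expect_setequal(lab$table$n_voxels, c(4L, 3L))
})

test_that("detectPuncta finds a single clean punctum at its centroid", {
  vox <- c(0.12, 0.12, 1)
  v <- array(0, c(48, 48, 12))
  ctr <- c(20, 25, 6) # 1-based voxel indices
  v <- punctaTurnover:::stampGaussian(v, (ctr - 1) * vox, vox,
                                      sigmaUm = c(0.2, 0.2, 0.97),
                                      amplitude = 100)
  det <- detectPuncta(v, vox)
  expect_identical(nrow(det), 1L)
  expect_lt(abs(det$x_um - (ctr[1] - 1) * vox[1]), vox[1])
  expect_lt(abs(det$y_um - (ctr[2] - 1) * vox[2]), vox[2])
  expect_lt(abs(det$z_um - (ctr[3] - 1) * vox[3]), vox[3])
  expect_gte(det$n_voxels, 4L)
})

test_that("minVoxels filters small components", {
  vox <- c(0.12, 0.12, 1)
  v <- array(0, c(32, 32, 8))
  v[16, 16, 4] <- 500 # single hot voxel
  det <- detectPuncta(v, vox, minVoxels = 4L)
  expect_identical(nrow(det), 0L)
  det1 <- detectPuncta(v, vox, minVoxels = 1L)
  expect_gte(nrow(det1), 1L)
})

test_that("invalid voxels cannot spawn detections", {
  vox <- c(0.12, 0.12, 1)
  v <- array(0, c(32, 32, 8))
  v <- punctaTurnover:::stampGaussian(v, c(15, 15, 3) * vox, vox,
                                      sigmaUm = c(0.2, 0.2, 0.97),
                                      amplitude = 100)
  valid <- array(TRUE, dim(v))
  valid[10:22, 10:22, ] <- FALSE # mask out the punctum
  det <- detectPuncta(v, vox, valid = valid)
  # the masked punctum must not be reported at its location
  if (nrow(det) > 0) {
    dist <- sqrt((det$x_um - 15 * vox[1])^2 + (det$y_um - 15 * vox[2])^2 +
                   (det$z_um - 3 * vox[3])^2)
    expect_gt(min(dist), 0.5)
  } else {
    expect_identical(nrow(det), 0L)
  }
})

test_that("detectSeries tags detections with their timepoint", {
  cfg <- tinyConfig(seed = 44L)
  s <- medianFilterSeries(imageSeries(generateSeries(cfg)),
                          channels = "puncta")
  det <- detectSeries(s)
  expect_true(all(det$timepoint %in% seq_len(7L)))
  expect_true(all(c("x_um", "y_um", "z_um", "n_voxels") %in% names(det)))
  expect_gt(nrow(det), 0L)
})
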