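# A pair of small volumes with a linear intensity field: trilinear
# interpolation reproduces a linear function exactly, so the extracted
# profiles have known values.
linearVolumes <- function(dim = c(20L, 20L, 8L), vox = c(0.2, 0.2, 0.5)) {
  xs <- (seq_len(dim[1]) - 1) * vox[1]
  a <- array(rep(xs, times = dim[2] * dim[3]), dim)
  list(a = a, b = 3 * a + 2, vox = vox)
}

test_that("profile extraction samples trilinear-exact values along x", {
  lv <- linearVolumes()
  ctr <- c(2.0, 2.0, 1.5)
  pr <- extractProfilePair(lv$a, lv$b, ctr, lv$vox, lengthUm = 1,
                           direction = c(1, 0, 0))
  expect_s3_class(pr, "profilePair")
  # channel A equals the x coordinate itself, channel B its affine image
  expect_equal(pr$intensity_a, ctr[1] + pr$position_um, tolerance = 1e-10)
  expect_equal(pr$intensity_b, 3 * pr$intensity_a + 2, tolerance = 1e-10)
  # sampled at voxel pitch
  expect_equal(unique(round(diff(pr$position_um), 10)), min(lv$vox))
})

test_that("profiles leaving the volume are truncated with a warning", {
  lv <- linearVolumes()
  expect_warning(pr <- extractProfilePair(lv$a, lv$b, c(0.1, 2, 1.5), lv$vox,
                                          lengthUm = 2,
                                          direction = c(1, 0, 0)),
                 "truncat")
  expect_true(nrow(pr) >= 5L)
})

test_that("correlationTest calls colocalization only for positive
           correlation below the cutoff", {
  n <- 21
  x <- seq(-1, 1, length.out = n)
  bump <- exp(-x^2 / 0.1)
  set.seed(71)
  pos <- data.frame(position_um = x, intensity_a = bump,
                    intensity_b = 2 * bump + rnorm(n, 0, 0.01))
  res <- correlationTest(pos)
  expect_true(res$colocalized)
  expect_gt(res$r, 0.9)
  neg <- data.frame(position_um = x, intensity_a = bump,
                    intensity_b = max(bump) - bump + rnorm(n, 0, 0.01))
  resN <- correlationTest(neg)
  expect_false(resN$colocalized)
  expect_lt(resN$r, 0)
  flat <- data.frame(position_um = x, intensity_a = rep(1, n),
                     intensity_b = bump)
  resF <- correlationTest(flat)
  expect_false(resF$colocalized)
  expect_match(resF$reason, "constant")
})

test_that("exact permutation Pearson p matches the lexicographic oracle", {
  set.seed(72)
  for (n in 3:7) {
    x <- rnorm(n); y <- rnorm(n)
    pp <- pearsonPermutationP(x, y)
    expect_equal(pp$p_value, oraclePermPearsonP(x, y))
    expect_equal(pp$n_permutations, factorial(n))
    expect_equal(pp$r, cor(x, y))
  }
  expect_error(pearsonPermutationP(1:9, 9:1), "n <= 8")
  expect_error(pearsonPermutationP(rep(1, 5), rnorm(5)), "constant")
})

test_that("appositionTest measures peak offsets along the profile", {
  x <- seq(-1, 1, by = 0.1)
  shifted <- function(mu) exp(-(x - mu)^2 / 0.05)
  close <- data.frame(position_um = x, intensity_a = shifted(0),
                      intensity_b = shifted(0.3))
  expect_true(appositionTest(close)$apposed)
  expect_equal(appositionTest(close)$peak_offset_um, 0.3)
  far <- data.frame(position_um = x, intensity_a = shifted(-0.4),
                    intensity_b = shifted(0.4))
  expect_false(appositionTest(far)$apposed)
})

test_that("Otsu threshold matches the exhaustive oracle and separates a
           bimodal sample", {
  set.seed(73)
  x <- c(rnorm(400, 20, 3), rnorm(200, 90, 8))
  thr <- otsuThreshold(x)
  expect_equal(thr, oracleOtsu(x))
  expect_gt(thr, 30); expect_lt(thr, 80)
  expect_error(otsuThreshold(rep(5, 10)), "constant")
})

test_that("pixelColocalization on constructed overlap", {
  a <- array(1, c(10, 10, 2)); b <- array(1, c(10, 10, 2))
  a[1:4, , ] <- 100        # A positive: 4 columns
  b[3:6, , ] <- 100        # B positive: 4 columns, overlap 2
  pc <- pixelColocalization(a, b)
  expect_equal(unname(pc["pct_of_a"]), 50)
  expect_equal(unname(pc["pct_of_b"]), 50)
  expect_error(pixelColocalization(a, array(1, c(9, 10, 2))), "congruent")
})

test_that("glomerularOccupancy uses ROI-restricted thresholds", {
  img <- matrix(10, 20, 20)
  img[1:10, 1:10] <- 200           # bright quadrant
  roi <- matrix(FALSE, 20, 20)
  roi[1:10, ] <- TRUE              # ROI: half bright, half dark
  occ <- glomerularOccupancy(img, roi)
  expect_equal(occ, 50)
  # uniformly bright ROI
  roiB <- matrix(FALSE, 20, 20); roiB[1:5, 1:5] <- TRUE
  expect_equal(glomerularOccupancy(img, roiB), 100)
  expect_error(glomerularOccupancy(img, matrix(FALSE, 20, 20)), "empty")
})
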