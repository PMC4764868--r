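# --- line-profile colocalization ---------------------------------------------

#' Extract a matched pair of line intensity profiles
#'
#' Samples both channels along a straight line through a punctum centroid at
#' voxel pitch (the smallest voxel edge), using trilinear interpolation. The
#' default direction is the principal axis of the punctum's voxel support
#' when given, else the x axis; the default length is 2 um. A line leaving
#' the volume is truncated with a warning.
#'
#' @param volumeA,volumeB congruent numeric 3D arrays (the two channels).
#' @param centroidUm numeric length-3 punctum centroid in micrometres.
#' @param voxelSize numeric length-3 voxel size in micrometres.
#' @param lengthUm profile length in micrometres (default 2).
#' @param direction optional numeric length-3 direction vector (um frame);
#'   overrides the support-derived default.
#' @param supportVox optional integer matrix (n x 3) of the punctum's voxel
#'   indices; its principal axis (eigenvector of the coordinate covariance
#'   in um) sets the direction.
#' @return A data.frame of class `profilePair`: `position_um` (centred on the
#'   centroid), `intensity_a`, `intensity_b`.
#' @export
extractProfilePair <- function(volumeA, volumeB, centroidUm, voxelSize,
                               lengthUm = 2, direction = NULL,
                               supportVox = NULL) {
  if (!all(dim(volumeA) == dim(volumeB)))
    stop("channel volumes must be congruent")
  if (lengthUm <= 0) stop("profile length must be positive")
  if (is.null(direction)) {
    if (!is.null(supportVox) && nrow(supportVox) >= 3L) {
      um <- sweep(supportVox - 1, 2L, voxelSize, "*")
      direction <- eigen(stats::cov(um), symmetric = TRUE)$vectors[, 1L]
    } else {
      direction <- c(1, 0, 0)
    }
  }
  direction <- direction / sqrt(sum(direction^2))
  pitch <- min(voxelSize)
  s <- seq(-lengthUm / 2, lengthUm / 2, by = pitch)
  ptsUm <- sweep(outer(s, direction), 2L, centroidUm, "+")
  ptsVox <- sweep(ptsUm, 2L, voxelSize, "/") + 1
  ia <- trilinearInterp(volumeA, ptsVox)
  ib <- trilinearInterp(volumeB, ptsVox)
  keep <- !is.na(ia) & !is.na(ib)
  if (!all(keep)) {
    warning("profile truncated at the volume boundary (",
            sum(!keep), " of ", length(keep), " samples dropped)")
    # keep the largest contiguous in-bounds run around the centre
    s <- s[keep]; ia <- ia[keep]; ib <- ib[keep]
  }
  if (length(s) < 5L)
    stop("profile has fewer than 5 samples inside the volume")
  out <- data.frame(position_um = s, intensity_a = ia, intensity_b = ib)
  class(out) <- c("profilePair", "data.frame")
  out
}

#' Correlation colocalization test on a profile pair
#'
#' Pearson correlation between the two channel profiles with a two-sided
#' p-value from the t distribution on `n - 2` degrees of freedom. A punctum
#' is called colocalized when `p < 1e-4` and the correlation is positive
#' (anti-correlated profiles never count as colocalization).
#'
#' @param pair a `profilePair` from [extractProfilePair()] (any data.frame
#'   with `intensity_a`, `intensity_b`).
#' @param pCutoff significance cutoff (default `1e-4`).
#' @return A list: `r`, `p_value`, `colocalized`, `reason` (non-`NA` when the
#'   test is undefined, e.g. a constant profile).
#' @examples
#' pr <- data.frame(position_um = 1:6, intensity_a = c(1, 3, 9, 8, 3, 1),
#'                  intensity_b = c(2, 4, 10, 9, 4, 2))
#' correlationTest(pr)
#' @export
correlationTest <- function(pair, pCutoff = 1e-4) {
  a <- pair$intensity_a; b <- pair$intensity_b
  if (length(a) < 5L) stop("need at least 5 profile samples")
  if (sd(a) == 0 || sd(b) == 0) {
    return(list(r = NA_real_, p_value = NA_real_, colocalized = FALSE,
                reason = "constant profile: correlation undefined"))
  }
  ct <- cor.test(a, b, method = "pearson", alternative = "two.sided")
  r <- unname(ct$estimate)
  list(r = r, p_value = ct$p.value,
       colocalized = isTRUE(ct$p.value < pCutoff && r > 0),
       reason = NA_character_)
}

#' Exact permutation p-value for a Pearson correlation
#'
#' Enumerates all `n!` pairings of `x` with permutations of `y` and returns
#' the two-sided exact p-value: the fraction of permutations whose absolute
#' Pearson correlation is at least the observed one. Limited to `n <= 8`
#' (40320 permutations); for larger profiles use the t-distribution p-value
#' of [correlationTest()].
#'
#' @param x,y numeric vectors of equal length `3 <= n <= 8`, neither
#'   constant.
#' @return A list: `r` (observed correlation), `p_value` (exact two-sided
#'   permutation p), `n_permutations`.
#' @examples
#' pearsonPermutationP(c(1, 2, 3, 5, 8), c(2, 3, 5, 9, 15))
#' @export
pearsonPermutationP <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3L || n > 8L) stop("exact permutation p requires 3 <= n <= 8")
  if (sd(x) == 0 || sd(y) == 0) stop("constant input: correlation undefined")
  perms <- .allPermutations(n)
  # r is monotone in sum(x * y[perm]) given fixed marginals
  xc <- x - mean(x)
  denom <- sqrt(sum(xc^2) * sum((y - mean(y))^2))
  rAll <- (matrix(y[perms], nrow(perms)) %*% xc) / denom
  rObs <- sum(xc * y) / denom
  tol <- 1e-12
  list(r = rObs,
       p_value = mean(abs(rAll) >= abs(rObs) - tol),
       n_permutations = nrow(perms))
}

# All permutations of 1..n as an n! x n integer matrix (insertion method).
.allPermutations <- function(n) {
  p <- matrix(1L, 1L, 1L)
  for (k in seq_len(n)[-1L]) {
    out <- matrix(0L, nrow(p) * k, k)
    row <- 1L
    for (i in seq_len(nrow(p))) {
      for (pos in seq_len(k)) {
        out[row, ] <- append(p[i, ], k, after = pos - 1L)
        row <- row + 1L
      }
    }
    p <- out
  }
  p
}

#' Peak apposition test on a profile pair
#'
#' Two markers are apposed when the intensity peaks of the two profiles lie
#' within `maxOffsetUm` (default 0.5 um) of each other along the line. Tied
#' maxima are broken by first occurrence and recorded.
#'
#' @param pair a `profilePair`.
#' @param maxOffsetUm maximum peak offset in micrometres (default 0.5).
#' @return A list: `apposed`, `peak_offset_um`, `reason` (non-`NA` for flat
#'   profiles or tie-broken peaks).
#' @export
appositionTest <- function(pair, maxOffsetUm = 0.5) {
  a <- pair$intensity_a; b <- pair$intensity_b
  if (sd(a) == 0 || sd(b) == 0) {
    return(list(apposed = FALSE, peak_offset_um = NA_real_,
                reason = "flat profile: no defined peak"))
  }
  ia <- which.max(a); ib <- which.max(b)
  tie <- sum(a == max(a)) > 1L || sum(b == max(b)) > 1L
  off <- abs(pair$position_um[ia] - pair$position_um[ib])
  list(apposed = off <= maxOffsetUm, peak_offset_um = off,
       reason = if (tie) "tied profile maxima broken by first occurrence"
              else NA_character_)
}

# --- Otsu thresholding and occupancy -----------------------------------------

#' Otsu threshold of an intensity sample
#'
#' The cut maximizing the between-class variance
#' `w0 * w1 * (mu0 - mu1)^2` over a 256-bin histogram of the analysed
#' region's intensities. With a plateau of equally optimal cuts (e.g. across
#' empty bins) the midpoint of the plateau is returned.
#'
#' @param x numeric vector or array of intensities (at least two distinct
#'   values).
#' @param nBins histogram bins (default 256).
#' @param range histogram range (default the data range).
#' @return The threshold level; voxels with intensity strictly above it form
#'   the foreground class.
#' @examples
#' otsuThreshold(c(rep(10, 50), rep(200, 50)))
#' @export
otsuThreshold <- function(x, nBins = 256L, range = NULL) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  if (length(unique(x)) < 2L)
    stop("Otsu threshold undefined for a constant image")
  if (is.null(range)) range <- base::range(x)
  edges <- seq(range[1L], range[2L], length.out = nBins + 1L)
  h <- tabulate(pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE),
                          1L), nBins), nBins)
  p <- h / sum(h)
  omega0 <- cumsum(p)
  mu <- cumsum(p * seq_len(nBins))
  muT <- mu[nBins]
  # between-class variance for a cut after bin k (k = 1 .. nBins-1)
  k <- seq_len(nBins - 1L)
  w0 <- omega0[k]; w1 <- 1 - w0
  sigmaB <- (muT * w0 - mu[k])^2 / (w0 * w1)
  sigmaB[!is.finite(sigmaB)] <- -Inf
  best <- which(sigmaB == max(sigmaB))
  cut <- best[ceiling(length(best) / 2)]
  edges[cut + 1L]
}

#' Pixel-overlap colocalization percentage
#'
#' Both channels are binarized at their own Otsu level (computed on the
#' analysed region); returns the doubly positive voxels as a percentage of
#' each channel's positive voxels.
#'
#' @param volumeA,volumeB congruent numeric arrays.
#' @return Named numeric: `pct_of_a` = `100 * |A+ & B+| / |A+|` and the
#'   symmetric `pct_of_b`; `NA` with a warning for an empty positive set.
#' @export
pixelColocalization <- function(volumeA, volumeB) {
  if (!all(dim(volumeA) == dim(volumeB)))
    stop("channel volumes must be congruent")
  aPos <- volumeA > otsuThreshold(volumeA)
  bPos <- volumeB > otsuThreshold(volumeB)
  both <- sum(aPos & bPos)
  pa <- if (sum(aPos) == 0) {
    warning("no positive voxels in channel A"); NA_real_
  } else 100 * both / sum(aPos)
  pb <- if (sum(bPos) == 0) {
    warning("no positive voxels in channel B"); NA_real_
  } else 100 * both / sum(bPos)
  c(pct_of_a = pa, pct_of_b = pb)
}

#' Glomerular occupancy within an ROI
#'
#' Percentage of ROI pixels whose intensity exceeds the channel's Otsu level,
#' with the level computed from the ROI pixels only (a single optical
#' section's regional analysis).
#'
#' @param sectionImage numeric 2D matrix (one optical section).
#' @param roiMask logical matrix of the same shape.
#' @return Occupancy percentage of the ROI.
#' @export
glomerularOccupancy <- function(sectionImage, roiMask) {
  if (!all(dim(sectionImage) == dim(roiMask)))
    stop("image and ROI mask must be congruent")
  if (!any(roiMask)) stop("ROI mask is empty")
  px <- sectionImage[roiMask]
  if (length(unique(px)) < 2L) {
    # uniformly bright or uniformly dark ROI: occupancy is all-or-nothing
    return(if (all(px > min(sectionImage))) 100 else 0)
  }
  level <- otsuThreshold(px)
  100 * mean(px > level)
}
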