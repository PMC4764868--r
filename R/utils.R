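# internal helpers shared across modules

# mirror (reflect-without-repeat) index into 1..n, as used for boundary
# padding of the separable convolutions; period is 2n-2 so the edge sample
# is not duplicated
mirrorIndex <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  j <- (i - 1L) %% (2L * n - 2L)
  j <- ifelse(j < 0L, j + 2L * n - 2L, j)
  as.integer(ifelse(j < n, j + 1L, 2L * n - j - 1L))
}

# Gaussian sigma from a full width at half maximum
fwhmToSigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# trilinear interpolation of a 3D array at continuous voxel-index
# coordinates (1-based); points outside the volume return NA
trilinearInterp <- function(vol, pts) {
  d <- dim(vol)
  n <- nrow(pts)
  out <- rep(NA_real_, n)
  inside <- pts[, 1] >= 1 & pts[, 1] <= d[1] &
            pts[, 2] >= 1 & pts[, 2] <= d[2] &
            pts[, 3] >= 1 & pts[, 3] <= d[3]
  if (!any(inside)) return(out)
  p <- pts[inside, , drop = FALSE]
  x0 <- pmin(floor(p[, 1]), d[1] - 1); x0 <- pmax(x0, 1)
  y0 <- pmin(floor(p[, 2]), d[2] - 1); y0 <- pmax(y0, 1)
  z0 <- pmin(floor(p[, 3]), d[3] - 1)
  z0 <- pmax(z0, 1)
  if (d[3] == 1L) z0 <- rep(1, nrow(p))
  fx <- p[, 1] - x0; fy <- p[, 2] - y0
  fz <- if (d[3] == 1L) rep(0, nrow(p)) else p[, 3] - z0
  z1 <- pmin(z0 + 1, d[3])
  at <- function(ix, iy, iz) vol[cbind(ix, iy, iz)]
  v <- (1 - fx) * (1 - fy) * (1 - fz) * at(x0, y0, z0) +
       fx * (1 - fy) * (1 - fz) * at(x0 + 1, y0, z0) +
       (1 - fx) * fy * (1 - fz) * at(x0, y0 + 1, z0) +
       fx * fy * (1 - fz) * at(x0 + 1, y0 + 1, z0) +
       (1 - fx) * (1 - fy) * fz * at(x0, y0, z1) +
       fx * (1 - fy) * fz * at(x0 + 1, y0, z1) +
       (1 - fx) * fy * fz * at(x0, y0 + 1, z1) +
       fx * fy * fz * at(x0 + 1, y0 + 1, z1)
  out[inside] <- v
  out
}

# shift a 3D array by an integer voxel vector, filling exposed voxels with
# `fill`; shift = c(dx, dy, dz) moves content towards larger indices
shiftVolume <- function(vol, shift, fill = NA_real_) {
  d <- dim(vol)
  out <- array(fill, d)
  src <- dst <- vector("list", 3L)
  for (a in 1:3) {
    s <- shift[a]
    if (abs(s) >= d[a]) return(out)
    if (s >= 0) {
      src[[a]] <- seq_len(d[a] - s)
      dst[[a]] <- seq_len(d[a] - s) + s
    } else {
      src[[a]] <- seq_len(d[a] + s) - s
      dst[[a]] <- seq_len(d[a] + s)
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- vol[src[[1]], src[[2]], src[[3]]]
  out
}

# longest run of TRUE in a logical vector
longestRun <- function(x) {
  if (!any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}
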