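#' @importFrom stats fft
NULL

# phase correlation between two equally sized 3D volumes; returns the
# integer (or optionally parabolic sub-voxel) shift s such that
# moving(x) ~= reference(x - s), plus the normalized correlation peak
phaseCorrelation <- function(reference, moving, maxShift = NULL,
                             subVoxel = FALSE) {
  d <- dim(reference)
  f0 <- fft(reference - mean(reference))
  f1 <- fft(moving - mean(moving))
  cp <- f0 * Conj(f1)
  mag <- Mod(cp)
  mag[mag < .Machine$double.eps] <- .Machine$double.eps
  r <- Re(fft(cp / mag, inverse = TRUE)) / length(reference)

  # wrapped index -> signed shift per axis
  signedShift <- function(idx0, n) ifelse(idx0 > n / 2, idx0 - n, idx0)

  if (!is.null(maxShift)) {
    ax <- lapply(1:3, function(a) {
      s <- signedShift(seq_len(d[a]) - 1L, d[a])
      abs(s) <= maxShift[a]
    })
    allowed <- outer(outer(ax[[1]], ax[[2]], "&"), ax[[3]], "&")
    r[!allowed] <- -Inf
  }
  peak <- which.max(r)
  pk <- arrayInd(peak, d)[1, ]
  # phase correlation peaks at the negated displacement of `moving`
  shift <- -vapply(1:3, function(a) signedShift(pk[a] - 1L, d[a]), numeric(1))
  score <- r[peak]

  if (subVoxel) {
    # 3-point parabolic refinement along each axis on the wrapped surface
    for (a in 1:3) {
      if (d[a] < 3L) next
      im <- pk; ip <- pk
      im[a] <- ((pk[a] - 2L) %% d[a]) + 1L
      ip[a] <- (pk[a] %% d[a]) + 1L
      y0 <- r[matrix(im, 1L)]; y1 <- r[matrix(pk, 1L)]
      y2 <- r[matrix(ip, 1L)]
      den <- y0 - 2 * y1 + y2
      if (is.finite(den) && abs(den) > .Machine$double.eps) {
        delta <- 0.5 * (y0 - y2) / den
        if (abs(delta) <= 1) shift[a] <- shift[a] - delta
      }
    }
  }
  list(shift = shift, score = score)
}

#' Estimate rigid per-timepoint drift against the reference channel
#'
#' Translation-only drift of each timepoint relative to the first, estimated
#' by phase correlation of the reference (cytosolic) channel. Only linear
#' translations in x, y and z are ever considered; every timepoint is
#' registered directly to timepoint 1 so estimation errors do not accumulate
#' across the session.
#'
#' @param series a [TimeSeriesVolume-class].
#' @param referenceChannel index or name of the registration reference
#'   channel (default `"reference"`, i.e. the cytosolic fill).
#' @param maxShift integer length-3 bound (voxels) on the admissible shift
#'   per axis; `NULL` (default) allows up to half the volume extent.
#' @param subVoxel logical; if `TRUE`, refine the integer peak by parabolic
#'   interpolation (off by default so correction stays integer-voxel and no
#'   interpolation alters punctum intensities before thresholding).
#' @return A data.frame with one row per timepoint: `timepoint`, `dx`, `dy`,
#'   `dz` (voxels, the estimated displacement of that timepoint relative to
#'   timepoint 1) and `score` (phase-correlation peak). Row 1 is zero by
#'   construction. A warning is recorded if an estimate sits at the search
#'   bound.
#' @examples
#' cfg <- simConfig(volumeShape = c(48, 48, 10), voxelSize = c(0.2, 0.2, 1),
#'                  nTimepoints = 3L, nInitialPuncta = 4L, gainRate = 0,
#'                  lossProb = 0, transportPacketRate = 0,
#'                  driftMax = c(2L, 2L, 1L), shotNoise = FALSE,
#'                  readNoiseSD = 0, rngSeed = 2L)
#' ss <- generateSeries(cfg)
#' estimateDrift(imageSeries(ss))
#' @export
estimateDrift <- function(series, referenceChannel = "reference",
                          maxShift = NULL, subVoxel = FALSE) {
  stopifnot(is(series, "TimeSeriesVolume"))
  tp <- nTimepoints(series)
  if (tp < 2L) stop("drift estimation needs at least 2 timepoints")
  ref0 <- getVolume(series, 1L, referenceChannel)
  if (sd(ref0) == 0)
    stop("reference channel '", referenceChannel,
         "' is constant at timepoint 1; cannot register")
  if (!is.null(maxShift)) maxShift <- rep_len(as.numeric(maxShift), 3L)
  out <- data.frame(timepoint = seq_len(tp), dx = 0, dy = 0, dz = 0,
                    score = NA_real_)
  for (t in 2:tp) {
    vt <- getVolume(series, t, referenceChannel)
    if (sd(vt) == 0)
      stop("reference channel '", referenceChannel,
           "' is constant at timepoint ", t, "; cannot register")
    pc <- phaseCorrelation(ref0, vt, maxShift = maxShift,
                           subVoxel = subVoxel)
    out[t, c("dx", "dy", "dz")] <- pc$shift
    out$score[t] <- pc$score
    if (!is.null(maxShift) && any(abs(pc$shift) >= maxShift))
      warning("drift estimate for timepoint ", t,
              " lies at the search bound; consider increasing maxShift")
  }
  out
}

#' Apply a drift correction to a series
#'
#' Shifts every channel of every timepoint by the negated drift estimate
#' (rounded to integer voxels: translation only, no interpolation). Voxels
#' shifted in from outside the imaged field are marked invalid and excluded
#' from downstream detection.
#'
#' @param series a [TimeSeriesVolume-class].
#' @param drift data.frame as returned by [estimateDrift()] (columns
#'   `timepoint`, `dx`, `dy`, `dz`), one row per timepoint.
#' @return A corrected [TimeSeriesVolume-class] of identical shape with an
#'   updated validity mask.
#' @export
applyCorrection <- function(series, drift) {
  stopifnot(is(series, "TimeSeriesVolume"))
  tp <- nTimepoints(series)
  if (nrow(drift) != tp)
    stop("drift must have one row per timepoint")
  d <- dim(series@data)
  dat <- series@data
  valid <- array(TRUE, d[c(1:3, 5L)])
  if (length(series@valid) > 0L) valid <- series@valid
  sh <- round(as.matrix(drift[, c("dx", "dy", "dz")]))
  for (t in seq_len(tp)) {
    s <- -as.integer(sh[t, ])
    if (all(s == 0L)) next
    for (ch in seq_len(d[4L]))
      dat[, , , ch, t] <- shiftVolume(dat[, , , ch, t, drop = TRUE], s,
                                      fill = 0)
    vm <- shiftVolume(valid[, , , t, drop = TRUE] * 1, s, fill = 0)
    valid[, , , t] <- vm > 0
  }
  new("TimeSeriesVolume", data = dat, voxelSize = series@voxelSize,
      timepointsMin = series@timepointsMin,
      channelNames = series@channelNames, valid = valid)
}

#' Circular median filter (per z-slice)
#'
#' Replaces each voxel by the median over a circular 2-pixel-radius
#' neighbourhood within its own z-slice (Fiji `Median...` semantics: a pixel
#' belongs to the radius-r kernel iff `dx^2 + dy^2 <= r^2 + 1`). At slice
#' borders the median is taken over the in-bounds part of the kernel. `NA`
#' (invalid) voxels are ignored by neighbouring medians and stay `NA`.
#'
#' @param volume numeric 3D array.
#' @param radiusPx kernel radius in pixels (default 2).
#' @return The filtered array, same shape.
#' @examples
#' v <- array(0, c(9, 9, 1)); v[5, 5, 1] <- 100
#' max(medianFilterVolume(v))  # isolated hot pixel suppressed
#' @export
medianFilterVolume <- function(volume, radiusPx = 2L) {
  stopifnot(length(dim(volume)) == 3L, radiusPx >= 1L)
  .median_filter_stack_cpp(as.numeric(volume), as.integer(dim(volume)),
                           as.integer(radiusPx))
}

#' Median-filter every channel and timepoint of a series
#'
#' @param series a [TimeSeriesVolume-class].
#' @param radiusPx kernel radius in pixels (default 2).
#' @param channels channel indices or names to filter (default all).
#' @return A filtered [TimeSeriesVolume-class].
#' @export
medianFilterSeries <- function(series, radiusPx = 2L,
                               channels = seq_len(nChannels(series))) {
  stopifnot(is(series, "TimeSeriesVolume"))
  if (is.character(channels)) {
    channels <- match(channels, channelNames(series))
    if (anyNA(channels))
      stop("unknown channel name; available: ",
           paste(channelNames(series), collapse = ", "))
  }
  dat <- series@data
  for (t in seq_len(nTimepoints(series)))
    for (ch in channels)
      dat[, , , ch, t] <- medianFilterVolume(dat[, , , ch, t, drop = TRUE],
                                             radiusPx)
  initialize(series, data = dat)
}
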