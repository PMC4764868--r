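#' @rdname TimeSeriesVolume-class
setMethod("nTimepoints", "TimeSeriesVolume",
          function(x) dim(x@data)[5L])

#' @rdname TimeSeriesVolume-class
setMethod("nChannels", "TimeSeriesVolume",
          function(x) dim(x@data)[4L])

#' @rdname TimeSeriesVolume-class
setMethod("voxelSize", "TimeSeriesVolume", function(x) x@voxelSize)

#' @rdname TimeSeriesVolume-class
setMethod("timepointsMin", "TimeSeriesVolume", function(x) x@timepointsMin)

#' @rdname TimeSeriesVolume-class
setMethod("channelNames", "TimeSeriesVolume", function(x) x@channelNames)

#' @rdname TimeSeriesVolume-class
setMethod("getVolume", "TimeSeriesVolume",
  function(x, timepoint, channel) {
    if (is.character(channel)) {
      channel <- match(channel, x@channelNames)
      if (is.na(channel)) stop("unknown channel name")
    }
    stopifnot(timepoint >= 1L, timepoint <= nTimepoints(x),
              channel >= 1L, channel <= nChannels(x))
    x@data[, , , channel, timepoint, drop = TRUE]
  })

#' @rdname TimeSeriesVolume-class
setMethod("validMask", "TimeSeriesVolume",
  function(x, timepoint) {
    d <- dim(x@data)
    if (length(x@valid) == 0L)
      return(array(TRUE, d[1:3]))
    x@valid[, , , timepoint, drop = TRUE]
  })

setMethod("show", "TimeSeriesVolume", function(object) {
  d <- dim(object@data)
  cat("TimeSeriesVolume:", paste(d[1:3], collapse = " x "), "voxels,",
      d[4L], "channel(s),", d[5L], "timepoint(s)\n")
  cat("  voxel size (um):", paste(signif(object@voxelSize, 3),
                                  collapse = " x "), "\n")
  cat("  timepoints (min):", paste(object@timepointsMin, collapse = ", "),
      "\n")
  cat("  channels:", paste(object@channelNames, collapse = ", "), "\n")
  if (length(object@valid) > 0L)
    cat("  invalid voxels:", sum(!object@valid), "\n")
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", paste(object@volumeShape, collapse = " x "),
      "voxels @", paste(signif(object@voxelSize, 3), collapse = " x "),
      "um,", object@nTimepoints, "timepoints every",
      object@intervalMin, "min\n")
  cat(sprintf("  PSF FWHM: %.2f um (xy), %.2f um (z)\n",
              object@psfFwhmXY, object@psfFwhmZ))
  cat(sprintf("  %d initial puncta; gain %.2f/interval; loss p=%.3f; %.2f transport packets/interval\n",
              object@nInitialPuncta, object@gainRate, object@lossProb,
              object@transportPacketRate))
  cat(sprintf("  amplitude %.0f, background %.0f, read noise sd %.1f, shot noise %s; seed %d\n",
              object@punctumAmplitude, object@backgroundLevel,
              object@readNoiseSD, object@shotNoise, object@rngSeed))
})

#' @rdname SyntheticSeries-class
#' @param x a SyntheticSeries.
setMethod("groundTruth", "SyntheticSeries", function(x) x@truth)

#' @rdname SyntheticSeries-class
setMethod("appliedDrift", "SyntheticSeries", function(x) x@appliedDrift)

#' @rdname SyntheticSeries-class
setMethod("imageSeries", "SyntheticSeries", function(x) x@series)

setMethod("show", "SyntheticSeries", function(object) {
  cat("SyntheticSeries with ground truth:\n")
  show(object@series)
  tr <- object@truth
  cat(sprintf("  %d true puncta (%d transport packets), %d present at t0\n",
              nrow(tr), sum(tr$is_transport_packet),
              sum(tr$birth_tp == 1L & !tr$is_transport_packet)))
})

#' @rdname SpikeTrialSet-class
setMethod("spikeTrials", "SpikeTrialSet", function(x) x@trials)

#' @rdname SpikeTrialSet-class
setMethod("nTrials", "SpikeTrialSet", function(x) length(x@trials))

setMethod("show", "SpikeTrialSet", function(object) {
  cat("SpikeTrialSet:", length(object@trials), "trial(s),",
      sum(lengths(object@trials)), "spikes total\n")
  cat(sprintf("  baseline [%g, %g) s, stimulus [%g, %g) s\n",
              object@baselineWindow[1L], object@baselineWindow[2L],
              object@stimWindow[1L], object@stimWindow[2L]))
  if (nzchar(object@label)) cat("  label:", object@label, "\n")
})
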