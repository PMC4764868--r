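#' @import methods
NULL

#' Two-channel 3D time-lapse volume
#'
#' Container for an ordered series of multi-channel 3D intensity volumes with
#' physical voxel size and timepoint timestamps. The first channel is by
#' convention the punctum reporter (e.g. sypGFP) and the second the cytosolic
#' reference/axon-fill channel (e.g. tdTomato) used for drift correction.
#'
#' Voxel `(i, j, k)` (1-based) has physical coordinates
#' `((i-1)*vx, (j-1)*vy, (k-1)*vz)` in micrometres.
#'
#' @slot data numeric 5-D array with dimensions `(x, y, z, channel, time)`.
#' @slot voxelSize numeric length-3, voxel edge lengths in micrometres
#'   `(x, y, z)`.
#' @slot timepointsMin numeric, acquisition time of each timepoint in minutes
#'   from session start.
#' @slot channelNames character, one name per channel.
#' @slot valid logical array `(x, y, z, time)` marking voxels that carry real
#'   data (voxels shifted in from outside the field during drift correction
#'   are invalid); a zero-length array means "all valid".
#'
#' @seealso [TimeSeriesVolume()] for the constructor, [generateSeries()],
#'   [estimateDrift()], [detectSeries()].
#' @export
setClass("TimeSeriesVolume",
  representation(
    data = "array",
    voxelSize = "numeric",
    timepointsMin = "numeric",
    channelNames = "character",
    valid = "array"
  )
)

setValidity("TimeSeriesVolume", function(object) {
  d <- dim(object@data)
  if (length(d) != 5L)
    return("data must be a 5-D array (x, y, z, channel, time)")
  if (length(object@voxelSize) != 3L || any(!is.finite(object@voxelSize)) ||
      any(object@voxelSize <= 0))
    return("voxelSize must be 3 positive finite values (micrometres)")
  if (length(object@timepointsMin) != d[5L])
    return("timepointsMin length must equal the number of timepoints")
  if (is.unsorted(object@timepointsMin, strictly = TRUE))
    return("timepointsMin must be strictly increasing")
  if (length(object@channelNames) != d[4L])
    return("channelNames length must equal the number of channels")
  if (length(object@valid) > 0L) {
    dv <- dim(object@valid)
    if (length(dv) != 4L || !all(dv == d[c(1:3, 5L)]))
      return("valid mask must have dimensions (x, y, z, time)")
  }
  TRUE
})

#' Construct a TimeSeriesVolume
#'
#' @param data numeric 5-D array `(x, y, z, channel, time)`.
#' @param voxelSize numeric length-3 voxel size in micrometres.
#' @param timepointsMin numeric acquisition times in minutes; defaults to
#'   30-minute spacing starting at 0.
#' @param channelNames character channel names; defaults to
#'   `c("puncta", "reference")` for two channels.
#' @param valid optional logical array `(x, y, z, time)` of valid voxels.
#'
#' @return A [TimeSeriesVolume-class] object.
#' @examples
#' a <- array(0, c(8, 8, 4, 2, 3))
#' tsv <- TimeSeriesVolume(a, voxelSize = c(0.2, 0.2, 1))
#' nTimepoints(tsv)
#' @export
TimeSeriesVolume <- function(data, voxelSize,
                             timepointsMin = NULL,
                             channelNames = NULL,
                             valid = array(logical(0), c(0, 0, 0, 0))) {
  d <- dim(data)
  if (is.null(d) || length(d) != 5L)
    stop("data must be a 5-D array (x, y, z, channel, time)")
  if (is.null(timepointsMin))
    timepointsMin <- 30 * (seq_len(d[5L]) - 1)
  if (is.null(channelNames)) {
    channelNames <- if (d[4L] == 2L) c("puncta", "reference")
                    else paste0("ch", seq_len(d[4L]))
  }
  new("TimeSeriesVolume", data = data, voxelSize = as.numeric(voxelSize),
      timepointsMin = as.numeric(timepointsMin),
      channelNames = as.character(channelNames), valid = valid)
}

#' Synthetic imaging-session configuration
#'
#' Parameters of the synthetic two-channel 3D time-lapse generator. The
#' defaults emulate a single-glomerulus ROI imaged every 30 minutes for 3
#' hours (7 timepoints) with the anisotropic two-photon PSF measured at
#' 0.46 um FWHM laterally and 2.28 um FWHM axially.
#'
#' @slot volumeShape integer length-3, volume size in voxels `(x, y, z)`.
#' @slot voxelSize numeric length-3, voxel size in micrometres.
#' @slot nTimepoints integer, number of timepoints (default 7).
#' @slot intervalMin numeric, inter-timepoint interval in minutes (default 30).
#' @slot psfFwhmXY numeric, lateral PSF full width at half maximum in
#'   micrometres (default 0.46); the rendered Gaussian sigma is
#'   `FWHM / (2*sqrt(2*log(2)))`.
#' @slot psfFwhmZ numeric, axial PSF FWHM in micrometres (default 2.28).
#' @slot nInitialPuncta integer, puncta present at the first timepoint.
#' @slot gainRate numeric, expected newly formed puncta per 30-min interval
#'   (Poisson mean).
#' @slot lossProb numeric in `[0, 1]`, per-punctum per-interval probability of
#'   elimination.
#' @slot transportPacketRate numeric, expected single-timepoint transient
#'   puncta (transport packets) per interval.
#' @slot driftMax integer length-3, bound (voxels) on the per-timepoint rigid
#'   shift drawn uniformly in `[-driftMax, driftMax]`.
#' @slot punctumAmplitude numeric, peak punctum signal in photon counts.
#' @slot backgroundLevel numeric, mean background photon count.
#' @slot readNoiseSD numeric, s.d. of additive Gaussian read noise.
#' @slot shotNoise logical, apply Poisson shot noise to the clean signal.
#' @slot minSeparationUm numeric, minimum 3D distance between simultaneously
#'   present puncta (micrometres).
#' @slot rngSeed integer seed making the whole simulation reproducible.
#'
#' @seealso [simConfig()], [generateSeries()], [expectedSessionCounts()].
#' @export
setClass("SimConfig",
  representation(
    volumeShape = "integer",
    voxelSize = "numeric",
    nTimepoints = "integer",
    intervalMin = "numeric",
    psfFwhmXY = "numeric",
    psfFwhmZ = "numeric",
    nInitialPuncta = "integer",
    gainRate = "numeric",
    lossProb = "numeric",
    transportPacketRate = "numeric",
    driftMax = "integer",
    punctumAmplitude = "numeric",
    backgroundLevel = "numeric",
    readNoiseSD = "numeric",
    shotNoise = "logical",
    minSeparationUm = "numeric",
    rngSeed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  if (length(object@volumeShape) != 3L || any(object@volumeShape < 1L))
    return("volumeShape must be 3 positive integers")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    return("voxelSize must be 3 positive values (micrometres)")
  if (object@nTimepoints < 2L)
    return("nTimepoints must be >= 2")
  if (object@intervalMin <= 0)
    return("intervalMin must be positive")
  if (object@psfFwhmXY <= 0 || object@psfFwhmZ <= 0)
    return("PSF widths must be positive")
  if (object@nInitialPuncta < 0L)
    return("nInitialPuncta must be >= 0")
  if (object@gainRate < 0 || object@transportPacketRate < 0)
    return("rates must be >= 0")
  if (object@lossProb < 0 || object@lossProb > 1)
    return("lossProb must lie in [0, 1]")
  if (length(object@driftMax) != 3L || any(object@driftMax < 0L))
    return("driftMax must be 3 non-negative integers (voxels)")
  if (object@punctumAmplitude < 0 || object@backgroundLevel < 0 ||
      object@readNoiseSD < 0)
    return("intensity parameters must be >= 0")
  if (object@minSeparationUm < 0)
    return("minSeparationUm must be >= 0")
  TRUE
})

#' Create a simulation configuration
#'
#' @param volumeShape integer length-3 volume size in voxels.
#' @param voxelSize numeric length-3 voxel size in micrometres.
#' @param nTimepoints number of timepoints.
#' @param intervalMin minutes between timepoints.
#' @param psfFwhmXY,psfFwhmZ PSF full width at half maximum (micrometres).
#' @param nInitialPuncta puncta present at the first timepoint.
#' @param gainRate expected new puncta per interval (Poisson mean).
#' @param lossProb per-punctum per-interval elimination probability.
#' @param transportPacketRate expected transport packets per interval.
#' @param driftMax integer length-3 bound on per-timepoint shifts (voxels).
#' @param punctumAmplitude peak punctum photon count.
#' @param backgroundLevel mean background photon count.
#' @param readNoiseSD Gaussian read-noise s.d.
#' @param shotNoise apply Poisson shot noise (logical).
#' @param minSeparationUm minimum distance between coexisting puncta.
#' @param rngSeed integer seed.
#'
#' @return A validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(nInitialPuncta = 10, gainRate = 0, lossProb = 0,
#'                  transportPacketRate = 0, rngSeed = 1)
#' cfg
#' @export
simConfig <- function(volumeShape = c(192L, 192L, 16L),
                      voxelSize = c(0.09, 0.09, 1.0),
                      nTimepoints = 7L,
                      intervalMin = 30,
                      psfFwhmXY = 0.46,
                      psfFwhmZ = 2.28,
                      nInitialPuncta = 40L,
                      gainRate = 1.5,
                      lossProb = 0.04,
                      transportPacketRate = 0.5,
                      driftMax = c(3L, 3L, 1L),
                      punctumAmplitude = 600,
                      backgroundLevel = 30,
                      readNoiseSD = 8,
                      shotNoise = TRUE,
                      minSeparationUm = 1.5,
                      rngSeed = 1L) {
  new("SimConfig",
      volumeShape = as.integer(volumeShape),
      voxelSize = as.numeric(voxelSize),
      nTimepoints = as.integer(nTimepoints),
      intervalMin = as.numeric(intervalMin),
      psfFwhmXY = as.numeric(psfFwhmXY),
      psfFwhmZ = as.numeric(psfFwhmZ),
      nInitialPuncta = as.integer(nInitialPuncta),
      gainRate = as.numeric(gainRate),
      lossProb = as.numeric(lossProb),
      transportPacketRate = as.numeric(transportPacketRate),
      driftMax = as.integer(driftMax),
      punctumAmplitude = as.numeric(punctumAmplitude),
      backgroundLevel = as.numeric(backgroundLevel),
      readNoiseSD = as.numeric(readNoiseSD),
      shotNoise = as.logical(shotNoise),
      minSeparationUm = as.numeric(minSeparationUm),
      rngSeed = as.integer(rngSeed))
}

#' Synthetic series with ground truth
#'
#' Result of [generateSeries()]: the rendered two-channel series, the table of
#' true puncta with their birth/death timepoints, and the rigid drift applied
#' at each timepoint.
#'
#' @slot series a [TimeSeriesVolume-class].
#' @slot truth data.frame, one row per true punctum: `id`, `x_um`, `y_um`,
#'   `z_um` (static ROI-frame position), `birth_tp`, `death_tp` (last
#'   timepoint present), `censored` (present at the final timepoint),
#'   `is_transport_packet`.
#' @slot appliedDrift integer matrix `nTimepoints x 3`, the rigid shift in
#'   voxels applied at each timepoint (row 1 is zero).
#' @slot config the [SimConfig-class] used.
#'
#' @export
setClass("SyntheticSeries",
  representation(
    series = "TimeSeriesVolume",
    truth = "data.frame",
    appliedDrift = "matrix",
    config = "SimConfig"
  )
)

setValidity("SyntheticSeries", function(object) {
  need <- c("id", "x_um", "y_um", "z_um", "birth_tp", "death_tp",
            "censored", "is_transport_packet")
  if (!all(need %in% names(object@truth)))
    return(paste("truth must have columns:", paste(need, collapse = ", ")))
  if (nrow(object@truth) > 0 &&
      any(object@truth$birth_tp > object@truth$death_tp))
    return("birth_tp must be <= death_tp")
  if (dim(object@series@data)[4L] != 2L)
    return("synthetic series must have exactly 2 channels")
  if (!all(dim(object@appliedDrift) ==
           c(dim(object@series@data)[5L], 3L)))
    return("appliedDrift must be nTimepoints x 3")
  TRUE
})

#' Per-trial spike times around a stimulus window
#'
#' Spike times for repeated trials of a 3-s stimulus preceded by an equal
#' baseline window, the unit of the evoked firing-rate (delta FR) statistics.
#'
#' @slot trials list of sorted numeric vectors of spike times (seconds,
#'   trial-relative).
#' @slot baselineWindow numeric length-2, `[start, end)` of the baseline
#'   window in seconds.
#' @slot stimWindow numeric length-2, `[start, end)` of the stimulus window;
#'   must start where the baseline ends.
#' @slot label character condition label (e.g. stimulus intensity).
#'
#' @seealso [generateSpikeTrials()], [deltaFR()], [frSignificance()], [psth()].
#' @export
setClass("SpikeTrialSet",
  representation(
    trials = "list",
    baselineWindow = "numeric",
    stimWindow = "numeric",
    label = "character"
  )
)

setValidity("SpikeTrialSet", function(object) {
  if (length(object@baselineWindow) != 2L || length(object@stimWindow) != 2L)
    return("windows must be length-2 numeric (start, end)")
  if (diff(object@baselineWindow) <= 0 || diff(object@stimWindow) <= 0)
    return("windows must have positive duration")
  if (object@baselineWindow[2L] > object@stimWindow[1L])
    return("baseline window must precede the stimulus window")
  for (tr in object@trials) {
    if (is.unsorted(tr)) return("spike times must be sorted within trials")
  }
  TRUE
})

#' Construct a SpikeTrialSet
#'
#' @param trials list of numeric spike-time vectors (seconds); each is sorted.
#' @param baselineWindow numeric length-2 baseline window (seconds).
#' @param stimWindow numeric length-2 stimulus window (seconds).
#' @param label condition label.
#' @return A [SpikeTrialSet-class].
#' @examples
#' SpikeTrialSet(list(c(0.5, 3.2), numeric(0)))
#' @export
SpikeTrialSet <- function(trials, baselineWindow = c(0, 3),
                          stimWindow = c(3, 6), label = "") {
  trials <- lapply(trials, function(x) sort(as.numeric(x)))
  new("SpikeTrialSet", trials = trials,
      baselineWindow = as.numeric(baselineWindow),
      stimWindow = as.numeric(stimWindow), label = as.character(label))
}
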