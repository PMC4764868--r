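# --- TIFF series I/O ----------------------------------------------------------

#' Write a series as a multi-page TIFF with a metadata sidecar
#'
#' Voxel data are stored as 16-bit pages in timepoint-channel-z order
#' (timepoint outermost), one page per z-slice, together with a JSON sidecar
#' (`<path>.json`) declaring the dimension order, voxel size, timepoints and
#' channel names. Intensities must be integer-valued in `[0, 65535]`
#' (non-integer values are rounded with a warning), so a write-read
#' round-trip is bit-exact.
#'
#' @param series a [TimeSeriesVolume-class].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
writeSeries <- function(series, path) {
  stopifnot(is(series, "TimeSeriesVolume"))
  d <- dim(series@data)
  dat <- series@data
  if (any(dat != round(dat))) {
    warning("non-integer intensities rounded for 16-bit TIFF storage")
    dat <- round(dat)
  }
  if (min(dat) < 0 || max(dat) > 65535)
    stop("intensities must lie in [0, 65535] for 16-bit TIFF storage")
  pages <- vector("list", d[5L] * d[4L] * d[3L])
  i <- 0L
  for (t in seq_len(d[5L]))
    for (ch in seq_len(d[4L]))
      for (z in seq_len(d[3L])) {
        i <- i + 1L
        pages[[i]] <- t(dat[, , z, ch, t]) / 65535
      }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  meta <- list(
    dimension_order = "TCZYX",
    shape_xyz = d[1:3],
    n_channels = d[4L],
    n_timepoints = d[5L],
    voxel_size_um = series@voxelSize,
    timepoints_min = series@timepointsMin,
    channel_names = series@channelNames,
    intensity_scale = 65535
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a series from a multi-page TIFF
#'
#' Reads a TIFF written by [writeSeries()] (or any plain multi-page TIFF in
#' timepoint-channel-z page order), taking the axis declaration from the
#' JSON sidecar or from explicit arguments. Without a sidecar, `voxelSize`,
#' `nChannels` and `nTimepoints` are required: the page count alone is
#' ambiguous.
#'
#' @param path TIFF path.
#' @param metadataPath sidecar JSON path (default `<path>.json`).
#' @param voxelSize,nChannels,nTimepoints,timepointsMin,channelNames
#'   overrides / replacements for missing metadata.
#' @return A [TimeSeriesVolume-class].
#' @export
readSeries <- function(path, metadataPath = paste0(path, ".json"),
                       voxelSize = NULL, nChannels = NULL,
                       nTimepoints = NULL, timepointsMin = NULL,
                       channelNames = NULL) {
  meta <- if (file.exists(metadataPath))
    jsonlite::read_json(metadataPath, simplifyVector = TRUE) else list()
  voxelSize <- voxelSize %||% meta$voxel_size_um
  nChannels <- nChannels %||% meta$n_channels
  nTimepoints <- nTimepoints %||% meta$n_timepoints
  timepointsMin <- timepointsMin %||% meta$timepoints_min
  channelNames <- channelNames %||% meta$channel_names
  if (is.null(voxelSize))
    stop("voxel size unknown: provide voxelSize or a metadata sidecar")
  pages <- tiff::readTIFF(path, all = TRUE)
  nPages <- length(pages)
  if (is.null(nChannels) || is.null(nTimepoints)) {
    cand <- vapply(Filter(function(c) nPages %% c == 0, 1:4),
                   function(c) paste0(c, " channel(s) x ", nPages / c,
                                      " z*timepoint pages"),
                   character(1))
    stop("axis order ambiguous for ", nPages,
         " pages: provide nChannels and nTimepoints; candidates: ",
         paste(cand, collapse = "; "))
  }
  nChannels <- as.integer(nChannels); nTimepoints <- as.integer(nTimepoints)
  if (nPages %% (nChannels * nTimepoints) != 0)
    stop("page count ", nPages, " is not divisible by nChannels (",
         nChannels, ") x nTimepoints (", nTimepoints,
         "): declared channel/timepoint counts do not match the file")
  nz <- nPages %/% (nChannels * nTimepoints)
  ny <- nrow(pages[[1L]]); nx <- ncol(pages[[1L]])
  dat <- array(0, c(nx, ny, nz, nChannels, nTimepoints))
  i <- 0L
  for (t in seq_len(nTimepoints))
    for (ch in seq_len(nChannels))
      for (z in seq_len(nz)) {
        i <- i + 1L
        dat[, , z, ch, t] <- t(pages[[i]]) * 65535
      }
  dat <- round(dat)
  TimeSeriesVolume(dat, voxelSize = as.numeric(voxelSize),
                   timepointsMin = timepointsMin,
                   channelNames = channelNames)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- tables and configs -------------------------------------------------------

#' Write / read a ground-truth punctum table as CSV
#'
#' @param truth data.frame as in [SyntheticSeries-class] `truth`.
#' @param path CSV path.
#' @return `path` / the truth data.frame.
#' @export
writeTruth <- function(truth, path) {
  write.csv(truth, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
  tr <- read.csv(path)
  tr$censored <- as.logical(tr$censored)
  tr$is_transport_packet <- as.logical(tr$is_transport_packet)
  tr
}

#' Read and validate a pipeline configuration (YAML)
#'
#' A single YAML file with per-stage sections (`seed`, `simulate`,
#' `register`, `detect`, `track`, `stats`); every stage's parameters are
#' validated before any computation starts.
#'
#' @param path YAML path.
#' @return The validated configuration list.
#' @seealso [runAll()], [writePipelineConfig()], [defaultPipelineConfig()]
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  validatePipelineConfig(cfg)
}

#' @rdname readPipelineConfig
#' @param config a configuration list.
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Default pipeline configuration
#'
#' @param seed global RNG seed.
#' @return A configuration list accepted by [runAll()].
#' @export
defaultPipelineConfig <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    simulate = list(enabled = TRUE),
    register = list(referenceChannel = "reference", subVoxel = FALSE),
    detect = list(thresholdMultiplier = 1, minVoxels = 4L,
                  connectivity = 26L, radiusPx = 2L),
    track = list(maxDisplacementUm = 0.5, allowGaps = FALSE),
    stats = list(roiId = "roi1")
  )
}

validatePipelineConfig <- function(cfg) {
  base <- defaultPipelineConfig()
  for (sec in names(base)) {
    if (is.null(cfg[[sec]])) cfg[[sec]] <- base[[sec]]
    else if (sec != "seed")
      for (k in names(base[[sec]]))
        if (is.null(cfg[[sec]][[k]])) cfg[[sec]][[k]] <- base[[sec]][[k]]
  }
  cfg$seed <- as.integer(cfg$seed)
  det <- cfg$detect
  if (det$thresholdMultiplier <= 0)
    stop("detect: thresholdMultiplier must be > 0")
  if (!det$connectivity %in% c(6L, 18L, 26L))
    stop("detect: connectivity must be 6, 18 or 26")
  if (det$minVoxels < 1L) stop("detect: minVoxels must be >= 1")
  if (det$radiusPx < 1L) stop("detect: radiusPx must be >= 1")
  if (cfg$track$maxDisplacementUm <= 0)
    stop("track: maxDisplacementUm must be > 0")
  if (isTRUE(cfg$simulate$enabled)) {
    simArgs <- cfg$simulate[setdiff(names(cfg$simulate), "enabled")]
    simArgs$rngSeed <- cfg$seed
    do.call(simConfig, simArgs)  # constructor validates
  } else if (is.null(cfg$input$series)) {
    stop("either simulate.enabled or input.series must be given")
  }
  cfg
}
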