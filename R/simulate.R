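#' @importFrom stats rpois runif rnorm rbinom sd median quantile spline
#' @importFrom withr with_seed
NULL

# --- event process ----------------------------------------------------------

# Birth/death/transport-packet event simulation alone, no geometry and no
# imaging. Assumes the RNG is already seeded by the caller. Returns a
# data.frame with birth_tp, death_tp (last timepoint present), censored,
# is_transport_packet.
simulateEvents <- function(config) {
  tp <- config@nTimepoints
  birth <- rep(1L, config@nInitialPuncta)
  death <- rep(tp, config@nInitialPuncta)
  alive <- rep(TRUE, config@nInitialPuncta)
  packet <- rep(FALSE, config@nInitialPuncta)
  for (i in seq_len(tp - 1L)) {
    # eliminations over interval [i, i+1): punctum last seen at timepoint i
    idx <- which(alive)
    if (length(idx) > 0 && config@lossProb > 0) {
      die <- idx[runif(length(idx)) < config@lossProb]
      death[die] <- i
      alive[die] <- FALSE
    }
    # newly formed puncta, first seen at timepoint i+1, themselves at risk
    nNew <- rpois(1L, config@gainRate)
    if (nNew > 0) {
      birth <- c(birth, rep(i + 1L, nNew))
      death <- c(death, rep(tp, nNew))
      alive <- c(alive, rep(TRUE, nNew))
      packet <- c(packet, rep(FALSE, nNew))
    }
    # transport packets: transient clusters present for exactly one timepoint
    nPk <- rpois(1L, config@transportPacketRate)
    if (nPk > 0) {
      birth <- c(birth, rep(i + 1L, nPk))
      death <- c(death, rep(i + 1L, nPk))
      alive <- c(alive, rep(FALSE, nPk))
      packet <- c(packet, rep(TRUE, nPk))
    }
  }
  data.frame(
    birth_tp = birth,
    death_tp = death,
    censored = !packet & death == tp,
    is_transport_packet = packet
  )
}

# Session counts under the analysis inclusion rule (present for >= 2
# consecutive timepoints, so transport packets and last-timepoint births are
# excluded), computed directly from a truth table.
truthSessionCounts <- function(truth, nTimepoints) {
  inc <- !truth$is_transport_packet &
         (truth$death_tp - truth$birth_tp + 1L) >= 2L
  t0 <- truth$birth_tp == 1L
  c(n_t0 = sum(inc & t0),
    n_t3h = sum(inc & truth$death_tp == nTimepoints),
    n_gain = sum(inc & !t0),
    n_lost = sum(inc & truth$death_tp < nTimepoints))
}

# --- geometry ---------------------------------------------------------------

# per-axis PSF Gaussian sigma in voxels
psfSigmaVox <- function(config) {
  sXY <- fwhmToSigma(config@psfFwhmXY)
  sZ <- fwhmToSigma(config@psfFwhmZ)
  c(sXY, sXY, sZ) / config@voxelSize
}

# interior placement bounds in um: >= 2x PSF support plus the drift bound
# from every edge, so no punctum is ever truncated
placementBoundsUm <- function(config) {
  sVox <- psfSigmaVox(config)
  marginVox <- 2 * ceiling(2 * sVox) + config@driftMax
  lo <- marginVox * config@voxelSize
  hi <- (config@volumeShape - 1 - marginVox) * config@voxelSize
  if (any(hi <= lo))
    stop("volume too small to contain a punctum plus PSF support: interior ",
         "placement region is empty along axis ",
         paste(which(hi <= lo), collapse = ","),
         " (need > ", paste(2 * marginVox + 1, collapse = "x"),
         " voxels)")
  list(lo = lo, hi = hi)
}

# rejection-sample n points uniformly in the interior, >= minSep from each
# other and from `existing` (matrix n x 3, um). Separation is measured as a
# lateral-equivalent distance: axis differences are scaled by `sepScale`
# (z differences count less because the axial PSF is wider), so a pair
# "separated" only along z is still rejected as unresolvable.
placePoints <- function(n, bounds, minSep, existing = NULL,
                        sepScale = c(1, 1, 1)) {
  pts <- matrix(numeric(0), 0L, 3L)
  if (n == 0L) return(pts)
  all <- existing
  for (k in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(5000L)) {
      p <- bounds$lo + runif(3) * (bounds$hi - bounds$lo)
      if (is.null(all) || nrow(all) == 0L ||
          min(sqrt(colSums(((t(all) - p) * sepScale)^2))) >= minSep) {
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("could not place puncta at the requested density and minimum ",
           "separation; reduce nInitialPuncta/gainRate or minSeparationUm")
    pts <- rbind(pts, p)
    all <- rbind(all, p)
  }
  unname(pts)
}

# Assign static ROI-frame positions to all simulated puncta such that puncta
# that coexist at any timepoint respect the minimum separation.
assignPositions <- function(truth, config) {
  bounds <- placementBoundsUm(config)
  sepScale <- c(1, 1, config@psfFwhmXY / config@psfFwhmZ)
  n <- nrow(truth)
  pos <- matrix(NA_real_, n, 3L)
  ord <- order(truth$birth_tp, seq_len(n))
  for (i in ord) {
    coexist <- which(!is.na(pos[, 1]) &
                     truth$birth_tp <= truth$death_tp[i] &
                     truth$death_tp >= truth$birth_tp[i])
    pos[i, ] <- placePoints(1L, bounds, config@minSeparationUm,
                            existing = pos[coexist, , drop = FALSE],
                            sepScale = sepScale)
  }
  pos
}

# --- rendering --------------------------------------------------------------

# add an anisotropic Gaussian blob at a continuous um position
stampGaussian <- function(vol, posUm, voxelSize, sigmaUm, amplitude,
                          cutoffSigma = 4) {
  d <- dim(vol)
  cVox <- posUm / voxelSize + 1
  sVox <- sigmaUm / voxelSize
  lo <- pmax(1L, floor(cVox - cutoffSigma * sVox))
  hi <- pmin(d, ceiling(cVox + cutoffSigma * sVox))
  if (any(lo > hi)) return(vol)
  gx <- exp(-0.5 * ((seq(lo[1], hi[1]) - cVox[1]) / sVox[1])^2)
  gy <- exp(-0.5 * ((seq(lo[2], hi[2]) - cVox[2]) / sVox[2])^2)
  gz <- exp(-0.5 * ((seq(lo[3], hi[3]) - cVox[3]) / sVox[3])^2)
  blob <- amplitude * (gx %o% gy %o% gz)
  vol[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
    vol[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE] + blob
  vol
}

# sample smooth tube centrelines (axon-like structures) spanning the volume;
# returns a matrix of um positions along all tubes
makeTubeCentrelines <- function(config, nTubes = 3L, stepUm = 0.15) {
  extent <- (config@volumeShape - 1) * config@voxelSize
  pts <- matrix(numeric(0), 0L, 3L)
  for (k in seq_len(nTubes)) {
    nCtrl <- 5L
    cx <- seq(0, extent[1], length.out = nCtrl)
    cy <- runif(nCtrl, 0.1, 0.9) * extent[2]
    cz <- runif(nCtrl, 0.2, 0.8) * extent[3]
    nOut <- max(2L, ceiling(extent[1] / stepUm))
    sy <- spline(cx, cy, n = nOut)
    sz <- spline(cx, cz, n = nOut)
    pts <- rbind(pts, cbind(sy$x, sy$y, sz$y))
  }
  pts
}

renderCleanVolume <- function(positionsUm, amplitudes, config,
                              sigmaUm, background) {
  vol <- array(background, config@volumeShape)
  if (length(amplitudes) > 0) {
    for (i in seq_along(amplitudes)) {
      vol <- stampGaussian(vol, positionsUm[i, ], config@voxelSize,
                           sigmaUm, amplitudes[i])
    }
  }
  vol
}

applyNoise <- function(clean, config) {
  v <- as.numeric(clean)
  if (config@shotNoise) v <- rpois(length(v), pmax(v, 0))
  if (config@readNoiseSD > 0) v <- v + rnorm(length(v), 0, config@readNoiseSD)
  v <- round(pmax(pmin(v, 65535), 0))
  array(v, dim(clean))
}

# --- public operations ------------------------------------------------------

#' Generate a synthetic two-channel time-lapse series with ground truth
#'
#' Simulates a 30-min-interval imaging session of a glomerular ROI: puncta
#' are born (Poisson per interval) and eliminated (Bernoulli per punctum per
#' interval), transient single-timepoint transport packets are added, a rigid
#' integer-voxel drift is applied per timepoint, puncta are rendered as
#' anisotropic Gaussian blobs (PSF-shaped) on the punctum channel, tube-like
#' axon structures are rendered on the reference channel, and Poisson shot
#' noise plus Gaussian read noise is applied. The same configuration and seed
#' give bit-identical output.
#'
#' @param config a [SimConfig-class].
#' @return A [SyntheticSeries-class] holding the rendered
#'   [TimeSeriesVolume-class], the ground-truth punctum table, the applied
#'   per-timepoint drift (voxels) and the configuration.
#' @examples
#' cfg <- simConfig(volumeShape = c(48, 48, 10), voxelSize = c(0.2, 0.2, 1),
#'                  nInitialPuncta = 5L, gainRate = 0, lossProb = 0,
#'                  transportPacketRate = 0, driftMax = c(0, 0, 0),
#'                  rngSeed = 7L)
#' ss <- generateSeries(cfg)
#' groundTruth(ss)
#' @export
generateSeries <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  placementBoundsUm(config)  # fail early if the volume is too small
  withr::with_seed(config@rngSeed, {
    truth <- simulateEvents(config)
    pos <- assignPositions(truth, config)
    truth$id <- seq_len(nrow(truth))
    truth$x_um <- pos[, 1]; truth$y_um <- pos[, 2]; truth$z_um <- pos[, 3]
    truth <- truth[, c("id", "x_um", "y_um", "z_um", "birth_tp", "death_tp",
                       "censored", "is_transport_packet")]

    tubes <- makeTubeCentrelines(config)
    tubeSigma <- c(0.25, 0.25, 0.6)  # um; thin cytosolic axon cross-section
    tubeAmp <- 0.12 * config@punctumAmplitude  # per sample; overlaps add up

    tp <- config@nTimepoints
    drift <- matrix(0L, tp, 3L)
    for (t in 2:tp) {
      drift[t, ] <- vapply(config@driftMax, function(m) {
        if (m == 0L) 0L else as.integer(sample(seq(-m, m), 1L))
      }, integer(1))
    }

    sigmaUm <- c(fwhmToSigma(config@psfFwhmXY), fwhmToSigma(config@psfFwhmXY),
                 fwhmToSigma(config@psfFwhmZ))
    d <- c(config@volumeShape, 2L, tp)
    dat <- array(0, d)
    for (t in seq_len(tp)) {
      shiftUm <- drift[t, ] * config@voxelSize
      present <- truth$birth_tp <= t & truth$death_tp >= t
      amp <- rep(config@punctumAmplitude, sum(present))
      # transport packets are smaller clusters in transit
      amp[truth$is_transport_packet[present]] <-
        0.7 * config@punctumAmplitude
      posT <- cbind(truth$x_um, truth$y_um, truth$z_um)[present, ,
                                                        drop = FALSE]
      posT <- sweep(posT, 2L, shiftUm, "+")
      ch1 <- renderCleanVolume(posT, amp, config, sigmaUm,
                               config@backgroundLevel)
      ch2 <- array(config@backgroundLevel, config@volumeShape)
      tubesT <- sweep(tubes, 2L, shiftUm, "+")
      for (i in seq_len(nrow(tubesT)))
        ch2 <- stampGaussian(ch2, tubesT[i, ], config@voxelSize, tubeSigma,
                             tubeAmp, cutoffSigma = 3)
      dat[, , , 1L, t] <- applyNoise(ch1, config)
      dat[, , , 2L, t] <- applyNoise(ch2, config)
    }
    series <- TimeSeriesVolume(
      dat, voxelSize = config@voxelSize,
      timepointsMin = config@intervalMin * (seq_len(tp) - 1),
      channelNames = c("puncta", "reference"))
    new("SyntheticSeries", series = series, truth = truth,
        appliedDrift = drift, config = config)
  })
}

#' Expected session counts by event simulation (imaging-free oracle)
#'
#' Monte-Carlo expectation of the session count summary (`n_t0`, `n_t3h`,
#' `n_gain`, `n_lost`) under a configuration's birth/death process, computed
#' by brute-force simulation of the event process alone -- no geometry, no
#' rendering, no detection. Counts follow the analysis inclusion rule
#' (puncta present for at least two consecutive timepoints), so this is the
#' ground-truth reference the imaging pipeline is benchmarked against.
#'
#' @param config a [SimConfig-class].
#' @param nReps number of Monte-Carlo replicates (>= 100).
#' @param seed integer seed for the replicate stream (default derived from
#'   the config seed).
#' @return A list with `mean` and `se` (named numeric vectors over `n_t0`,
#'   `n_t3h`, `n_gain`, `n_lost`, and the implied `turnover_pct`), plus
#'   `nReps` and the per-replicate count matrix `reps`.
#' @examples
#' cfg <- simConfig(nInitialPuncta = 100L, gainRate = 0, lossProb = 0.05,
#'                  transportPacketRate = 0)
#' expectedSessionCounts(cfg, nReps = 200)$mean
#' @export
expectedSessionCounts <- function(config, nReps = 200L,
                                  seed = config@rngSeed + 10000L) {
  stopifnot(is(config, "SimConfig"))
  if (nReps < 100L) stop("nReps must be >= 100")
  reps <- withr::with_seed(seed, {
    t(vapply(seq_len(nReps), function(r) {
      truthSessionCounts(simulateEvents(config), config@nTimepoints)
    }, numeric(4)))
  })
  colnames(reps) <- c("n_t0", "n_t3h", "n_gain", "n_lost")
  tov <- 100 * (reps[, "n_gain"] + reps[, "n_lost"]) /
    pmax(reps[, "n_t0"] + reps[, "n_t3h"], 1)
  m <- c(colMeans(reps), turnover_pct = mean(tov))
  s <- c(apply(reps, 2, sd), turnover_pct = sd(tov)) / sqrt(nReps)
  list(mean = m, se = s, nReps = nReps, reps = reps)
}

#' Generate Poisson spike trials around a 3-s stimulus
#'
#' Homogeneous Poisson spike trains at `baselineRate` outside and `stimRate`
#' inside a stimulus window, for repeated trials laid out as a baseline
#' window immediately followed by an equal-duration stimulus window
#' (mimicking a 3-s light-pulse protocol).
#'
#' @param baselineRate baseline firing rate in Hz (>= 0).
#' @param stimRate firing rate during the stimulus in Hz (>= 0).
#' @param nTrials number of trials.
#' @param seed integer seed.
#' @param baselineDur,stimDur window durations in seconds (default 3 each).
#' @return A [SpikeTrialSet-class] with baseline window `[0, baselineDur)`
#'   and stimulus window `[baselineDur, baselineDur + stimDur)`.
#' @examples
#' ts <- generateSpikeTrials(5, 20, nTrials = 10, seed = 1)
#' deltaFR(ts)$mean_delta_fr
#' @export
generateSpikeTrials <- function(baselineRate, stimRate, nTrials,
                                seed = 1L, baselineDur = 3, stimDur = 3) {
  stopifnot(baselineRate >= 0, stimRate >= 0, nTrials >= 1)
  trials <- withr::with_seed(seed, {
    lapply(seq_len(nTrials), function(i) {
      nb <- rpois(1L, baselineRate * baselineDur)
      ns <- rpois(1L, stimRate * stimDur)
      sort(c(runif(nb, 0, baselineDur),
             baselineDur + runif(ns, 0, stimDur)))
    })
  })
  SpikeTrialSet(trials, baselineWindow = c(0, baselineDur),
                stimWindow = c(baselineDur, baselineDur + stimDur))
}
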