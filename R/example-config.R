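#' Reference session configurations for the two dynamic regimes
#'
#' Ready-made [SimConfig-class] objects emulating a 7-timepoint, 30-min
#' interval session of a single ROI at desk-scale problem size
#' (96 x 96 x 14 voxels at 0.12 x 0.12 x 1 um): an `"immature"`-axon-like
#' regime with high punctum turnover (event-process expectation near 25%
#' per 3 h) and a `"mature"`-axon-like regime with low turnover (near 11%).
#' Both include drift, transport packets, shot noise and read noise at the
#' generator defaults.
#'
#' @param dynamics `"immature"` (high turnover) or `"mature"` (low
#'   turnover).
#' @param rngSeed integer seed.
#' @param ... further arguments overriding [simConfig()] defaults.
#' @return A [SimConfig-class].
#' @examples
#' cfg <- exampleSessionConfig("mature", rngSeed = 3L)
#' expectedSessionCounts(cfg, nReps = 200)$mean[["turnover_pct"]]
#' @export
exampleSessionConfig <- function(dynamics = c("immature", "mature"),
                                 rngSeed = 1L, ...) {
  dynamics <- match.arg(dynamics)
  rates <- switch(dynamics,
                  immature = list(gainRate = 1.0, lossProb = 0.05),
                  mature = list(gainRate = 0.45, lossProb = 0.021))
  args <- list(volumeShape = c(96L, 96L, 14L),
               voxelSize = c(0.12, 0.12, 1),
               nInitialPuncta = 20L,
               gainRate = rates$gainRate,
               lossProb = rates$lossProb,
               transportPacketRate = 0.5,
               driftMax = c(3L, 3L, 1L),
               punctumAmplitude = 600,
               backgroundLevel = 30,
               readNoiseSD = 8,
               rngSeed = rngSeed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(simConfig, args)
}
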