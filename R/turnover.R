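# --- core formulas ----------------------------------------------------------

#' Presynaptic terminal turnover
#'
#' Turnover over an imaging session, defined as
#' `100 * (n_gain + n_lost) / (n_t0 + n_t3h)`: the summed formation and
#' elimination events as a percentage of the summed punctum counts at the
#' first and last timepoints. 0 means a static population; 100 means
#' complete replacement.
#'
#' @param n_t0 puncta present at the first timepoint.
#' @param n_t3h puncta present at the last timepoint.
#' @param n_gain puncta formed after the first timepoint.
#' @param n_lost puncta eliminated before the last timepoint.
#' @return Turnover percentage; `NA` (with a warning) when
#'   `n_t0 + n_t3h == 0`.
#' @examples
#' turnover(100, 110, 20, 10)   # 14.29 %
#' turnover(50, 50, 50, 50)     # complete replacement: 100 %
#' @export
turnover <- function(n_t0, n_t3h, n_gain, n_lost) {
  stopifnot(n_t0 >= 0, n_t3h >= 0, n_gain >= 0, n_lost >= 0)
  den <- n_t0 + n_t3h
  if (any(den == 0)) {
    warning("turnover undefined where n_t0 + n_t3h == 0; reported as NA")
    return(ifelse(den == 0, NA_real_, 100 * (n_gain + n_lost) / den))
  }
  100 * (n_gain + n_lost) / den
}

#' Survival fraction of the session-start cohort
#'
#' `SF_t = n_t / n_0h`: the fraction of puncta present at the first timepoint
#' that are still present at timepoint `t`. Later gains are excluded, so
#' `SF_1 = 1` and SF is non-increasing.
#'
#' @param tracks a filtered `punctaTracks` object.
#' @param t timepoint index (1-based) or vector of indices; default all.
#' @return Named numeric vector of survival fractions; `NA` with a warning if
#'   no puncta are present at the first timepoint.
#' @export
survivalFraction <- function(tracks, t = seq_len(tracks$nTimepoints)) {
  stopifnot(inherits(tracks, "punctaTracks"))
  cohort <- tracks$presence[, 1L]
  n0 <- sum(cohort)
  if (n0 == 0) {
    warning("no puncta present at the first timepoint; SF undefined")
    return(setNames(rep(NA_real_, length(t)), t))
  }
  sf <- colSums(tracks$presence[cohort, t, drop = FALSE]) / n0
  setNames(sf, t)
}

#' Fold change between two values
#'
#' @param a,b numeric values with `b > 0`.
#' @param digits decimals to report (default 2).
#' @return `a / b` rounded to `digits`.
#' @examples
#' foldChange(26.5, 11.3)  # 2.35
#' @export
foldChange <- function(a, b, digits = 2L) {
  if (any(b == 0)) stop("fold change undefined for zero denominator")
  round(a / b, digits)
}

# --- track-level summaries --------------------------------------------------

# gain/loss events per interval from a presence matrix: a gain at interval i
# is an absent -> present transition into timepoint i+1, a loss a
# present -> absent transition out of timepoint i
intervalEvents <- function(presence) {
  tpn <- ncol(presence)
  gains <- losses <- start <- integer(tpn - 1L)
  for (i in seq_len(tpn - 1L)) {
    start[i] <- sum(presence[, i])
    gains[i] <- sum(!presence[, i] & presence[, i + 1L])
    losses[i] <- sum(presence[, i] & !presence[, i + 1L])
  }
  data.frame(interval = seq_len(tpn - 1L), n_start = start,
             n_gain = gains, n_lost = losses)
}

#' Per-interval gain and loss rates
#'
#' Gains (new puncta appearing at the end of an interval) and losses
#' (puncta disappearing over the interval) expressed as a percentage of the
#' puncta present at the interval's start, averaged over all intervals.
#' Intervals that start with zero puncta are excluded with a warning.
#'
#' @param tracks a filtered `punctaTracks` object.
#' @return A list with `per_interval` (data.frame: `interval`, `n_start`,
#'   `n_gain`, `n_lost`, `gain_pct`, `loss_pct`) and the means
#'   `gain_pct_per_interval`, `loss_pct_per_interval`.
#' @export
intervalRates <- function(tracks) {
  stopifnot(inherits(tracks, "punctaTracks"))
  if (tracks$nTimepoints < 2L)
    stop("interval rates need at least 2 timepoints")
  ev <- intervalEvents(tracks$presence)
  ok <- ev$n_start > 0L
  if (!all(ok))
    warning(sum(!ok), " interval(s) with zero starting puncta excluded")
  ev$gain_pct <- ifelse(ok, 100 * ev$n_gain / ev$n_start, NA_real_)
  ev$loss_pct <- ifelse(ok, 100 * ev$n_lost / ev$n_start, NA_real_)
  list(per_interval = ev,
       gain_pct_per_interval = mean(ev$gain_pct[ok]),
       loss_pct_per_interval = mean(ev$loss_pct[ok]))
}

#' Session turnover summary for one ROI
#'
#' Computes the session counts (`n_t0`, `n_t3h`, `n_gain`, `n_lost`; gains
#' and losses count every presence transition, so puncta formed and later
#' eliminated contribute to both and the identity
#' `n_t3h = n_t0 + n_gain - n_lost` holds exactly), turnover, mean
#' per-interval gain/loss percentages, and the survival-fraction curve of
#' the session-start cohort.
#'
#' @param tracks a filtered `punctaTracks` object.
#' @param roiId ROI identifier carried into the output (default `"roi1"`).
#' @return A one-row data.frame: `roi_id`, `n_t0`, `n_t3h`, `n_gain`,
#'   `n_lost`, `turnover_pct`, `gain_pct_per_30min`, `loss_pct_per_30min`;
#'   the SF curve is attached as `attr(, "sf")` (named by minutes).
#' @export
summarizeTurnover <- function(tracks, roiId = "roi1") {
  stopifnot(inherits(tracks, "punctaTracks"))
  tpn <- tracks$nTimepoints
  ev <- intervalEvents(tracks$presence)
  n_t0 <- sum(tracks$presence[, 1L])
  n_t3h <- sum(tracks$presence[, tpn])
  n_gain <- sum(ev$n_gain)
  n_lost <- sum(ev$n_lost)
  rates <- suppressWarnings(intervalRates(tracks))
  tov <- if (n_t0 + n_t3h > 0) 100 * (n_gain + n_lost) / (n_t0 + n_t3h)
         else NA_real_
  out <- data.frame(roi_id = roiId, n_t0 = n_t0, n_t3h = n_t3h,
                    n_gain = n_gain, n_lost = n_lost, turnover_pct = tov,
                    gain_pct_per_30min = rates$gain_pct_per_interval,
                    loss_pct_per_30min = rates$loss_pct_per_interval)
  sf <- suppressWarnings(survivalFraction(tracks))
  names(sf) <- (seq_len(tpn) - 1L) * tracks$intervalMin
  attr(out, "sf") <- sf
  out
}

# --- robustness and recovery harnesses --------------------------------------

# full register -> filter -> detect -> track -> summarize run on a series
runPipelineOnSeries <- function(series, thresholdMultiplier = 1,
                                maxDisplacementUm = 0.5, minVoxels = 4L,
                                radiusPx = 2L, roiId = "roi1") {
  drift <- estimateDrift(series)
  corrected <- applyCorrection(series, drift)
  filtered <- medianFilterSeries(corrected, radiusPx = radiusPx,
                                 channels = 1L)
  det <- detectSeries(filtered, thresholdMultiplier = thresholdMultiplier,
                      minVoxels = minVoxels)
  tracks <- filterTransients(
    linkDetections(det, maxDisplacementUm = maxDisplacementUm,
                   nTimepoints = nTimepoints(series),
                   intervalMin = diff(timepointsMin(series))[1L]))
  list(drift = drift, detections = det, tracks = tracks,
       summary = summarizeTurnover(tracks, roiId = roiId))
}

#' Threshold-robustness re-analysis
#'
#' Runs the full detect-track-summarize pipeline on the same registered
#' series at the standard threshold and at a twofold lower threshold
#' (multipliers 1.0 and 0.5), pairs the resulting tracks between the two
#' runs by centroid proximity, and compares their gain/loss event
#' timepoints. Punctum dynamics largely independent of the detection
#' threshold show near-complete event agreement.
#'
#' @param series a [TimeSeriesVolume-class] (unregistered; registration is
#'   part of the run).
#' @param multipliers the two threshold multipliers (default `c(1, 0.5)`).
#' @param maxDisplacementUm track gating and pairing radius (default 0.5).
#' @param minVoxels minimum component size for detection.
#' @return A list: `summary_high`, `summary_low` (turnover summaries at each
#'   threshold), `n_paired` (tracks matched between runs), `n_event_agree`,
#'   `n_event_disagree` (paired tracks with identical vs differing
#'   birth/death timepoints), `agreement_rate`.
#' @export
thresholdRobustness <- function(series, multipliers = c(1, 0.5),
                                maxDisplacementUm = 0.5, minVoxels = 4L) {
  stopifnot(is(series, "TimeSeriesVolume"), length(multipliers) == 2L)
  runA <- runPipelineOnSeries(series, thresholdMultiplier = multipliers[1L],
                              maxDisplacementUm = maxDisplacementUm,
                              minVoxels = minVoxels)
  runB <- runPipelineOnSeries(series, thresholdMultiplier = multipliers[2L],
                              maxDisplacementUm = maxDisplacementUm,
                              minVoxels = minVoxels)
  trA <- runA$tracks; trB <- runB$tracks
  if (nrow(trA$tracks) == 0L || nrow(trB$tracks) == 0L) {
    return(list(summary_high = runA$summary, summary_low = runB$summary,
                n_paired = 0L, n_event_agree = 0L, n_event_disagree = 0L,
                agreement_rate = NA_real_))
  }
  centroidOf <- function(tr, id) {
    d <- tr$detections[tr$detections$track_id == id, ]
    colMeans(d[, c("x_um", "y_um", "z_um")])
  }
  ca <- t(vapply(trA$tracks$track_id, function(id) centroidOf(trA, id),
                 numeric(3)))
  cb <- t(vapply(trB$tracks$track_id, function(id) centroidOf(trB, id),
                 numeric(3)))
  agree <- 0L; disagree <- 0L; paired <- 0L
  usedB <- rep(FALSE, nrow(cb))
  for (i in seq_len(nrow(ca))) {
    d <- sqrt(colSums((t(cb) - ca[i, ])^2))
    d[usedB] <- Inf
    j <- which.min(d)
    if (d[j] <= maxDisplacementUm) {
      usedB[j] <- TRUE
      paired <- paired + 1L
      same <- trA$tracks$birth_tp[i] == trB$tracks$birth_tp[j] &&
              trA$tracks$death_tp[i] == trB$tracks$death_tp[j]
      if (same) agree <- agree + 1L else disagree <- disagree + 1L
    }
  }
  list(summary_high = runA$summary, summary_low = runB$summary,
       n_paired = paired, n_event_agree = agree,
       n_event_disagree = disagree,
       agreement_rate = if (paired > 0) agree / paired else NA_real_)
}

#' End-to-end parameter-recovery experiment
#'
#' For each replicate, generates a synthetic session, runs the full
#' register-filter-detect-track-summarize pipeline, and compares the
#' estimated turnover statistics against the imaging-free event-simulation
#' oracle [expectedSessionCounts()]. This is the package's acceptance
#' harness: an unbiased pipeline recovers the oracle's expected turnover
#' within Monte-Carlo error.
#'
#' @param config a [SimConfig-class]; each replicate uses `rngSeed + r`.
#' @param nReps number of pipeline replicates (>= 10).
#' @param oracleReps event-simulation replicates for the oracle
#'   (default 500).
#' @param thresholdMultiplier detection threshold multiplier.
#' @return A list: `estimates` (data.frame of per-replicate summaries),
#'   `estimate_mean`, `estimate_se` (turnover), `oracle_mean`, `oracle_se`,
#'   `bias` (estimate - oracle) and `bias_z` (bias over its combined s.e.).
#' @export
recoveryExperiment <- function(config, nReps = 20L, oracleReps = 500L,
                               thresholdMultiplier = 1) {
  stopifnot(is(config, "SimConfig"))
  if (nReps < 10L) stop("nReps must be >= 10")
  est <- lapply(seq_len(nReps), function(r) {
    cfg <- config
    cfg@rngSeed <- config@rngSeed + r
    ss <- generateSeries(cfg)
    run <- runPipelineOnSeries(imageSeries(ss),
                               thresholdMultiplier = thresholdMultiplier)
    run$summary
  })
  est <- do.call(rbind, est)
  oracle <- expectedSessionCounts(config, nReps = oracleReps,
                                  seed = config@rngSeed + 999983L)
  em <- mean(est$turnover_pct, na.rm = TRUE)
  ese <- sd(est$turnover_pct, na.rm = TRUE) / sqrt(sum(!is.na(est$turnover_pct)))
  om <- oracle$mean[["turnover_pct"]]
  ose <- oracle$se[["turnover_pct"]]
  list(estimates = est,
       estimate_mean = em, estimate_se = ese,
       oracle_mean = om, oracle_se = ose,
       bias = em - om, bias_z = (em - om) / sqrt(ese^2 + ose^2))
}

#' Group comparisons of turnover summaries
#'
#' Conventional reporting statistics over per-ROI turnover summaries:
#' unpaired or paired two-sample t-tests and two-way ANOVA on a chosen
#' response column.
#'
#' @param summaries data.frame of stacked [summarizeTurnover()] rows plus
#'   design columns.
#' @param response name of the response column (default `"turnover_pct"`).
#' @param group name of the grouping column for the t-test.
#' @param group2 optional second factor; when given, a two-way ANOVA
#'   `response ~ group * group2` is run instead.
#' @param paired logical, paired t-test (rows must be aligned).
#' @return For the t-test: the `htest` object. For the ANOVA: the `aov`
#'   summary.
#' @export
groupTests <- function(summaries, response = "turnover_pct",
                       group, group2 = NULL, paired = FALSE) {
  if (!response %in% names(summaries)) stop("unknown response column")
  if (!group %in% names(summaries)) stop("unknown group column")
  y <- summaries[[response]]
  g <- factor(summaries[[group]])
  if (nlevels(g) < 2L || min(table(g)) < 2L)
    stop("need >= 2 groups with >= 2 observations each")
  if (is.null(group2)) {
    t.test(y[g == levels(g)[1L]], y[g == levels(g)[2L]], paired = paired)
  } else {
    g2 <- factor(summaries[[group2]])
    if (nlevels(g2) < 2L) stop("second factor needs >= 2 levels")
    summary(aov(y ~ g * g2))
  }
}
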