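# --- multi-unit activity ------------------------------------------------------

#' Zero-phase Butterworth high-pass filter
#'
#' 4th-order Butterworth high-pass applied forward and backward
#' (zero-phase), isolating multi-unit spiking from slow field potentials.
#'
#' @param x numeric voltage trace.
#' @param samplingRate sampling rate in Hz.
#' @param cutoff high-pass cutoff in Hz (default 500).
#' @param order filter order (default 4).
#' @return The filtered trace (same length).
#' @examples
#' fs <- 20000
#' t <- seq(0, 0.5, by = 1 / fs)
#' x <- sin(2 * pi * 50 * t) + 0.1 * sin(2 * pi * 2000 * t)
#' y <- highpassFilter(x, fs)   # 50 Hz component removed
#' @export
highpassFilter <- function(x, samplingRate, cutoff = 500, order = 4L) {
  if (samplingRate <= 2 * cutoff)
    stop("cutoff must be below the Nyquist frequency (samplingRate / 2)")
  bf <- signal::butter(order, W = cutoff / (samplingRate / 2),
                       type = "high")
  as.numeric(signal::filtfilt(bf, x))
}

# robust noise RMS: median absolute deviation of the trace scaled to the
# Gaussian sigma, insensitive to the spikes themselves; `raw` uses the plain
# root-mean-square
noiseRMS <- function(x, method = c("robust", "raw")) {
  method <- match.arg(method)
  if (method == "robust") median(abs(x)) / 0.6745 else sqrt(mean(x^2))
}

#' Threshold-based multi-unit spike detection
#'
#' Detects spikes as excursions of the (high-pass filtered) trace beyond
#' `k` times the noise RMS (default 5), using an absolute-value threshold so
#' both polarities are caught. Each contiguous supra-threshold excursion
#' yields one spike timed at its absolute peak; events closer than the
#' refractory period to the previous spike are discarded. The noise RMS is
#' estimated robustly over the whole trace as `median(|x|) / 0.6745` so the
#' spikes themselves do not inflate the threshold (`rmsMethod = "raw"` gives
#' the plain RMS).
#'
#' @param x numeric filtered voltage trace.
#' @param samplingRate sampling rate in Hz.
#' @param k threshold multiple of the noise RMS (default 5).
#' @param refractoryMs minimum spike separation in milliseconds (default 1).
#' @param rmsMethod `"robust"` (default) or `"raw"`.
#' @return Numeric vector of spike times in seconds (0 = first sample); the
#'   threshold used is attached as `attr(, "threshold")`. A silent trace
#'   (zero RMS) yields no spikes with a warning.
#' @export
detectSpikes <- function(x, samplingRate, k = 5, refractoryMs = 1,
                         rmsMethod = c("robust", "raw")) {
  rmsMethod <- match.arg(rmsMethod)
  sigma <- noiseRMS(x, rmsMethod)
  if (sigma == 0) {
    warning("trace has zero noise RMS; no spikes detected")
    out <- numeric(0)
    attr(out, "threshold") <- 0
    return(out)
  }
  thr <- k * sigma
  supra <- abs(x) > thr
  if (!any(supra)) {
    out <- numeric(0)
    attr(out, "threshold") <- thr
    return(out)
  }
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  peaks <- vapply(runs, function(i) {
    seg <- starts[i]:ends[i]
    seg[which.max(abs(x[seg]))]
  }, integer(1))
  times <- (peaks - 1L) / samplingRate
  refr <- refractoryMs / 1000
  keep <- logical(length(times))
  last <- -Inf
  for (i in seq_along(times)) {
    if (times[i] - last >= refr) {
      keep[i] <- TRUE
      last <- times[i]
    }
  }
  out <- times[keep]
  attr(out, "threshold") <- thr
  out
}

# per-trial spike counts in a half-open window [a, b)
countInWindow <- function(trials, w) {
  vapply(trials, function(s) sum(s >= w[1L] & s < w[2L]), numeric(1))
}

#' Evoked change in firing rate (delta FR)
#'
#' Per trial, the number of spikes in the baseline window immediately before
#' the stimulus is subtracted from the number during the stimulus window and
#' converted to Hz by dividing by the window duration.
#'
#' @param trials a [SpikeTrialSet-class].
#' @return A list: `delta_fr` (Hz per trial), `mean_delta_fr`,
#'   `stim_rate_hz`, `baseline_rate_hz` (per-trial rates).
#' @examples
#' ts <- SpikeTrialSet(list(c(0.1, 0.5, 3.2, 3.4, 4.9)))
#' deltaFR(ts)$mean_delta_fr   # (3 - 2) / 3 Hz
#' @export
deltaFR <- function(trials) {
  stopifnot(is(trials, "SpikeTrialSet"))
  durS <- diff(trials@stimWindow)
  durB <- diff(trials@baselineWindow)
  nS <- countInWindow(trials@trials, trials@stimWindow)
  nB <- countInWindow(trials@trials, trials@baselineWindow)
  dfr <- nS / durS - nB / durB
  list(delta_fr = dfr, mean_delta_fr = mean(dfr),
       stim_rate_hz = nS / durS, baseline_rate_hz = nB / durB)
}

#' Significance of an evoked firing-rate change
#'
#' Unpaired two-tailed t-test of the per-trial stimulus-window firing rates
#' against the per-trial baseline-window rates, declared significant at
#' `alpha / m` -- Bonferroni correction over the `m` stimulus conditions
#' tested per recording (default `m = 8`, per-comparison level 0.00625).
#'
#' @param trials a [SpikeTrialSet-class] with at least 2 trials.
#' @param m number of stimulus conditions corrected for (default 8).
#' @param alpha family-wise level (default 0.05).
#' @return A list: `mean_delta_fr`, `p_value`, `alpha_corrected`,
#'   `significant`, `reason` (non-`NA` when degenerate, e.g. zero variance).
#' @export
frSignificance <- function(trials, m = 8L, alpha = 0.05) {
  stopifnot(is(trials, "SpikeTrialSet"))
  if (nTrials(trials) < 2L) stop("need at least 2 trials")
  d <- deltaFR(trials)
  aCorr <- alpha / m
  if (sd(d$stim_rate_hz) == 0 && sd(d$baseline_rate_hz) == 0) {
    return(list(mean_delta_fr = d$mean_delta_fr, p_value = NA_real_,
                alpha_corrected = aCorr, significant = FALSE,
                reason = "zero variance in both windows; t-test undefined"))
  }
  tt <- t.test(d$stim_rate_hz, d$baseline_rate_hz,
               alternative = "two.sided", paired = FALSE)
  list(mean_delta_fr = d$mean_delta_fr, p_value = tt$p.value,
       alpha_corrected = aCorr,
       significant = isTRUE(tt$p.value < aCorr), reason = NA_character_)
}

#' Peri-stimulus time histogram
#'
#' Spike counts in fixed-width bins aligned to stimulus onset, summed over
#' trials, with half-open bins `[a, b)`.
#'
#' @param trials a [SpikeTrialSet-class].
#' @param binWidthS bin width in seconds (default 0.020).
#' @param windowS numeric length-2 window relative to stimulus onset
#'   (default the baseline plus the stimulus window).
#' @return A data.frame: `bin_start_s`, `bin_end_s` (onset-relative),
#'   `count`; the per-trial raster (data.frame `trial`, `time_s`) is
#'   attached as `attr(, "raster")`.
#' @export
psth <- function(trials, binWidthS = 0.020, windowS = NULL) {
  stopifnot(is(trials, "SpikeTrialSet"), binWidthS > 0)
  onset <- trials@stimWindow[1L]
  if (is.null(windowS))
    windowS <- c(trials@baselineWindow[1L], trials@stimWindow[2L]) - onset
  edges <- seq(windowS[1L], windowS[2L] + binWidthS * 1e-9, by = binWidthS)
  if (edges[length(edges)] < windowS[2L])
    edges <- c(edges, edges[length(edges)] + binWidthS)
  rel <- unlist(lapply(trials@trials, function(s) s - onset))
  rel <- rel[rel >= edges[1L] & rel < edges[length(edges)]]
  counts <- tabulate(findInterval(rel, edges), length(edges) - 1L)
  raster <- do.call(rbind, lapply(seq_along(trials@trials), function(i) {
    s <- trials@trials[[i]] - onset
    if (length(s) == 0) NULL else data.frame(trial = i, time_s = s)
  }))
  out <- data.frame(bin_start_s = edges[-length(edges)],
                    bin_end_s = edges[-1L], count = counts)
  attr(out, "raster") <- raster
  out
}
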