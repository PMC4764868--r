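# punctaTurnover

Detection, tracking and turnover statistics for presynaptic puncta in
two-photon time-lapse volumes.

Repeatedly imaging the same fluorescently labelled axons reveals that
presynaptic terminals (puncta) are gained and lost over hours. Turning raw
3D+time stacks into a defensible turnover percentage takes a chain of
fragile steps — drift correction, spot detection near the noise floor,
punctum identity tracking across sessions, transport-packet exclusion — and
an error in any one of them biases the biology. This package implements the
full chain and validates it end to end: a synthetic-data generator with
exact ground truth lets every stage be tested by parameter recovery instead
of by eye.

## What it computes

For a session of 7 stacks at 30-minute intervals, with counts `n_t0`
(first timepoint), `n_t3h` (last), `n_gain` and `n_lost` (every
appearance/disappearance transition):

```
turnover %      = 100 * (n_gain + n_lost) / (n_t0 + n_t3h)
conservation    : n_t3h = n_t0 + n_gain - n_lost   (holds exactly)
survival        : SF_t = n_t / n_0h on the t0 cohort, SF_0 = 1
evoked rate     : deltaFR = (stim spikes - baseline spikes) / 3 s,
                  tested at alpha/m = 0.05/8 = 0.00625
```

Pipeline stages: phase-correlation drift correction against a cytosolic
reference channel; Fiji-semantics circular median filtering; 3-scale
*a trous* B3-spline wavelet spot detection with universal hard thresholds
and 26-connected labeling; mutual-nearest-neighbour tracking gated at
0.5 um with a two-consecutive-timepoint transient filter; turnover, per-
interval rates, survival fractions and group tests. Side modules cover
line-profile colocalization (Pearson, exact permutation p for short
profiles, peak apposition), Otsu-based pixel colocalization and glomerular
occupancy, and multi-unit spike statistics (500 Hz zero-phase high-pass,
5x robust-RMS spike detection, PSTH, Bonferroni-corrected rate tests).

## Worked example

Simulate a high-turnover ("immature") session with known ground truth, run
the full pipeline, and summarize:

```r
library(punctaTurnover)

cfg <- exampleSessionConfig("immature", rngSeed = 42L)
ss  <- generateSeries(cfg)      # SyntheticSeries: images + ground truth
s   <- imageSeries(ss)
s
#> TimeSeriesVolume: 96 x 96 x 14 voxels, 2 channel(s), 7 timepoint(s)
#>   voxel size (um): 0.12 x 0.12 x 1
#>   timepoints (min): 0, 30, 60, 90, 120, 150, 180
#>   channels: puncta, reference

drift <- estimateDrift(s)       # phase correlation vs timepoint 1
head(drift, 3)
#>   timepoint dx dy dz      score
#> 1         1  0  0  0         NA
#> 2         2 -2  1  1 0.06394007
#> 3         3  3 -3  0 0.06495188

s   <- applyCorrection(s, drift)
s   <- medianFilterSeries(s, channels = "puncta")
det <- detectSeries(s)          # wavelet spot detection per timepoint
tr  <- filterTransients(linkDetections(det, nTimepoints = nTimepoints(s)))
tr
#> punctaTracks: 25 track(s) over 7 timepoints ( 30 min interval )
#>   present at t0: 20 ; at final timepoint: 16

sm <- summarizeTurnover(tr)
sm
#>   roi_id n_t0 n_t3h n_gain n_lost turnover_pct gain_pct_per_30min
#> 1   roi1   20    16      5      9     38.88889           4.751984
#>   loss_pct_per_30min
#> 1           7.945732

attr(sm, "sf")                  # survival fraction of the t0 cohort
#>    0   30   60   90  120  150  180
#> 1.00 1.00 0.90 0.85 0.70 0.65 0.55
```

For this seed the recovered counts (20, 16, 5 gains, 9 losses) equal the
generator's ground truth exactly. `recoveryExperiment(cfg)` repeats this
over 20 replicates and checks the mean turnover against the imaging-free
event-process oracle `expectedSessionCounts(cfg)`; both shipped regimes
(`"immature"` ~25% and `"mature"` ~11% expected turnover) recover without
detectable bias.

A YAML-configured one-shot run (`runAll()`, or
`Rscript inst/scripts/puncta_pipeline.R run-all --out results --seed 1`)
writes truth/drift/detections/tracks/summary CSVs plus a manifest with
checksums.

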