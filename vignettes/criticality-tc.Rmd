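---
title: "Temporal correlations, criticality, and cognition-linked iEEG analysis with criticalTC"
author: "criticalTC authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal correlations, criticality, and cognition-linked iEEG analysis with criticalTC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(criticalTC)
```

## The scientific problem

Cortical networks are hypothesised to operate near a critical point — the
phase transition between activity that dies out (subcritical) and activity
that grows without bound (supercritical) — because several
information-processing quantities are simultaneously maximised there. A
practical, recording-based proxy for proximity to criticality is the
*temporal correlation* (TC): the half-decay time of the autocorrelation of
high-γ (56–96 Hz) band power, which tracks local population firing. Long
TCs indicate reverberating, near-critical dynamics; short TCs indicate
either quickly dissipating (subcritical) or saturated/chaotic
(supercritical) dynamics.

`criticalTC` provides the full analysis chain around this statistic:

1. a branching-style probabilistic network model in which distance to
   criticality is tuned by one parameter (the spectral radius λ of the
   synaptic weight matrix) and which has built-in mechanisms emulating
   sleep-like off-periods, interictal spike events, and
   excitability-reducing medication;
2. the TC estimator for multichannel recordings (preprocessing, 125 ms
   log high-γ power bins, windowed autocorrelations, the half-decay rule,
   shuffled surrogates, window subsampling, and a DFA/Hurst cross-check);
3. state annotation (slow-wave detection via a vigilance index, spike-rate
   binning, medication-day classification);
4. nonparametric inference (paired Wilcoxon, Brunner–Munzel with relative
   effects, Benjamini–Hochberg correction, Kolmogorov–Smirnov uniformity
   checks of p-value families);
5. a seeded synthetic-data generator with known ground truth, so every
   stage is testable without access to restricted clinical recordings.

## The network model

`N` neurons sit on an `L × L` grid with periodic boundary conditions
(`N = L²`). Every ordered pair is connected with weight
`w[i, j] = u[i, j] · exp(−r²/(2σ²))`, where `u` is uniform on `[0, 1)`,
`r` the torus Euclidean distance, and `σ = 4` grid units. A uniformly
random 20 % of neurons are inhibitory: their outgoing rows are negated
(for `N = 1024` that is `round(0.2·1024) = 205` neurons; for the reduced
`N = 256` used in the sweep suites, 51). Self-connections are removed.
Finally the whole matrix is rescaled by one scalar so its spectral radius
(largest eigenvalue modulus — eigenvalues may be complex for the signed
matrix) equals the control parameter λ, to within 1 × 10⁻⁶ relative
tolerance.

A neuron is active (`s = 1`) or inactive; its activation probability at
`t + 1` is its weighted input sum at `t`, clipped to `[0, 1]` — negative
input sums therefore silence deterministically, implementing inhibition
through the clipped-probability rule itself. One uniformly chosen neuron
per step is forced active as background drive. Runs last 5 000 steps, the
first 500 are discarded as transient.

Three perturbations are available:

* **Medication (`fExc`)** — outgoing weights of every excitatory neuron
  are multiplied by a factor `fExc ≤ 1` *after* λ-rescaling, so the
  perturbation measurably moves the effective spectral radius. That is the
  point: re-normalising afterwards would undo the mechanism.
* **Sleep-like off-steps (`pOff`)** — with per-step probability `pOff` the
  entire network, including the background drive and any spike event of
  that step, is silenced. The off-step is applied last within a step;
  otherwise `pOff = 1` would not produce quiescence. Off-steps are
  single-step events; multi-step off-period durations are a documented
  simplification.
* **Spike events (`pIed`)** — with per-step probability `pIed` a random
  centre neuron plus its nearest `⌈0.2·N⌉ − 1` neighbours by torus
  distance (ties broken by neuron index) are forced active after the
  stochastic update.

The model TC is the half-decay time of the sample autocorrelation of the
post-transient population activity, computed to a maximum lag of 500
steps. The baseline is the median ACF over the last fifth of computed
lags — the model analogue of the 40–60 s tail used for recordings, which
is not separately prescribed for the model; this is our choice and it is
held fixed everywhere. Constant post-transient activity (a fully
saturated supercritical run, or complete quiescence) has no decay to
measure: `populationTc()` raises an undefined-TC error, and λ sweeps
record such runs at the one-step floor, the model clock's analogue of
the 0.125 s data floor.

The per-step update is implemented in C++ (an `Rcpp` kernel using R's own
RNG, so simulations are bit-reproducible under `set.seed()`): sweeps of
hundreds of 5 000-step runs are interactive rather than hours-long.

```{r model-example}
cfg <- modelConfig(nNeurons = 64L, gridSide = 8L, lambdaTarget = 1,
                   nSteps = 1000L, transient = 200L)
w <- buildNetwork(cfg, seed = 1)
spectralRadius(networkWeights(w))
tr <- simulateActivity(cfg, perturbationConfig(), w, seed = 2)
orderParameter(tr)
```

## The TC statistic for recordings

Preprocessing mirrors standard iEEG conditioning: 50/100 Hz band-stop
notches; anti-alias filtering and decimation to the common 256 Hz rate;
a 0.1 Hz high-pass (the nominal 128 Hz upper band edge equals the Nyquist
frequency at 256 Hz, so the low-pass side is realised by the decimation
filter); rejection of constant channels and channels with abnormal
narrow-band spectral peaks; and masking of seizure intervals expanded by
±600 s.

The channel screen deserves a note. The quality rule "a spectral value
more than six IQRs above the third quartile" cannot be applied to raw
Welch spectra of physiological signals: a 1/f background *always* places
its low-frequency bins far above `Q3 + 6·IQR` of the full spectral value
distribution, which would reject every channel. We therefore detrend the
log₁₀ spectrum with a running median (21 bins of 0.5 Hz) and apply the
`Q3 + 6·IQR` rule to the residuals, restricted to frequencies ≥ 2 Hz and
excluding the half-window edges where the background estimate is
one-sided. A smooth continuum passes; narrow peaks (line-noise residues,
oscillatory artifacts) are flagged. This is an interpretation of the
quality rule, configurable via `peakIqrFactor`.

Power extraction: per channel, non-overlapping 125 ms windows (32 samples
at 256 Hz) are Hann-tapered and turned into single-segment periodograms —
at 8 Hz frequency resolution there is no room for Welch sub-segmentation
within a window, so a single tapered periodogram is the Welch estimate.
The median power over the frequency bins inside 56–96 Hz is
log₁₀-transformed, giving 8 bins per second. Degenerate (zero-variance)
windows and bins overlapping masked time become invalid bins, never
`-Inf`; any 120 s window containing an invalid bin is excluded whole
rather than interpolated.

Autocorrelation: per channel, 120 s windows are placed every 30 s (90 s
overlap). The biased (divide-by-n) sample ACF of the mean-subtracted bin
series is computed at lags 0.125–60 s; the biased estimator is stable at
long lags. Lag 0 is excluded throughout — it is 1 by definition and
independent of data quality, and including it would distort the decay.
ACFs are aggregated across windows by the element-wise median, and:

* baseline = median of the aggregated ACF over the 40–60 s lag band;
* threshold = baseline + (ACF(0.125 s) − baseline)/2;
* TC = (first lag ≥ 2 bins below threshold − 1) × 0.125 s.

Measuring the width from the lag-1 peak makes the smallest attainable
value exactly one bin, 0.125 s; a first-crossing convention could not
produce that floor. If the lag-1 value does not exceed the baseline the
floor is returned and flagged degenerate. A capped value of 60 s is
defined for an ACF that never crosses, but with the baseline lying inside
the computed lag range the aggregated ACF always reaches values at or
below the baseline — and hence below the threshold — within the baseline
band, so the cap is a numerical safety net rather than a reachable
outcome; group statistics use returned values as-is.

One property of the crossing rule worth knowing: it is scale-free, so for
a temporally uncorrelated (e.g. time-shuffled) series the returned value
is the 0.125 s floor *with high probability* (about 0.8), occasionally
one or two bins more, regardless of how many windows are aggregated. The
median over a handful of shuffled series is the floor essentially always;
tests and the acceptance script use that median.

Surrogates permute the valid power bins in time, preserving the power
distribution while destroying temporal structure. When two states
contribute unequal window counts, `subsampleCompare()` subsamples the
majority to the minority size without replacement, 100 times, and
averages. `dfaHurst()` provides the standard DFA-1 exponent as an
independent long-range-correlation cross-check.

## State annotation

Slow-wave periods are scored on 30 s windows through the vigilance index
(θ + δ)/(α + β_high + spindle), with a window labelled slow-wave when its
index exceeds that day's mean plus one population SD — per-day
thresholds make the labels invariant to amplitude rescaling. The spindle
(11–16 Hz) and high-β (20–30 Hz) edges are not uniquely standardised; both
are configurable in `vigilanceBandScheme()`. A 120 s analysis window is
slow-wave if any of its four 30 s constituents is.

Spike-rate binning contrasts event-free windows with windows at 5–30
events/min; rates in (0, 5) or above 30 are excluded from the contrast,
and a channel is retained only with at least 50 windows in *each*
category. Medication days are classified by DDD-normalised summed dose;
days with rescue medication (midazolam, diazepam, lorazepam) are removed;
the highest and lowest remaining days are the contrast, ties resolving to
the earliest day; subjects whose eligible days all carry equal load show
no tapering and are excluded.

## Inference

Within-subject state contrasts use the paired Wilcoxon signed-rank test.
Across-subject cognition contrasts use the Brunner–Munzel test, chosen
because TC distributions are non-normal and heteroscedastic; the relative
effect P(X<Y) + ½P(X=Y) is estimated from midranks (computed from exact
rank sums, so it equals the O(n²) pairwise count bitwise), and p-values
use the t-approximation with Satterthwaite-type degrees of freedom, with
an exact permutation variant for groups of at most 10. Cognitive domains
are impaired when at least two tests in the domain score ≥ 1 SD below the
norm mean (boundary inclusive). The comparison grid tests every (feature,
sampling context, domain) cell with at least 5 subjects per group,
corrects with Benjamini–Hochberg across the whole grid as one family, and
checks each feature's p-value set against Uniform(0, 1) with a one-sided
KS test. The 5-per-group minimum is our definition of "insufficient
sample size"; cells below it stay empty.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes —
not the physiology. Per channel, a log-AR(1) envelope at the 8 Hz bin
clock with lag-1 coefficient `exp(−0.125/τ)` (so the ground-truth
correlation time τ lives on the same clock as the estimator) multiplies a
band-limited 55–100 Hz Gaussian carrier on a 1/f background. Slow-wave
epochs add 0.5–4 Hz noise at a stated dB boost over the background's δ
power; spike events insert a fixed 70 ms sharp transient plus 300 ms slow
half-wave template (detectability by rate-binning, not morphological
realism, is the goal); optional 50/100 Hz sinusoids exercise the notch.
All draws are seeded; ground truth is emitted alongside every signal.

The cohort generator draws per-subject latent correlation times from a
lognormal (median 0.5 s, log-SD 0.5 — matching the sub-second group
means reported for this kind of recording), schedules a tapered
maintenance drug across three days (day 1 highest load, day 2 lowest, day
3 intermediate, so "first", "low-ASM" and "last" contexts are distinct
days), shortens each day's correlation time by `asmFactor^loadNorm`
(default factor 0.7 on the highest-load day), covers 18 % of each day
with +10 dB slow-wave epochs, injects spikes at 6/min (inside the 5–30
contrast bin), and draws cognitive scores so that the probability of
domain impairment follows a logistic link in −log(τ) (slope 2.5, midpoint
at τ = 0.5 s, giving ~45 % impairment rates). Setting the slope to zero
decouples cognition from dynamics and is the null configuration.

What the generator does *not* emulate: physiological sleep architecture,
seizures, volume conduction, electrode geometry, non-stationary artifacts
beyond line noise, or realistic spike waveform diversity. Passing tests
therefore demonstrate that the pipeline recovers the statistical
structure it is designed for, not that it is robust to every failure mode
of clinical recordings.

## Study conditions and problem sizes

The validation suites run at desk scale, chosen once: simulator sweeps
use N = 256 neurons with 50 repetitions per grid point (100 for the
supercritical non-monotonicity check, which contrasts two conditions
only); estimator-recovery and annotation checks use 300 s single-channel
signals over 20 seeds; the end-to-end cohort uses 80 subjects × 3 day
contexts × 20 seeds. The λ grid is {0.80, 0.85, …, 1.20}.

## Numerical choices

* ACF estimation is FFT-based and identical to `stats::acf(demean =
  TRUE)`; windows are processed in batch per channel.
* Column medians over small numbers of rows (band bins, ACF windows) use
  a vectorised odd-even sorting network rather than per-column `apply()`.
* The decimation path requires the input rate to be an integer multiple
  of 256 Hz (the rates this kind of monitoring produces: 256–2048 Hz);
  other rates error rather than silently resample.
* EDF export quantises to 16 bits per channel over that channel's
  observed range; round-trips are exact to one quantisation step. The
  EDF codec is minimal (common rate across channels, 1 s records) and
  written in-package because no R-side EDF reader is available here.
* Seeds: every stochastic stage takes an explicit seed and derives
  per-unit seeds deterministically (affine maps kept below 2³¹);
  pipelines re-run byte-identically.

## Known limitations

* TC values are quantised to 0.125 s; short correlation times (τ below
  ~0.3 s) therefore resolve coarsely, and group contrasts at the floor
  rely on ties handled by the midrank machinery.
* The Brunner–Munzel t-approximation is slightly anti-conservative below
  ~10 subjects per group; the permutation variant exists for that regime.
* The comparison grid's KS uniformity check treats cell p-values as a
  sample; cells sharing subjects are dependent, so the check is a
  discovery heuristic (as in the original analysis design), not a
  calibrated test.
* The vigilance-index band edges for spindle and high-β activity are
  conventions, not fits; changing them shifts absolute index values but
  the per-day mean + 1 SD threshold absorbs monotone changes.
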