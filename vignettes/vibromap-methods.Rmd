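---
title: "Methods: synthetic vibrotactile ECoG and cluster permutation mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic vibrotactile ECoG and cluster permutation mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

vibromap maps individual finger representations on sensorimotor cortex
from electrocorticographic (ECoG) recordings during vibrotactile
stimulation of single fingertips. Because raw clinical recordings of
this kind cannot be redistributed, the package pairs the analysis chain
with a synthetic session generator that has full ground truth, so every
statistical claim the pipeline makes can be checked against what was
actually injected. This vignette documents the generative model, the
analysis chain, and the design decisions behind the permutation null —
including two null constructions we measured to be miscalibrated on
this data class and therefore do not use by default.

## The generative model

`generateSession(simConfig())` simulates one recording session:

- **Design.** Randomised single-finger 200 Hz vibration, 100–500 ms
  duration drawn uniformly, offset-to-onset inter-stimulation interval
  1–1.4 s, 10 trials per finger per set, sets alternating between the
  contralateral (CL) and ipsilateral (IL) hand when both are
  configured. An 8 x 8 subdural grid at 10 mm pitch is sampled at
  500 Hz.
- **Background.** Per-channel 1/f² noise synthesised in the frequency
  domain with an exact RMS of 20 µV. The inverse FFT is taken at a
  5-smooth padded length (`smoothLength()`), because R's mixed-radix
  FFT degrades to near-quadratic cost at prime lengths; padding to the
  next 2-3-5-smooth integer keeps generation O(n log n) without
  changing the spectrum model.
- **Evoked components.** Four Gaussian atoms per stimulus — N40
  (38 ms, −20 µV), P100 (108 ms, +15 µV), N140 (138 ms, −12 µV), P200
  (186 ms, +10 µV), 30 ms FWHM — the long-latency somatosensory
  sequence reported for this paradigm.
- **Mid-gamma ERS.** A 65–115 Hz band-limited burst, onset 30 ms after
  the stimulus, 150 ms long, 5 µV RMS, with 20 ms Hann ramps
  (event-related synchronisation).
- **Alpha/beta ERD.** The 8–30 Hz component of the background is
  attenuated by 50% between 150 and 600 ms (event-related
  desynchronisation).
- **Somatotopy.** All responses are injected at the five finger sites
  (a latero-medial line of electrodes, thumb first) with a Gaussian
  spatial falloff of σ = 8 mm, so neighbouring contacts at 10 mm see
  ~46% of the peak amplitude.
- **Nuisance options.** Shared 60 Hz line noise, random biphasic
  interictal transients, a constant stimulator latency offset, and a
  weak delayed ipsilateral response are all off by default but
  available for robustness experiments.

Everything is deterministic given `simConfig(seed = )`, and the
returned ground-truth manifest records the target electrode, actual
response windows and true site coordinates per event.

The generator is deliberately a *model*, not a forgery: real ECoG has
non-Gaussian, non-stationary background, correlated channels, and
broadband rather than band-limited gamma. Conclusions about absolute
sensitivity do not transfer to clinical data; conclusions about
*calibration* (false-positive control) and *consistency* (recovering
what was injected) do, which is what the studies below measure.

## The analysis chain

```{r}
library(vibromap)
ses <- generateSession(simConfig(nSets = 1, seed = 1))
res <- runPipeline(ses$recording, ses$events, ses$layout,
                   analysisConfig(), bands = "MidG")
```

1. **Epoching** around stimulus onsets (−600 to 1000 ms), optional
   per-grid common average reference, zero-phase FIR band-pass.
2. **Time domain:** 1–30 Hz, baseline correction, per-finger evoked
   averages and polarity-constrained peak detection in windows
   bracketing N40/P100/N140/P200, with a noise floor of 2 baseline
   standard deviations.
3. **Time–frequency:** Morlet wavelets (7 cycles, unit-peak Gaussian
   spectrum, 1 Hz spacing over 8–230 Hz excluding the 55–65 and
   115–125 Hz line-harmonic gaps), trial-wise power on a 20 ms grid,
   log-ratio baseline normalisation to dB against −150 to −10 ms.
4. **Statistics:** per (condition, band, finger), a one-sample t map
   over channel x frequency x time cells; cells with |t| above the
   two-sided alpha = 0.05 forming threshold are clustered under the
   6-neighbourhood (adjacent time bin, adjacent frequency bin,
   electrode graph within 10 mm); cluster mass is compared against a
   max-|mass| permutation null, giving family-wise-error-corrected
   p-values with the plus-one Monte Carlo estimator.
5. **Somatotopy:** each finger's primary significant mid-gamma ERS
   cluster is localised by the power-weighted centroid of its member
   electrodes; the finger map reports the latero-medial order score
   (Spearman correlation of finger index with the projected centroid)
   and map span.

## Choosing the permutation null

The classical null for a one-sample cluster test is the **sign-flip**:
under the symmetry hypothesis the per-trial normalized maps are sign-
symmetric, so flipping signs at random regenerates the null. On
log-power this hypothesis is false in a way that matters: baseline-
normalized log power is left-skewed (the log of an approximately
chi-square variate), so the null mean is zero but the distribution is
asymmetric, and the sign-flip t statistic acquires a positive bias of
roughly −γ₁/(2√n) per cell (γ₁ the skewness, ≈ +0.16 at n = 10
trials). Tiny per-cell bias, but a max-statistic over ~28,000 cells
harvests it: on 200 null sessions we measured a family-wise error rate
of **0.43** at nominal 0.05.

A **centered bootstrap-t** null (resampling trials with replacement and
studentising around the observed mean) removes the skew sensitivity but
over-disperses the null at these trial counts; measured FWER **0.00**
out of 200 — conservative, which costs sensitivity.

The default is therefore a **time-shift surrogate** null: for each
surrogate resample, every trial's analysis-plus-baseline window is slid
as a block by a random time offset within a wavelet-valid extended
time–frequency transform of the same trial, and re-normalized against
its shifted baseline. Under the null "no stimulus-locked spectral
modulation" the shifted maps are exchangeable with the observed one
regardless of the marginal skew, because each surrogate is itself a
genuine log-power map of the same process. `extendedTfrWindow()`
defines the admissible slide range: the analysis window padded 420 ms
backwards and 100 ms forwards, clipped so the slowest wavelet in the
band retains full support (no edge-contaminated bins enter any
surrogate). Measured FWER on 200 null sessions: **0.075**, inside the
acceptance band [0.02, 0.09]. All three methods are available via
`analysisConfig(nullMethod = )` and agree on strong effects; only
their null calibration differs.

## Common average reference

Per-grid CAR is implemented (`commonAverageReference()`) but **off by
default**. With a focal injected response on a 64-contact grid, CAR
subtracts 1/64 of the response from every contact, creating a weak
*negative* image of the response across the whole grid. On real data
CAR removes genuinely common artefacts (reference drift, line noise)
that the generator mostly lacks, so for the synthetic studies CAR only
bleeds signal; enable it when line noise or shared artefacts are
simulated or expected.

## Simulation studies

Three packaged studies quantify the pipeline against ground truth:

- `fwerCalibration()`: the null-world family-wise error rate described
  above.
- `fingerRecoveryStudy()`: on default-SNR sessions, whether each
  finger's primary significant ERS cluster contains the true
  electrode, the centroid error in mm, and per-session somatotopic
  order score and span. `somatotopyRecoveryStudy()` repeats this on a
  fine-pitch 4 mm grid (sites spanning 16 mm, the sub-2-cm regime);
  the grid is enlarged to 12 x 16 contacts there because a centroid is
  unbiased only when its spatial support is not truncated by the array
  edge.
- `erpRecoveryStudy()`: whether the four component latencies are
  recovered within ±6 ms at the true site.

## Limitations

- The generator's band-limited, fixed-latency responses are an
  idealisation; real high-gamma is broadband and latency-jittered.
- The time-shift null assumes within-epoch stationarity of the
  background; slow non-stationarities inside an epoch would widen it.
- Cluster-level inference licenses statements about clusters, not
  about individual cells; centroids are descriptive summaries.
- Onset estimates are limited by the 20 ms time grid and the temporal
  smearing of the 7-cycle wavelet.
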