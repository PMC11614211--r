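---
title: "Decoding stimulus periods from sEEG: methods and design notes"
author: "seegDecode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding stimulus periods from sEEG: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seegDecode)
```

## The analysis in one paragraph

`seegDecode` asks, contact by contact, whether a stereotactic-EEG channel
carries information that separates stimulus presentations from quiet
inter-trial periods. Each epoch is converted to a Morlet time-frequency
power grid with the band-passed voltage trace appended as one extra row;
the flattened grids are standardized, reduced to 50 principal components
fit on training folds only, and classified with a linear support vector
machine under stratified 6-fold cross-validation. Pooled held-out accuracy
is tested against an exact Binomial(n, 0.5) null. For significant contacts
the SVM weights are composed with the PCA basis back into time-frequency
space ("eigenspectrograms"), per-epoch signed contribution maps are formed,
and their structure is validated with a one-sample sign-flip cluster
permutation test. Contact results aggregate into region accuracy tables and
three group-level time-frequency maps (proportion significant,
directionality, classification value). A synthetic local-field-potential
generator with planted ground-truth effects makes the whole chain testable
without any patient data.

## Task model and the synthetic generator

The generator reproduces the delivery statistics of the numerical task:
each trial is a fixation cross jittered uniformly in 0.5-1.5 s, a 1 s
number stimulus in one of four modalities (Arabic numeral, dot assortment,
spoken number, beep sequence; quantities 1-9 uniform), and an inter-trial
period jittered uniformly in 1.5-3.5 s. Forty presentations of each
modality are delivered by default, randomly interleaved, with catch trials
added so they form 10% of the total; catch trials exist to model the
attention checks of the task and are excluded from every analysis stage.

Continuous data are synthesized per channel as 1/f^a noise (default a = 1,
20 uV RMS, optional mains line), built by spectral shaping of white
Gaussian noise. A planted effect multiplies the channel's exact (brick-wall
FFT) band component by a cosine-ramped gain (50 ms ramps) inside a window
around each matching stimulus onset - `magnitude` for increases,
`1/magnitude` for decreases - and can add a fixed biphasic evoked-potential
template. The manifest returned with every recording lists each planted
effect with the trials it touched, so downstream recovery can be scored
against ground truth.

What the generator does *not* emulate matters for interpreting green tests:
real sEEG has correlated noise across contacts, non-stationary background
power, epileptiform transients, imperfect event timing, and effects whose
band and latency drift across trials. Passing recovery tests therefore show
that the pipeline detects the kind of effect it is designed for at a
realistic SNR; they do not certify performance on clinical recordings.

## Preprocessing

Channels are common-average referenced (the standard sEEG montage for
high-frequency broadband sensitivity); the operation is idempotent and
leaves every time point with zero channel mean.

Epochs are (-1, +1) s for both conditions. Stimulus epochs align to
stimulus onset. Baseline (ITI) epochs require the alignment point to fall
at least 1.99 s after the preceding stimulus offset - the guard that lets
evoked activity return to baseline - with the window ending before the next
fixation onset; the window is centred in the eligible interval and gaps
shorter than `guard + 1` s yield no baseline epoch. Under the task's
jitter distribution only inter-trial periods of at least 2.99 s can host a
baseline, about a quarter of trials, so the balanced epoch set carries
roughly 40 + 40 epochs per recording - matching the observation count of
the binomial null. Classes are balanced by seeded uniform subsampling of
the larger class, which keeps chance level at exactly 0.5.

Trial rejection uses a single global peak-to-peak threshold chosen by
cross-validation: over a grid spanning the observed per-epoch maximum
peak-to-peak range, the threshold minimizes the CV-RMSE between the mean of
threshold-surviving training epochs and the median of validation epochs.
This is the global-threshold criterion of cross-validated artifact
rejection; channel-level repair is deliberately out of scope. After
rejection, classes are re-balanced the same way.

## Features

Defaults (all configurable through `tfrConfig()`):

* 50 log-spaced Morlet frequencies from 3 to 250 Hz. The lower bound is a
  consequence of the 2 s epoch: with at least 3 cycles per wavelet, a 1 or
  2 Hz wavelet's support (truncated at 2.5 SD) exceeds what symmetric edge
  cropping can accommodate, so 3 Hz is the lowest frequency whose features
  stay uncontaminated by epoch boundaries while keeping the theta band and
  the post-stimulus window representable.
* `n_cycles = freq / 2` (minimum 3), the usual resolution/variance
  compromise; with this choice the spectral SD is roughly 2 Hz across the
  grid.
* Temporal decimation by 25 (a 40 samples/s grid at 1000 Hz input), and
  symmetric cropping by the half-support of the longest wavelet, leaving
  about +/-0.6 s of usable time.
* Voltage row: zero-phase 4th-order Butterworth band-pass, 0.1-40 Hz,
  sampled on the same grid and appended as the final row, so evoked
  potentials reach the classifier alongside power.
* log10 power, then per-feature z-scoring fit on training epochs only.
  Without the log/z step, PCA is dominated by the 1/f low-frequency rows
  and the voltage row's incommensurate units.

`flattenGrid()`/`unflattenGrid()` are exact inverses, and scaling a signal
by c shifts every log-power feature by 2 log10(c) - both are tested
properties, not aspirations.

## Classification and significance

Within each stratified fold: standardization and PCA are fit on training
epochs only, the first 50 components (reduced with a warning when the
training set cannot support them) feed a linear SVM with C = 1 (no tuning
is part of the design), and held-out epochs are scored. Accuracy pools all
held-out predictions. Significance uses the exact binomial upper tail with
n fixed at the per-modality presentation count (40): when accuracy is
estimated on a different pooled test count it is rescaled to that n. This
follows the stated null of the study design; with ~94 pooled observations
rescaled to 40 the test is conservative for the pooled contrast and
slightly anticonservative for small per-format contrasts - a documented
trade-off, and the pooled-n alternative is available through `nullSpec()`.

The power statement is reproduced by `powerOneSampleT()`: the only tail
convention consistent with d = 0.4 and n = 40 giving 79.97% is a one-tailed
one-sample t-test at alpha = 0.05, and that is the default.

## Cluster statistics

The "one sample" observations are per-epoch signed contribution maps: the
held-out fold's coefficient grid multiplied element-wise by the epoch's
standardized feature grid, signed +1 for stimulus and -1 for ITI epochs.
This choice (rather than the 6 per-fold coefficient maps) is what makes an
alpha of 0.01 reachable: six observations admit only 64 sign flips. Summing
a map plus the class-signed intercept reproduces the epoch's SVM decision
value exactly; the identity is asserted to 1e-10 in the tests.

Per point, a one-sample t statistic against zero is thresholded at the
99th percentile of the central t distribution (df = n - 1); positive and
negative exceedances form separate 4-connected clusters whose mass is the
sum of t values. The appended voltage row participates as its own
connectivity domain - voltage and power are incommensurate, so a voltage
cell is never merged vertically into a power cluster. The null is the
maximum absolute cluster mass over 1000 seeded whole-observation sign
flips; a cluster is significant when its mass exceeds the 99th percentile
of those maxima. Because informative features contribute positively for
both classes by construction, contribution clusters over discriminative
regions are predominantly positive regardless of whether the underlying
power change is an increase or a decrease; directionality at the group
level reads the cluster mass sign.

## Group maps

Significant-contact counts are reported per format plus the intersection
across the four per-format contrasts. Region accuracy aggregates
significant contacts per anatomical label, by maximum by default (the
figure convention whose gradients start at the significance floor), with
the mean available. The three feature maps use all analyzed contacts as
the denominator of the proportion map; directionality and classification
value are masked wherever no significant cluster covers a point.

## Numerical choices and degenerate inputs

* Seeds: one master seed fans out through `childSeed()`, a string-keyed
  polynomial hash into the 32-bit range, giving each stage, contact and
  format an independent, reproducible stream; identical configurations
  reproduce every output file byte for byte.
* SVM orientation: the sign of the libsvm weight vector is fixed by
  checking agreement between decision values and predicted labels, so
  "positive decision" always means "stimulus".
* Constant features get unit scale during z-scoring; all-zero maps yield an
  empty cluster set; thresholds of +Inf keep every epoch; single-channel
  recordings refuse average referencing.
* Cluster p-values use the add-one permutation estimator, so they are never
  exactly zero.
* EDF export quantizes to 16-bit over each channel's observed range
  (resolution ~0.003 uV at typical amplitudes), far below the noise floor;
  header time fields are constants so exports are byte-deterministic.

## Validation scale

The test-suite and acceptance-script problem sizes are chosen to exercise
the full pipeline at the study's own design values while staying desk-sized:
null calibration runs 200 effect-free contacts (10 cohorts of 20) in the
test suite and 100 in the acceptance script; the family-wise-error check
uses 500 and 200 pure-noise map sets respectively at 1000 permutations
each; planted-effect recovery uses one 16-contact cohort with six
magnitude-3 effects - two high-frequency broadband increases (70-150 Hz),
two theta increases (4-8 Hz), one alpha increase (8-12 Hz) and one
alpha-beta desynchronization (8-25 Hz decrease). The battery mirrors the
spectral signatures the method is meant to detect: broadband gamma tracking
local spiking, low-frequency power changes in both directions. Narrow-band
*decreases* are intrinsically harder than increases in log-wavelet space -
out-of-band leakage through the wavelet's ~2 Hz spectral SD floors the
measurable change (a 9-fold in-band power drop in an 8-12 Hz band measures
as roughly a 2.5-fold drop at the 10 Hz wavelet) - which is why the
desynchronization effect spans the alpha-beta range, as event-related
desynchronization physiologically does.

## Known limitations

* The binomial null treats pooled CV predictions as independent
  Bernoulli(0.5) draws; cross-validation induces mild dependence, which the
  rescaling to n = 40 absorbs conservatively for the pooled contrast.
* Per-format contrasts inherit the small baseline pool (~10 epochs per
  format after balancing), so per-format significance is noisy at the
  default cohort size; the pooled "all" contrast is the primary readout.
* The simplified global rejection threshold does not repair or interpolate
  channels.
* Group maps assume a shared feature-grid shape across contacts; mixed
  sampling rates across recordings are out of scope.
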