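---
title: "Multi-modal QEEG features for post-stroke cognitive screening: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-modal QEEG features for post-stroke cognitive screening: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qeeg)
```

## The problem

Vascular cognitive impairment after ischemic stroke spans a continuum from
mild cognitive impairment (MCI) to dementia. Resting/task EEG carries
quantitative signatures of that continuum: power shifts from fast to slow
rhythms (delta up, beta down), functional connectivity between and within
hemispheres weakens, and the signal becomes less complex. `qeeg` turns a
19-channel 10-20 recording into a feature vector capturing all three
signatures, screens the features for group differences, and classifies
subjects into normal / post-stroke MCI / post-stroke dementia.

Because clinical recordings of this kind are not freely redistributable,
the package ships a synthetic cohort generator that emulates exactly these
group signatures, so the entire pipeline is testable and demonstrable
without patient data. The same code paths accept real EDF or delimited
recordings.

## Pipeline and preprocessing

The canonical processing order is fixed for reproducibility:

1. artifact-free input (ICA or other artifact removal is out of scope —
   the package assumes cleaned signals);
2. band-pass 1–30 Hz at the native rate;
3. resample to 240 Hz;
4. feature extraction.

**Band-pass filter.** The filter is specified the way clinical filter
banks are: high-pass passband edge 1 Hz, low-pass edge 30 Hz, at most 1 dB
passband droop, at least 80 dB stopband attenuation, Butterworth family,
with stop edges at 0.5 and 35 Hz. Standard order estimation for those
specs yields orders around 15 (high-pass) and 65 (low-pass). A recursive
transfer-function realization of such orders is numerically unusable, so
`bandpass()` applies the exact analytic Butterworth magnitude response in
the frequency domain, zero-phase, after mirror extension of the signal.
This meets the attenuation spec exactly and injects no phase into any
channel — important because coherence features depend on cross-channel
phase, and zero-phase filtering also keeps group-delay transients out of
the entropy features. The residual cost is a short transient at the
recording edges (any zero-phase scheme has one); steady-state behavior is
what the filter tests measure, trimming 2 s per edge.

**Resampling.** 250 to 240 Hz is the exact rational ratio 24/25, applied
as polyphase resampling with anti-alias filtering (`signal::resample`).
240 Hz is used because it makes the dyadic wavelet band edges land on the
classical EEG band boundaries (below).

## Spectral features: wavelet band segmentation and relative power

A five-level Daubechies-2 (DB2) decomposition at 240 Hz induces the band
mapping A5 = delta 0–3.75 Hz, D5 = theta 3.75–7.5, D4 = alpha 7.5–15,
D3 = beta 15–30, D2 = gamma 30–60; `band_definitions()` derives these
edges programmatically from `fs / 2^k`.

`wavelet_band_split()` realizes the decomposition as a multiresolution
analysis in its maximal-overlap (undecimated) form, evaluated in the
frequency domain: the squared magnitude responses of the DB2
analysis/synthesis cascades form an exact partition of unity, so the five
components (plus the discarded 60–120 Hz residual) sum back to the input
to machine precision, are alias-free, and carry zero phase. We chose this
realization over the decimated transform deliberately: decimated subband
reconstructions contain alias images of out-of-band content, which would
contaminate the band-power integration below, whereas the undecimated
components are plain linear time-invariant filterings of the input.

DB2 filters are only four taps long, so the band responses are far from
brick-wall — a 10 Hz tone leaves roughly half its energy outside the D4
component. Band power therefore combines the wavelet split with Welch
spectral estimation and a response correction:

- Welch PSD of each band component (2 s Hamming windows, 75% overlap —
  the window function is a toolbox-ecosystem default, documented here
  because it is a choice, not a given);
- integration over the band's *nominal* interval only;
- bin-wise division by the component's own power response (known
  analytically), which makes the in-band power estimate unbiased for any
  in-band spectral shape. The response never falls below 0.25 inside a
  band's own interval, so the deconvolution is well-conditioned.

Relative power divides each band's absolute power by the sum over the
included bands, per channel, so rows sum to 1 and the feature is
scale-free. Gamma is excluded by default (the 1–30 Hz band-pass leaves
only noise there), giving 4 bands x 19 channels = 76 features; a 5-band
variant is available via the `bands` argument.

## Coherence features

Magnitude-squared coherence
$C_{ab}(f) = |P_{ab}(f)|^2 / (P_{aa}(f)\,P_{bb}(f))$
is estimated with the same Welch segmentation (a single source of truth
for spectral parameters). Coherence from a single segment is identically
1, so at least two segments are required; with 60 s recordings and 2 s
windows at 75% overlap the estimator averages over ~117 segments and its
bias floor for independent signals is well below the 0.2 test bound.

Pairs follow the three canonical schemes: 8 homologous interhemispheric
pairs (Fp1–Fp2 … O1–O2) and the complete graph over each hemisphere's 8
lateral electrodes (28 pairs each); midline electrodes belong to no
scheme. One scalar per pair is reported: the unweighted mean of the MSC
bins over 1–30 Hz. Averaging over the full analysis band (rather than per
classical band) is the minimal reduction consistent with reporting one
value per pair; it is a documented choice, and per-band means can be
obtained by calling `msc()` directly. The recording reference montage is
not modeled; coherence values depend on it, and the package simply
processes the channels as given.

## Complexity features

**Spectral entropy** (bits): Shannon entropy of the Welch PSD restricted
to 1–30 Hz and normalized to a probability distribution over bins. A
one-bin spectrum gives 0; a flat spectrum over $B$ bins gives $\log_2 B$.

**Dispersion entropy** (nats): the series is mapped through the normal
CDF with its own mean and standard deviation, quantized into $c$ classes
with half-up rounding of $c\,y + 0.5$ (the original dispersion-entropy
convention; R's banker's rounding is deliberately avoided), embedded into
patterns of length $m$ at delay $d$, and the Shannon entropy of the
pattern distribution is taken with natural logarithm. Values lie in
$[0, m \ln c]$, with 0 exactly when one pattern occurs. A constant series
has zero standard deviation; it is treated as a single repeated pattern
(entropy 0) rather than an error, because flat spectra are legal inputs
to the spectral variant.

**Spectral dispersion entropy** (nats): dispersion entropy applied to the
ordered Welch PSD bin series over 1–30 Hz with $m = 2$, $c = 6$, $d = 1$.
Where spectral entropy sees only the distribution of bin values, the
dispersion patterns are sensitive to the spectrum's shape along
frequency. The input is the PSD (power) series; "spectral amplitude"
readings of the definition would use its square root, and the choice is
confined to one line of `spectral_dispersion_entropy()` should a user
want to switch. Entropies are reported unnormalized (no division by the
maximum), with units documented per feature.

## Group statistics

`screen_features()` runs a classic one-way fixed-effects ANOVA per
feature across the three groups, plus Tukey HSD post hoc pairwise
comparisons (Tukey–Kramer under the unequal group sizes 18/19/13).
P-values are reported **raw per feature** — the convention of per-channel
QEEG significance tables, where each channel/pair is read as its own
test. This is a multiplicity-uncorrected convention and is flagged
loudly here; `p_adjust = "BH"` applies Benjamini–Hochberg across features
for users who want familywise control. Both the omnibus ANOVA p and all
three pairwise Tukey p-values are emitted for every feature, since
reported tables in this literature do not always distinguish them.

## Classification and evaluation

Five feature scenarios are assembled by column prefix, in deterministic
extraction order: A relative power (76), B coherence (64), C spectral
entropy (19), D spectral dispersion entropy (19), E = B + D (83).

Classifiers: SVMs with linear, quadratic, cubic and Gaussian kernels
(penalty C = 1 throughout; Gaussian kernel
$K(x,x') = \exp(-\lVert x-x'\rVert^2/s^2)$ with scale $s = \sqrt{p}$ for
$p$ predictors), and k-NN in fine (k = 1, Euclidean), medium (k = 10,
Euclidean) and cubic (k = 10, Minkowski order 3) variants. Multiclass SVM
uses one-vs-one voting (`e1071`). "Cubic distance" is read as Minkowski
order 3, pairing the cubic k-NN name with the cubic metric. k-NN ties
break deterministically to the nearest neighbor among tied classes.

Cross-validation is stratified k-fold (5 by default, 10 supported):
folds partition subjects within each class — with only 13 dementia
subjects, unstratified folds can end up with none — and every subject is
predicted exactly once. Features are z-scored with training-fold
statistics only, preventing test-fold leakage and putting coherence (in
[0,1]) and entropies (nats/bits) on comparable scales for distance-based
k-NN. Fold assignment derives from the seed and the class-wise subject
order, so results are invariant to row order. The reported accuracy is
the mean of per-fold accuracies; sensitivity, specificity, precision and
F1 are computed from the aggregate confusion matrix by one-vs-rest
counting and macro-averaged. Fold-averaged and aggregate conventions can
differ in the first decimal; the aggregate is the default because it is
exactly recomputable from the published confusion matrix.

## The synthetic cohort generator

`generate_cohort()` emulates the study conditions: 18 normal, 19
post-stroke MCI, 13 post-stroke dementia subjects, 19 channels at 250 Hz,
60 s each, amplitudes scaled to 20 µV RMS. Each channel is
$w \cdot \text{shared} + (1-w) \cdot \text{private}$: one shared source
per subject, one private source per channel, giving band-mean coherence
that increases monotonically with the coupling weight $w$.

Severity is encoded in three monotone knobs, with directions taken from
the clinical findings being emulated and magnitudes chosen once as
plausible synthetic values:

| group | delta/theta/alpha/beta profile | coupling $w$ | concentration $k$ |
|---|---|---|---|
| normal | .25 / .25 / .25 / .25 | 0.70 | 1.00 |
| stroke MCI | .40 / .225 / .225 / .15 | 0.50 | 0.70 |
| stroke dementia | .55 / .185 / .185 / .08 | 0.35 | 0.45 |

Sources are sums of band-limited Gaussian noise components whose
variances follow the band profile. Delta components are generated over
1–3.75 Hz (not 0–3.75) because the analysis pipeline band-limits at 1 Hz.
The concentration knob $k$ acts twice: each band component occupies only
the central $k$ fraction of its band, and its log-power spectrum carries
a smooth random texture (spline through Gaussian knots every ~0.8 Hz) of
amplitude $0.8k$. Narrower occupancy lowers spectral entropy; weaker
texture flattens the within-band structure and lowers spectral dispersion
entropy. Both effects were necessary: during design we found that
occupancy narrowing alone does not order spectral dispersion entropy
monotonically across groups (band-edge gaps *add* pattern diversity for
intermediate severity), while the texture term restores the intended
ordering — severe groups end up with narrow, smooth, featureless spectra,
which is also the physiologically sensible reading of "reduced spectral
complexity".

Cohorts are bit-for-bit reproducible from (config, seed).

**What the generator does not emulate** — and hence what passing tests do
and do not show about real data: no 1/f background, no dipole/forward
head model or volume conduction, no artifacts, no nonstationarity beyond
the band mixing, no reference-montage effects, Gaussian marginals only.
Tests against this cohort validate the *pipeline* (feature definitions,
statistics, classifier plumbing, monotone responses to known ground
truth); they do not validate clinical effect sizes. Classification
accuracies on the synthetic cohort are near ceiling because the group
signatures are injected globally across channels; the published
clinical accuracies (which reflect overlapping biological populations)
are not reproducible without the patient recordings, and the package
does not attempt to imitate them.

## Numerical choices and degenerate inputs

- Welch: Hamming window, one-sided density scaling (Parseval holds to a
  few percent), segment count $\lfloor (N-L)/(0.25L)\rfloor + 1$; series
  shorter than one window are an error.
- Coherence bins with zero power in either signal are set to 0 rather
  than NaN; estimates are clipped into [0, 1].
- All-zero channels are an error for relative power (the ratio is
  undefined); constant series are a defined degenerate case (entropy 0)
  for dispersion entropy.
- Epochs are half-open $[t_0, t_1)$ slices; boundaries are validated
  against the recording duration. Task epoch lengths are protocol
  metadata the caller must supply.
- z-scoring guards zero-variance features (scale set to 1).
- EDF I/O quantizes to 16-bit integers over each channel's physical
  range; round trips are exact to that quantization.

## Problem sizes used by the test suite

The shipped tests build one default 50-subject, 60 s cohort per session
(~1.5 min of feature extraction) and reuse it; Monte-Carlo checks use
1000 ANOVA replicates, 4000 permutations for the Tukey oracle, and 200
series for the dispersion-entropy oracle. These sizes were chosen so the
whole suite completes in a few minutes while keeping every statistical
bound comfortably away from its threshold.

## Known limitations

- The package assumes a fixed 19-channel 10-20 montage; re-referencing,
  bipolar derivations and high-density caps are out of scope.
- No artifact handling: inputs are assumed cleaned.
- DB2's short filters mean heavy spectral overlap between adjacent bands;
  the deconvolution corrects band power in expectation but single-band
  component *waveforms* still contain out-of-band energy.
- Raw per-feature p-values invite multiplicity abuse if read as a
  familywise claim; use the BH option for discovery-style screening.
- The EDF writer covers continuous unannotated recordings only.
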