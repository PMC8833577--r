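---
title: "Detecting, distilling and reverse-engineering epileptogenic HFOs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting, distilling and reverse-engineering epileptogenic HFOs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Interictal high-frequency oscillations (HFOs, brief 80–500 Hz oscillatory
events in intracranial EEG) are a candidate spatial biomarker of the
epileptogenic zone in medication-resistant epilepsy. Two obstacles stand
between raw recordings and a clinically usable biomarker. First, automated
detectors emit many false positives (ringing of filtered sharp transients,
muscle activity), and expert verification is slow and poorly reproducible.
Second, healthy cortex also generates HFOs, so even a perfectly curated pool
of real HFOs mixes epileptogenic events (eHFOs) with physiological ones —
and no per-event ground truth exists for that distinction.

`epihfo` implements a complete workflow around these obstacles:

1. a short-term-energy (STE) candidate detector;
2. image encodings of each 1-s event window (Gabor scalogram, EEG tracing
   plot, amplitude-coding plot) feeding binary CNN classifiers that emulate
   expert artefact rejection and spike co-occurrence labelling;
3. a weakly supervised protocol that trains an eHFO classifier from labels
   that only exist at the *channel* level — resection status — restricted to
   patients whose post-operative seizure freedom certifies those labels;
4. perturbation-based probes of the trained model (pixel-wise significance
   templates, inverted-T scalogram perturbation, spike-template insertion);
5. outcome-level statistics (resection ratios, rank ROC/AUC, logistic
   outcome models, SOZ rate comparisons);
6. a synthetic iEEG cohort generator so every stage is testable without
   clinical recordings.

# Detection

The detector band-passes each channel to 80–500 Hz (4th-order Butterworth,
applied forward and backward so the phase is zero), computes a centred 3 ms
moving-RMS envelope, and marks samples where the envelope exceeds its mean
by 5 SD. Marked runs closer than 10 ms are merged; a surviving run becomes a
candidate HFO (c-HFO) when it lasts at least 6 ms and its rectified
band-passed signal shows at least six local maxima above mean + 3 SD of the
rectified signal. The thresholds (5 SD envelope, 3 SD peaks, six peaks,
80–500 Hz) are the defining constants of this detector family; the window
and merge-gap values are declared, versioned defaults of this
implementation. Envelope statistics are computed over the whole analysed
segment by default (interictal sleep segments are treated as stationary);
epoch-wise statistics are available through `epoch_seconds`.

Because every threshold is SD-relative, detection is invariant to rescaling
a recording by any positive constant — a property the test suite asserts.
Events whose 1-s context window would cross a recording boundary are dropped
rather than padded: padding would fabricate signal.

A customized average reference is applied before detection: channels flagged
as artefact-laden are excluded from the reference mean but still
re-referenced and analysed.

# Event encodings

Each candidate is represented by a one-second window centred on the event
(500 ms either side at 2000 Hz) and converted to three images, resized to
224×224 for the reference geometry (64×64 for desk-scale experiments):

* **Scalogram** — continuous Gabor-wavelet magnitude, 10–500 Hz. The
  frequency axis is *linear* with the highest frequency in row 1; linear
  spacing makes the low-frequency band used by the interpretation stage a
  rectangle in image coordinates. The wavelet width is fixed at 6 cycles at
  every frequency: at 10 Hz this keeps the wavelet support inside the 1-s
  window, while at ripple frequencies it gives sharp ridges. Each image is
  min–max normalized to [0, 1].
* **EEG tracing plot** — the signal is min–max scaled into the 0–2000 range
  and drawn as a one-pixel polyline on a 2000×2000 canvas (one sample per
  column), then box-averaged down to the target size. Box averaging was
  chosen over interpolating resamplers to avoid ringing around the stroke.
* **Amplitude-coding plot** — each image column carries a constant intensity
  equal to the min–max normalized mean signal value in that column's time
  bin. This encoding is exactly invertible to the bin-averaged normalized
  signal, which the tests exploit, and it is the plane the spike-insertion
  probe manipulates.

The artefact task consumes the scalogram repeated on all three input planes;
the spike and eHFO tasks consume (scalogram, tracing, amplitude) in that
fixed order. Degenerate constant windows map to uniform 0.5 images.

# Classifiers

Both supervised tasks use the same binary architecture: a convolutional
backbone whose final layer is replaced by three fully connected layers with
LeakyReLU, batch normalisation and 10% dropout in between, ending in a
sigmoid. Two backbones are provided: a ResNet-18-style residual stack for
the 224×224 reference geometry, and a declared 4-block stride-2 CNN
(`small_cnn`, 64×64) used by the test suite and the scaled-down studies.
The engine (convolution via im2col in compiled code, batch normalisation,
Adam, weighted cross-entropy) is part of the package; its gradients are
validated against finite differences in development and its training is
bit-reproducible for a given seed.

Training uses binary cross-entropy with Adam at learning rate 3e-4 for 15
epochs. Checkpoints are chosen from the per-epoch validation-loss curve:
the artefact detector takes the *first local minimum* (an early-stopping
flavour; if the curve is monotone the global minimum is the fallback), the
spike detector and the eHFO model take the global minimum. Weight
initialization is random and seeded — no pretrained weights are required or
downloaded. Batch size defaults to 128, Adam keeps its standard moment
coefficients, and no schedule, augmentation or class re-balancing is
applied. The hard-label threshold on the sigmoid output is 0.5.

Cross-validation supports the patient-wise scheme (one patient out as test;
the pooled remainder split 10% validation / 90% training) and 5-fold
pooling (20/70/10 test/train/validation).

# Weak supervision of eHFOs

Per-event labels for epileptogenicity do not exist, so labels are inherited
from channels: every real HFO on a *resected* channel is labelled 1, every
HFO on a *preserved* channel 0 — but only in patients who became
seizure-free at 24 months, because only there does the resection certify
that (a) everything epileptogenic was inside the resection and (b) nothing
epileptogenic remained outside. Non-seizure-free patients contribute no
training events. Three known error sources are handled explicitly:

* resections include anatomical margins that are not epileptogenic — these
  false-positive labels are down-weighted with `w = 0.5` in the loss for
  resected non-SOZ channels (SOZ-channel positives and all negatives keep
  `w = 1`);
* patients contribute at most 2500 events (uniformly sampled without
  replacement) so prolific patients do not dominate;
* probable artefacts are removed beforehand by the trained artefact
  detector at threshold 0.5.

The eHFO model reuses the trained spike detector's convolutional stack,
frozen, as a feature extractor — the spike detector already encodes HFO
morphology — and trains a fresh head with the weighted loss, selecting the
global-minimum checkpoint. Because the backbone is frozen (and run in
inference mode, so its batch statistics are fixed), the implementation
extracts features once and optimises the head on them; this is numerically
identical to backpropagating through the frozen stack and much faster. A
patient-specific model is trained for every target patient from the *other*
seizure-free patients (8 others for a seizure-free target, all 9 for a
non-seizure-free target in the reference cohort shape), and all inference
for a patient uses that patient's own model — a leakage guard asserts the
target never contributes training events.

The central claim — that the classifier *purifies* its own noisy labels —
is tested synthetically: with 30% of resected-channel events carrying
non-epileptogenic morphology, held-out accuracy against morphological
ground truth must exceed the weak-label/ground-truth agreement.

# Interpretation

With per-event classes in hand, the trained model is reverse-engineered:

* **Significance template.** For each scalogram pixel, a one-tailed Welch
  t-test of "mean eHFO intensity exceeds mean non-eHFO intensity" at
  α = 0.005; the binary image averages across patients into a population
  template. Welch's form is used because group sizes and variances differ.
  No multiple-testing correction is applied across pixels — α is per-pixel
  by design — and a permutation check in the test suite quantifies the
  implied false-positive rate (≤ 2α) instead. Pixels with zero variance in
  both groups are set to 0.
* **Inverted-T perturbation.** The template concentrates in an inverted-T:
  all frequencies within ±45 ms of the event centre plus the 10–59 Hz band
  across the window. The corresponding mask rectangle is computed with
  outward-rounded index arithmetic so the stated physical bounds are fully
  covered. Inside the mask each scalogram pixel moves half-way to the image
  maximum (`0.5·v + 0.5·max`); other planes are untouched. If the model
  truly keys on this signature, classified non-eHFOs should move towards
  eHFO — summarised per patient and tested with a one-tailed t-test on the
  probability changes.
* **TDCP insertion.** A spike-like time-domain characteristic pattern — a
  Gaussian-windowed monophasic deflection, 60 ms support by default (the
  original spike template's analytic form is not published; width and shape
  are configuration parameters here) — literally replaces the affected
  columns of the amplitude-coding plane: the pattern's min–max-normalized
  profile is mapped onto the plot's intensity range, so an upgoing pattern
  rises from the plot minimum to a peak at the plot maximum and a downgoing
  pattern falls from the plot maximum to a valley at the plot minimum.
  Every admissible centre column is tried (exhaustive search; a stride is
  available), and the placement with the largest probability increase is
  reported.

  Validating the *placement* search needs care: a global-average-pooled CNN
  given three largely redundant input planes is free to ignore the
  amplitude plane's spatial structure entirely, in which case placements
  carry no information about the scan. The shipped validation therefore
  trains a classifier whose only class signal is the amplitude-coding
  position of a single spike (centred vs off-centre, with the scalogram and
  tracing planes drawn from spike-free windows in both classes); on that
  model, whose decision rule is localized by construction, the scan must
  concentrate its best placements near the window centre. Because training
  spikes carry random polarity, each event's optimal placement is taken as
  the insertion — over both TDCP directions — with the maximum probability
  change; the mismatched polarity's argmax is noise. Probability-change
  significance is still measured on the eHFO model's classified non-eHFOs.

# Outcome-level evaluation

Per patient, the resection ratio of a class is the fraction of its events
on resected channels. ROC curves over patients use the Mann–Whitney rank
formulation of the AUC with midrank tie handling; the p-value is a
one-sided Mann–Whitney test (exact for small tie-free tables, the scale of
a 14-patient cohort). The two-covariate logistic model (eHFO resection
ratio + complete SOZ resection) is fitted by maximum likelihood; complete
separation is detected, flagged, and re-fitted with a small ridge penalty.
eHFO rates (events/min/channel) are compared between SOZ and non-SOZ
channels with a two-sided paired t-test across patients; patients lacking
either channel group are excluded from the pair. The chi-square test
relating model classes to expert spike classes uses no continuity
correction (the reference counts are in the thousands); a flag restores
Yates' correction.

# The synthetic cohort generator

The generator emulates the statistical structure the pipeline needs, not
biophysics:

* **Background**: Gaussian 1/f^α noise (α = 1 by default, RMS 10 µV),
  synthesized by spectral shaping — the standard single-parameter EEG
  surrogate.
* **Events**: ripples (85–245 Hz) and fast ripples (255–480 Hz) as
  Hann-windowed sinusoids with enough cycles to satisfy the detector's
  six-peak rule; spike-bearing HFOs add a Gaussian-windowed monophasic
  transient (60 ms, random polarity). Event amplitudes are anchored at 10×
  the band-passed background RMS. Durations are drawn so that the detected
  population falls predominantly in the 60–200 ms range.
* **Epileptogenic signature**: a ×2 broadband power boost within ±45 ms of
  onset, a complementary-band tone at onset, and a 15–50 Hz component under
  a 900 ms envelope — a recoverable inverted-T target for the
  interpretation stage.
* **Artefacts**: exponentially damped "ringing" of a sharp transient (few
  resolvable peaks at detector scale) and Hann-windowed broadband noise
  bursts. The literature gives no quantitative artefact morphology; these
  are stand-ins with the right qualitative failure modes, not claims.
* **Cohort structure**: per-channel Poisson event placement with a 500 ms
  exclusion zone (each analysis window contains one event, keeping ground
  truth unambiguous); ~30% of channels resected, ~12% SOZ; in seizure-free
  patients every resected-channel HFO is epileptogenic with probability
  1 − `label_noise` and preserved channels are clean, while non-seizure-free
  patients carry epileptogenic events on both sides of the resection
  boundary (p = 0.5 resected / 0.35 preserved) — the incomplete-resection
  scenario.

All randomness flows from one seed with fixed per-patient substreams:
identical configuration and seed reproduce recordings sample-for-sample.

What passing synthetic tests does **not** show: the generator's event
classes are far more separable than clinical morphology, channel counts and
rates are idealised, and no propagation, state-dependence (sleep stages) or
montage artefacts are modelled. Synthetic results validate the machinery
and its statistical behaviour, not clinical performance numbers.

# Numerical and design choices

* Sample indices are 1-based with half-open `[start, end)` event intervals,
  applied uniformly across tables and windows; event centres round down.
* The lossless interchange container is float64 raw + JSON header; EDF
  (16-bit) is supported for interoperability but quantizes, so golden tests
  use the raw container.
* Mask indices round outward so physical bounds are covered; min–max
  normalization maps constant images to uniform 0.5; probabilities are
  clipped at 1e-7 inside the loss.
* Checkpoint epochs are 1-based; "first local minimum" is defined as the
  smallest epoch whose loss is ≤ its predecessor and < its successor, with
  the global minimum as fallback on monotone curves.
* The 2500-event cap is applied after artefact filtering, per patient,
  seeded. The frozen eHFO backbone comes from the spike detector rather
  than random weights (both are selectable): a frozen random stack would
  extract features unrelated to HFO morphology, which is hard to reconcile
  with "feature extractor".

# Problem sizes used by the shipped studies

The scaled-down studies run by the tests and by `scripts/acceptance.R` use:
12 patients (8 seizure-free), ~300 events per patient, 30% label noise,
64×64 encodings and the `small_cnn` backbone for purification; 250 + 250
training events per class for the interpretation probe; 60-second
single-channel traces with two injected bursts for detector validation; and
14-patient outcome tables. These sizes were chosen as the smallest cohorts
on which the statistical contrasts of interest are stable across seeds.

# Known limitations

* The reference 224×224 ResNet-18-style configuration trains slowly on a
  single CPU; the desk-scale configuration is the practical default outside
  GPU-class hardware.
* EDF support covers continuous 16-bit recordings only (no EDF+
  annotations, no discontinuous files).
* The perturbation probes inherit every caveat of occlusion-style
  interpretation: they certify sensitivity to the planted features, not a
  complete description of the model's decision function.
* AUCs and accuracies reported on synthetic cohorts are properties of the
  generator's separability, not reproductions of clinical values.
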