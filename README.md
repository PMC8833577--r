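# epihfo

Detection, weakly supervised classification and reverse engineering of
epileptogenic high-frequency oscillations (HFOs) in intracranial EEG.

## The problem

Interictal HFOs — brief 80–500 Hz oscillatory events in intracranial EEG —
are a promising spatial biomarker of the epileptogenic zone in
medication-resistant epilepsy. Using them in practice requires solving two
problems at once: automated detectors emit artefacts that normally need
slow, poorly reproducible expert review, and even genuine HFOs mix
epileptogenic events (eHFOs) with physiological ones that no expert can
label per event. `epihfo` is a toolbox for the full workflow: candidate
detection, CNN-based artefact and spike classification from image encodings
of each event, weakly supervised *discovery* of eHFOs from channel
resection status and surgical outcome, perturbation-based interpretation of
the trained model, and outcome-level statistics — plus a synthetic iEEG
cohort generator that makes every stage testable offline.

## The core method

* **Detection.** A short-term-energy detector: band-pass 80–500 Hz
  (zero-phase), moving-RMS envelope thresholded at mean + 5 SD, runs merged
  over < 10 ms gaps, and events kept only if the rectified signal shows ≥ 6
  peaks above mean + 3 SD. Output events are candidate HFOs (c-HFOs).
* **Encoding.** Each 1-s event window becomes three images (Gabor-wavelet
  scalogram 10–500 Hz, EEG tracing plot, amplitude-coding plot), resized to
  224×224 (64×64 at desk scale).
* **Classification.** Binary CNNs (ResNet-18-style or a compact 4-block
  backbone) with a 3-layer LeakyReLU/BatchNorm/dropout head and sigmoid
  output, trained with Adam (lr 3e-4, 15 epochs, BCE loss).
* **Weak supervision.** In seizure-free patients, every real HFO on a
  resected channel is labelled y = 1 and on a preserved channel y = 0, with
  loss weight w = 0.5 for resected non-SOZ channels (uncertain positives);
  training uses a frozen spike-detector backbone, a per-patient 2500-event
  cap, and patient-specific models trained without the target's data. The
  loss is `w · BCE(x, y)` with `BCE = −[y·log x + (1−y)·log(1−x)]`.
* **Interpretation.** Pixel-wise one-tailed t-tests (α = 0.005) between
  eHFO and non-eHFO scalograms yield an inverted-T template (±45 ms across
  all frequencies plus 10–59 Hz across the window); perturbing non-eHFOs
  inside it (`0.5·v + 0.5·max`) or inserting a spike-like pattern into the
  amplitude-coding plane probes what the model learned.
* **Evaluation.** Per-patient resection ratios, rank-based ROC/AUC,
  logistic outcome models, SOZ vs non-SOZ rate comparisons and
  model-vs-expert cross-tabulations.

## Worked example

```r
library(epihfo)

cfg <- sim_config(n_patients = 4, channels_per_patient = 8,
                  recording_minutes = 2, seizure_free_fraction = 0.75,
                  seed = 42)
cohort <- generate_cohort(cfg)

rec <- apply_average_reference(cohort$recordings[[1]],
                               subset(cohort$channels, patient == "pt1"))
rec
#> <hfo_recording> patient pt1: 8 channels x 240000 samples @ 2000 Hz (2.00 min)

events <- ste_detect(rec)
nrow(events)
#> [1] 17
head(events[, c("channel", "start_sample", "end_sample", "n_peaks", "peak_frequency")], 3)
#>   channel start_sample end_sample n_peaks peak_frequency
#> 1    ch01       167959     168049      35       422.2222
#> 2    ch01       184760     184861      22       217.8218
#> 3    ch02        32502      32569      14       208.9552

w <- extract_window(rec, events[1, ])
imgs <- encode_event(w, size = 64)   # scalogram / tracing / amplitude images
```

The detector found 17 candidates in 2 minutes of 8-channel synthetic data;
each row gives the half-open sample interval of one event, its
suprathreshold peak count (all ≥ 6 by construction) and the periodogram
peak frequency within 80–500 Hz — the first event is a fast ripple near
422 Hz. `encode_event()` turns an event into the three 64×64 images the
classifiers consume.

The end-to-end pipeline (simulate → detect → encode → train → eHFO
discovery → evaluate) runs from a single config:

```r
man <- run_pipeline(list(sim = list(n_patients = 4, channels_per_patient = 6,
                                    recording_minutes = 2),
                         model = list(epochs = 4), seed = 7),
                    out_dir = "run1")
```

writing `events.csv`, `discoveries.csv` (per-event eHFO probabilities),
per-channel count tables, an evaluation report and a digest manifest. A
thin command-line wrapper is installed at `inst/cli/epihfo.R`
(`simulate`, `detect`, `run` subcommands).

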