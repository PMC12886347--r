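---
title: "Methods: analysing formant-perturbation compensation experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analysing formant-perturbation compensation experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(formantcomp)
```

## The measurement model

In a compensation paradigm a speaker produces a vowel hundreds of times
while hearing their own voice through earphones; on randomly interspersed
trials the first and second formants (F1, F2) of the feedback are shifted in
the F1–F2 plane. Because auditory feedback takes roughly 100–200 ms to
influence the ongoing articulation, the first 100 ms of the vowel reflect
only the feedforward motor plan, while the 300–400 ms window reflects the
plan plus any feedback-driven correction. This package operationalises:

- **corrective response** = mean formant change in [300, 400) ms minus mean
  change in [0, 100) ms of a perturbed trial;
- **adaptive (one-shot) response** = mean change in [0, 100) ms of the
  unperturbed trial after a perturbation minus the same window of the
  unperturbed trial before it.

"Formant change" is always relative to a word-specific, time-normalised
baseline trajectory, which removes the consonant–vowel and vowel–consonant
formant transitions: eligible unperturbed trials (those *not* immediately
following a perturbed trial, which can carry one-shot learning) are linearly
resampled to 100 points between vowel onset and offset and averaged; the
baseline is then linearly stretched to each trial's duration and subtracted.
Trials shorter than the 400 ms analysis window are excluded and counted.

All geometry is participant-specific. Centroids are componentwise medians
of pre-test productions (even counts: mean of the two middle values). With
F1 on the abscissa and F2 on the ordinate, perturbations are applied along
the ɛ→æ centroid vector (`eps_to_ae`) or its +90° perpendicular chosen to
have a positive F2 component (`eps_to_out`), scaled to 0.5/1.0/1.5 of the
ɛ–æ distance. Response angles are reported relative to the ɛ→ɪ angle, so 0°
means "the response points at the speaker's /ɪ/". Angles are degrees wrapped
to (−180, 180]; condition angles average the response *vectors* first and
then take the angle, which is far more robust than averaging angles of noisy
single trials.

## Tunable parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| analysis windows | [0,100), [300,400) | ms | early window is feedback-free at typical latencies; late window captures the ramped correction |
| minimum duration | 400 | ms | trials must cover the late window |
| baseline resolution | 100 | points | resolves transition shape at typical 2–10 ms formant frame rates |
| magnitude scales | 0.5, 1.0, 1.5 | × ɛ–æ distance | spans sub- to supra-natural error sizes |
| permutation shuffles | 10,000 | — | p-value resolution ~1e-4 with the add-one convention |

Simulator defaults (`speaker_params()`): duration uniform on 450–650 ms;
corrective latency 150 ms (within the 100–200 ms range over which auditory
feedback begins to act) with a 100 ms ramp time constant; feedback gain 0.15
of the perturbation magnitude (compensation is routinely 10–25 % in adults);
direction bias β = 0.8 toward the ɛ–ɪ axis; one-shot learning rate 0.05 with
retention 0.9 per trial; exposure decay λ = 0.005 per perturbed trial
(≈ 27 % attenuation across a 126-perturbation session); consonant-transition
onsets of −40…−60 Hz (F1) and +150…+250 Hz (F2) decaying with τ = 30 ms;
trial jitter 15 Hz, sample noise 10 Hz, 2 ms sampling.

## Design choices where the design was open

- **Perturbed-trial placement.** The ≥2-unperturbed-gap constraint is
  enforced over *word* trials only; sentence trials are transparent (they
  neither break nor count toward gaps), and the block start counts as zero.
  Positions are drawn by an exact gap bijection (an 18-subset of 1..72
  mapped by `p_i = s_(i) + 2i`), which is uniform over exactly the
  constraint-satisfying sets — equivalent to accept–reject over uniform
  subsets but constant-time (the acceptance rate of rejection sampling here
  is ≈ 7×10⁻⁴).
- **Exposure halves.** "Half a session" is 3.5 blocks: blocks 1–3 vs 5–7,
  with block 4 split at its 9th perturbed trial. Because magnitudes are
  randomised within block 4, the per-magnitude half counts are 21 only in
  expectation (always within 18–24).
- **Windows.** Half-open [t0, t1) with left-edge sample timestamps.
- **Normalisation.** Percent responses divide both formant components by
  the *Euclidean* perturbation magnitude of the trial's condition; a single
  scalar keeps angles unchanged. (The alternative — per-formant components —
  would distort angles.) Group tests use percent responses; angles are
  computed on the Hz vectors.
- **Permutation test.** Two-sided via absolute statistics; add-one p-value
  `(#extreme + 1)/(n_perm + 1)`; the pooled sample is sorted before
  shuffling so that swapping equally sized groups reproduces p bit-exactly
  under the same seed; one angle per participant per direction (the
  condition-average angle consolidated across magnitude and exposure) is
  the exchangeable unit. A participant×magnitude unit is a defensible
  alternative; the participant level avoids pseudo-replication.
- **Adaptive triads.** A perturbed trial contributes an adaptive response
  only if both flanking unperturbed word trials exist within the same block
  and survived exclusion; broken triads are skipped and counted, never
  imputed.
- **Mixed models.** `response ~ direction * magnitude * exposure +
  (1 | participant)` with sum-to-zero contrasts, Satterthwaite Type-III
  tests via `lmerTest`, and Benjamini–Hochberg FDR across each model's term
  family. Degrees-of-freedom machinery and marginal-mean contrasts are
  deliberately delegated to the standard packages; the package's contract
  is the returned (term, F, df, p) structure.
- **One-sample a priori tests** are run on percent responses (participant
  means across all conditions).

## What the simulator does and does not emulate

The generator reproduces the features the pipeline must be sensitive to:
steady-state vowel targets with onset transitions, duration variability,
latency-ramped corrective responses whose direction mixes the
anti-perturbation axis and the ɛ–ɪ axis (β), exposure-dependent gain decay
(e^(−λk)), one-shot adaptive offsets that persist and decay across trials,
and trial- and sample-level noise. Between-participant variability enters
through centroid jitter and β jitter in `run_pipeline()`.

It does **not** emulate formant-tracking failures, mispronunciations,
vowel-offset transitions, somatosensory feedback, session-order or fatigue
effects, or any articulatory constraint linking F1 and F2. Passing recovery
tests therefore demonstrates that the *analysis* is correct and calibrated,
not that real speakers behave like the generator; with real data the manual
screening and annotation steps (spectrogram inspection, onset/offset
marking) are taken as given inputs.

## Numerical notes and known limitations

- Linear interpolation is used both for the 100-point resampling and for
  stretching the baseline to a trial's duration. For curved transitions
  (exponential, τ = 30 ms) the interpolation error is ≈ 0.1–0.2 Hz in the
  early window, which biases condition-average response angles by well
  under 1°; exact closed-form recovery tests therefore use flat transitions
  and fixed durations, and angular recovery is asserted at 5°.
- A zero response vector has an undefined angle and is reported as missing,
  never as 0; circular means with (numerically) zero resultant are likewise
  missing.
- Degenerate inputs fail loudly: missing vowels, coincident centroids,
  non-positive magnitude scales, single-participant mixed models and
  not-fully-crossed designs are errors, not warnings. An outward
  perturbation lacking an F1 increase (atypical vowel space) warns.
- Exclusion bookkeeping always satisfies kept + excluded = total; the
  simulator's default duration range (450–650 ms) produces no exclusions by
  construction, so exclusion paths are exercised with constructed short
  trials.

## Problem sizes used by the test suite

The suite verifies the schedule constraints on 1,000 seeds; permutation
p-values against exhaustive enumeration at n = 4+4; FDR against the
brute-force step-up on 1,000 random vectors; type-I calibration of the
permutation test (499 shuffles) and the mixed model over 500 null
replicates each; noise-free closed-form recovery to 1e-9; and noisy angular
recovery on twenty 7-block single-direction sessions (42 trials per
magnitude, 10 Hz sample noise). The end-to-end qualitative check simulates
8 participants × 2 sessions × 3 blocks with direction-dependent gains
(0.25 vs 0.10) and λ = 0.01, and asserts the sign pattern: corrective F1
down / F2 up, larger amplitude for `eps_to_ae`, first-half amplitude above
second-half.
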