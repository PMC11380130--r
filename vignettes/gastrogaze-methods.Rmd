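---
title: "Methods: disgust avoidance and gastric rhythm analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disgust avoidance and gastric rhythm analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of what it computes, why the
defaults are what they are, which numerical conventions were fixed where a
choice had to be made, and what the synthetic-data tests do and do not
establish. It states no empirical result that the test suite does not
itself compute.

## The measurement problem

Disgust has two readouts this package quantifies. Behaviourally, people
look away from disgusting images after a brief initial glance toward them;
in a preferential-looking task (two stimuli side by side, free viewing)
this appears as a negative dwell-time difference (disgust − neutral) that
sets in after roughly one second and does not habituate. Physiologically,
disgust attenuates the gastric slow wave: the electrogastrogram's
normogastric rhythm (2–4 cycles/min, typically ~3 cpm = 0.05 Hz) loses
power, a pattern resembling the gastric physiology of nausea
("proto-nausea"). The package implements both measurement chains plus the
statistics layer that relates them to age, sex and disgust-sensitivity
questionnaires.

## Electrogastrogram chain

### Model and assumptions

The EGG is modelled as a linear mixture: a small number of slow
oscillatory sources (gastric and otherwise) project onto four cutaneous
sensors, contaminated by electrode drift, broadband noise and sparse
movement spikes. Two assumptions drive the design: (i) artifacts are
separable in time (spikes) or frequency (drift, high-frequency noise)
before source separation; (ii) gastric and non-gastric sources are close
enough to statistically independent for ICA to isolate them, after which a
normogastric signal-to-noise criterion decides which components are
gastric.

### Stage order and parameters

The chain is `demean → hampel → bandpass → decompose →
select_and_reconstruct → block_spectrum → band_summary →
gastric_disgust_index`, in that order; despiking before band-pass matters
because the band-pass smears a spike across many samples (the test suite
asserts the two orders do not commute).

* **Hampel filter** — window 4000 samples (one normogastric cycle at
  200 Hz), threshold 3. Dispersion is MAD × 1.4826 (Gaussian-consistent);
  the window is centered and truncated symmetrically at the edges, so
  every window stays odd-sized. The implementation is exact (bit-identical
  to the brute-force per-window median/MAD definition; the rejection test
  is evaluated by counting order statistics rather than materialising the
  MAD, which is what makes the exact filter affordable at 4000-sample
  windows).
* **Band-pass** — Butterworth, 0.5–10 cpm. The order is not dictated by
  the method description, so order 4 was chosen and is configurable. The
  filter is applied forward–backward (zero phase) so the slow gastric
  phase is not shifted; the design is realised as second-order sections
  because at 200 Hz the corners sit at ~4e-5 of Nyquist and a transfer
  function in polynomial form would be numerically unusable. Edges are
  padded by odd reflection with steady-state section initial conditions;
  residual edge transients decay over roughly one high-pass period
  (~2 min), which is why amplitude assertions in the tests trim edges.
* **ICA** — FastICA with whitening, logcosh negentropy contrast, deflation
  scheme, seeded initialisation (default seed 0), at most 500 iterations,
  tolerance 1e-4. Non-convergence warns and is flagged, never silent. With
  all components kept, reconstruction is exact (tested at 1e-6 relative).
* **Component SNR** — peak power in 2–4 cpm over mean power in the
  remaining *analysed* frequencies. "Remaining" is restricted to the
  band-pass range (0.5–10 cpm): frequencies the filter already removed
  would deflate the denominator artificially. This choice is configurable
  (`analysed`). The SNR uses the same Hann/FFT estimator as the block
  spectra, over the whole recording, for internal consistency. Components
  with SNR < 3 are discarded; a component at exactly 3 is kept ("under 3"
  is the exclusion rule). If nothing survives, the participant is excluded
  for gastric measures.
* **Spectra** — per condition block, per sensor: Hann window, FFT,
  one-sided power normalised so that total power equals the
  window-compensated mean square of the segment (a Parseval identity the
  tests assert on every spectrum); spectra are then averaged over sensors
  without per-sensor normalisation (whether the original analysis
  normalised per sensor is unknowable from the method description;
  unnormalised averaging is the simpler convention and is documented
  here). Spectra are computed on the contiguous block span, not on
  concatenated stimulus epochs — concatenation would splice the phase and
  create spurious broadband power.
* **Bands** — brady 0.5–2, normo 2–4, tachy 4–10 cpm. A bin at exactly 2
  or 4 cpm belongs to the normogastric band (closed normo band, open
  neighbours); the convention matters because bin placement depends on
  block length. The results prose of the source literature sometimes puts
  the bradygastric floor at 0.1 cpm; 0.5 is adopted because it matches the
  filter's high-pass corner, and `gastric_bands(brady_low = 0.1)` exposes
  the alternative.
* **Index** — ln(normogastric peak power, disgust ÷ neutral). Non-positive
  peaks or an all-zero spectrum flag the participant missing rather than
  propagating NaN.

### A note on the SNR threshold and white noise

The component SNR's numerator is a maximum over in-band bins, so under
pure white noise its expectation grows with spectral resolution (more
bins, higher maximum). At the 0.2 cpm resolution of a 300 s segment the
median white-noise SNR sits below 3; over much longer segments it can
exceed 3. The threshold of 3 should therefore be read as calibrated for
block-scale segments, not as a universal constant — the test suite pins
the white-noise behaviour at the working resolution.

## Gaze chain

* **Fixation detection** — proprietary tracker algorithms are out of
  scope; the package substitutes a documented velocity-threshold detector
  (central-difference speed over ±2 samples, default threshold 2 px/ms,
  minimum duration 50 ms, blinks break runs). Against the generator's
  ground truth, >90% of blink-free fixations are matched by detected
  midpoints.
* **Dwell** — a fixation belongs to an AOI iff its x centroid lies in the
  AOI's half-open horizontal span `[x_min, x_max)`, regardless of y; this
  horizontal-span rule is the field convention for side-by-side stimulus
  pairs, and a vertical gate is available but off by default. Dwell per
  stimulus is summed fixation duration. The alternative convention —
  counting raw samples inside the span — exists in the literature, and
  both appear in the source description of this task; fixation-duration
  dwell is primary here because it is the one stated under data reduction,
  and `dwell(mode = "samples")` provides the other for sensitivity
  analyses.
* **Exclusion** — a trial is excluded iff strictly more than 50% of its
  stimulus-window samples are invalid; the fraction is computed over the
  12 s stimulus window only. Raising the threshold can only retain more
  trials (tested as a monotonicity property).
* **Avoidance score** — mean over retained trials of (dwell disgust −
  dwell neutral), in ms; negative = avoidance.
* **Time course** — dwell share per 500 ms bin as a percentage of *valid*
  time in that bin (the normalisation had to be fixed; percent-of-bin
  makes bins comparable when blinks are unevenly distributed), differenced
  and averaged first over a participant's trials, then over participants,
  with between-participant SEM. The bin width is a free parameter; 500 ms
  resolves the ~1 s approach phase without starving single bins of valid
  samples. A participant with zero valid time in a bin is missing for that
  bin.

## Questionnaires

Totals are sums of (reverse-keyed where specified) integer item responses;
subscales are sums over mapped items; any missing item flags the affected
scores missing (no imputation — downstream correlations are
pairwise-complete). Scoring specifications are editable JSON files. The
TDDS map follows the instrument's interleaved 7/7/7
moral/sexual/pathogen structure. The child 22-item and DS-r subscale maps
shipped here are **synthetic defaults** (clearly marked in each file's
`provenance`): the true item keys live in the instruments' source
publications and must be supplied for substantive use. The scoring engine
itself is fully tested independent of any particular map.

## Statistics

* **Standardisation** — z-scores with the sample (n−1) SD by default
  (configurable); trial number, age and questionnaire covariates are
  standardised before entering models.
* **Mixed models** — candidate sets are explicit lists, never automatic
  selection. Every candidate carries random intercepts for participant and
  parent/carer (siblings share a parent; no random slopes, since none are
  motivated), and all candidates are fitted on identical listwise-complete
  rows over the union of their variables. Estimation is maximum likelihood,
  not REML: the candidates differ in fixed effects, and REML likelihoods
  are not comparable across fixed-effect structures. The ledger reports
  AIC, BIC, ΔAIC/ΔBIC to the best model per criterion, and Wald statistics
  (Z = β/SE, normal p); convergence failures and singular fits are flagged
  per model. The dwell response is modelled standardised — printed
  coefficients from any particular study are not reproduction targets, as
  they depend on unavailable raw data and an unstated response transform.
* **Correlations** — Pearson R with two-sided p on pairwise-complete rows,
  n per cell, no multiplicity correction by default; cells with fewer than
  3 complete pairs are flagged missing.

## Synthetic generators: what they emulate, and what a green test means

* **EGG** — three sinusoidal sources (3, 1, 6 cpm; normogastric dominant)
  mixed by a fixed full-rank 4×3 matrix, plus per-sensor linear drift,
  Gaussian noise (SD 0.1 by default — the field has no calibrated
  noise-floor model, so this is a stated free knob) and Poisson
  single-sample spikes (±8 units, 2/min) of exactly the kind a Hampel
  window is designed to remove. During the disgust block the normogastric
  amplitude is multiplied by (1 − δ), so the ground-truth peak-power ratio
  is (1 − δ)². Blocks default to 780 s, matching a 28-trial block of 20 s
  presentations with jittered intervals; heavy Monte-Carlo tests scale to
  300 s purely for runtime (0.2 cpm resolution still separates the bands).
  Optional ±5% per-cycle frequency jitter approximates slow-wave
  instability; pure sinusoids are the default because they admit
  closed-form spectral checks. Within-block trial structure (fixation
  dots, cartoons) is deliberately not simulated: the analysis is
  block-level spectra, so within-block event structure cannot affect the
  target computation.
* **Gaze** — fixation-level structure only (no saccade kinematics): an
  initial ~200 ms centre fixation, then gamma-distributed fixations
  (mean 300 ms) whose target is disgust with probability `approach_bias`
  (default 0.7) before 1 s and `avoid_bias` (default 0.3) after, separated
  by 30 ms linear saccades; fixations never straddle the phase boundary,
  so degenerate biases produce exact membership. Blinks are contiguous
  invalid runs (12/min, 250 ms). Validity is an explicit boolean column,
  never sentinel coordinates.
* **Cohort** — ages uniform over 60–167 months, a configurable sibling
  fraction sharing parent ids, and questionnaire items discretised from a
  single latent factor per family so instrument totals correlate at
  ≈ the requested ρ (discretisation costs a few percent of attenuation,
  well inside the ±0.1 recovery tolerance the tests use). Avoidance and
  gastric indices are drawn independently of the questionnaires,
  mirroring the null relations reported in this population.

A green end-to-end test therefore establishes that the pipeline recovers
planted parameters under this stated world — sinusoidal sources, linear
mixing, Gaussian noise, fixation-level gaze. It does not establish
robustness to nonstationary gastric frequency drift, electrode
displacement, correlated sensor noise, smooth pursuit, or calibration
decay; none of these are modelled.

## Numerical conventions and degenerate inputs

* Hampel at a constant signal: MAD = 0 and deviation = 0, so nothing is
  replaced; any nonzero deviation at zero MAD is replaced.
* `component_snr` with zero out-of-band power returns +Inf with a warning
  (in floating point this occurs only for identically zero signals; an
  on-bin tone leaves ~1e-30 numerical dust in the denominator).
* All-zero spectra flag proportions missing rather than dividing by zero.
* Blocks must span at least two normogastric cycles (40 s) for a spectrum.
* Seeds: every generator takes an explicit seed and restores the caller's
  RNG state; equal configs and seeds give byte-identical output.

## Known limitations

* The ICA is a deflation FastICA; source recovery is only guaranteed up to
  sign and permutation, and the SNR screen — not component identity —
  carries the gastric interpretation.
* Edge transients of the zero-phase band-pass are not removed, only
  documented; analyses of blocks shorter than ~2 high-pass periods should
  trim or taper.
* The questionnaire default maps (except TDDS) are synthetic placeholders,
  as stated above.
* The CLI covers the simulate/score/correlate paths and single-recording
  EGG/gaze runs; multi-participant batch orchestration is left to the
  caller.
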