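---
title: "Models and methods of the stressmux pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods of the stressmux pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the generative
model behind the synthetic data, the extraction and statistical procedures,
the parameters that matter, and the decisions taken where the design was
genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The experimental world being modeled

The unit of data is a 195-s trial on a fixed clock: 40 s of resting
baseline, 25 s of preparation with the feet poised over the water, 90 s of
immersion (cold water ~0.6 °C under treatment, ~33 °C under control), and
40 s of recovery. A session comprises five trials (T1–T5); every subject
contributes one treatment and one control session. The analyses live on a
1-Hz grid of 195 points per trial (integer seconds 0–194).

Stress physiology in this paradigm has three temporal signatures the
pipeline must separate:

- *evoked* responses, time-locked to immersion (HR, CO, MAP up; LVET, SV,
  HF-HRV down; pupil dilation; frontal delta/theta power up);
- *anticipatory* responses during baseline/prep of treatment sessions
  (elevated MAP, pupil, central alpha/beta disinhibition);
- *habituation* — shrinking of these responses over repeated exposures.

## 2. The synthetic-data generator

### Effect model

Every continuous measure follows one additive structure per subject `i`,
condition `c`, trial `t`, time `s`:

```
y = baseline_i,c + ant * h_a^(t-1) * 1[s < 65] * 1[c = treatment]
      + ev * h_e^(t-1) * shape(s)  * 1[c = treatment] + noise
```

`baseline_i,c` is the population baseline plus a subject offset
(`between_sd`) plus a session offset (`cond_sd`, modeling day-to-day level
shifts). `shape(s)` ramps linearly over `ramp` seconds after immersion
onset (+`onset_lag`), holds through immersion, and decays exponentially
(`recovery_tau` = 10 s) in recovery. Habituation is multiplicative,
`delta_t = delta * h^(t-1)`, with separate ratios allowed for anticipatory
and evoked components. `noise` is white at 1 Hz.

Population baselines follow the published resting means of a CPT cohort
(HR 66 bpm, PEP 83 ms, LVET 288 ms, SV 37.6 mL, MAP 80 mmHg, log HF 6.35);
the derived measures then land in the right range automatically
(CO ≈ 66·37.6/1000 ≈ 2.5 L/min, TPR ≈ 80·80/2.5 ≈ 2600 dyn s cm⁻⁵). Evoked
magnitudes and habituation ratios are *illustrative defaults* (HR +12 bpm,
h = 0.85, and analogous values per measure): the source literature reports
effect windows and directions, not magnitudes, so these were chosen once as
plausible mid-sized laboratory effects and are not tuned thereafter. The
null configuration (`null_effect_specs()`) zeroes every delta and sets
h = 1 while retaining all variance components; it is the calibration world.

### Waveform rendering

`render_trial()` produces raw signals whose landmarks are known exactly.
These are geometric stand-ins with controllable fiducials, not
biomechanical simulations:

- **ECG** — Gaussian Q (at `r_time − 40 ms`), R, and T waves. Beat times
  come from an inhomogeneous point process with instantaneous rate
  HR(t)/60 and respiratory sinus arrhythmia: RR intervals are modulated
  sinusoidally at the respiration frequency (0.25 Hz, inside the HF band by
  design so HF manipulations are visible to the estimator) with amplitude
  `sqrt(2·exp(hf_log))` ms, which makes band-integrated RR power match the
  HF profile up to estimator bias.
- **dZ/dt** — per beat, a rise with an abrupt slope change exactly at the B
  point (placed at `q_time + PEP`, honoring the field definition of PEP as
  the Q→B interval), peak height `A` at 40% of LVET, and a sharp incisura
  notch whose minimum falls exactly at X = B + LVET. `A` is chosen by
  inverting the Kubicek formula so extraction recovers the true stroke
  volume. One spec example places B at `R + PEP`; that conflicts with the
  PEP = Q→B definition used everywhere else, and the field definition wins
  (see the ledger).
- **Z0** — baseline impedance (25 Ω) plus a 0.2-Ω respiration sinusoid.
- **Pressure** — one pulse per beat with maximum SBP = MAP + 2PP/3 and
  minimum DBP = MAP − PP/3 (PP = 40 mmHg), so MAP = DBP + PP/3 holds.
- **Pupil** — the truth profile at 500 Hz plus noise and Poisson blink
  dropouts (shared across eyes, 0.2–0.4 s).
- **EEG** — 1/f background noise plus four band oscillators (2, 5.5, 10,
  22 Hz) whose amplitudes follow the per-epoch effect structure at
  designated channel groups (frontal for delta/theta, broad for alpha,
  central for beta). Oscillator phase is common across channels within a
  band — a crude stand-in for volume conduction that gives channels the
  high mutual correlation the bad-channel rules assume. Default rates are
  desk-scale analysis rates (250 Hz physio/EEG, 500 Hz pupil), not
  acquisition rates, since the analysis begins after downsampling anyway.

`simulate_study()` has a fast path (`render = FALSE`, the default) that
emits the 1-Hz measure panels directly from the truth profiles plus noise,
skipping waveform synthesis. Large calibration and power simulations use
this path; the rendered path exercises the extraction chain. A green test
on the fast path therefore validates the statistics, not the signal
processing — the two are linked by the construction-consistency tests,
which verify that extracting a noiseless rendered trial reproduces the
truth profiles the fast path draws from.

### What the generator does not emulate

No EMG/ocular artifacts (artifact removal is out of scope), no motion or
electrode drift, no arrhythmias or ectopic beats, no pulse-transit delays
or waveform-shape change under stress, no cortisol circadian curve beyond a
linear within-session decline with an AM/PM level offset. Green tests
establish correctness of the pipeline's contracts on well-formed data, not
robustness to every pathology of real recordings.

## 3. Extraction choices

- **R peaks**: adaptive threshold at 45% of the 99.9th amplitude
  percentile on a lightly smoothed, polarity-corrected trace, 250-ms
  refractory (larger peak wins), peak refined on the raw trace.
- **B point**: maximum of a wide-stencil (±3 samples) second difference of
  the twice-smoothed dZ/dt between R and the ejection peak. The original
  analyses used trained human scorers; an automated slope-change-onset rule
  replaces them deliberately. Under default noise the B/X errors are
  unbiased with σ ≈ 3 ms, giving median absolute PEP/LVET errors within one
  sample (tested).
- **X point**: global dZ/dt minimum in a window after the ejection peak,
  bounded by the next R.
- **Ensemble averaging**: the 15-s window is *centered* on each grid second
  (`[t−7.5, t+7.5)`, half-open on the right); the upstream description says
  only "across a 15 s window". Fiducials are re-extracted from the averaged
  waveforms; grid points with fewer than two beats are masked.
- **Stroke volume**: Kubicek with ρ = 135 Ω·cm, L = 30 cm (configurable).
  The original pipeline delegates SV to its toolbox's internals; Kubicek is
  that family's documented default, and the generator inverts the same
  formula, so the choice is self-consistent rather than validated against
  hardware.
- **MAP** = DBP + PP/3 (the device's internal estimate being unavailable);
  **TPR** = 80·MAP/CO in dyn·s·cm⁻⁵, the constant chosen to give the
  conventional unit scale (~3000).
- **Respiration correction**: Z0 band-passed to 0.1–0.4 Hz, analytic-signal
  phase and envelope, state = z-scored (phase × magnitude) at R times; each
  cardiovascular 1-Hz series is replaced by OLS residuals against the state
  with the subject mean re-added. The recipe is specified upstream for HF
  only and "modeled out" of the rest; the same recipe is reused for all
  cardiovascular measures and is toggleable per measure.
- **HF-HRV**: trailing 32-s windows ending at each grid second; RR
  deviations in ms, mean-centered per window; Lomb–Scargle power integrated
  over 0.15–0.40 Hz at spacing 1/32 Hz; `log(power + 1e-6)`. A window needs
  at least 8 beats. The original used a point-process inverse-Gaussian
  estimator (external code, not described in the source); the trailing
  window, band integration and log transform — the testable contract — are
  preserved, and the estimator sits behind one function so the point-process
  variant could be added later. The upstream unit label "ms²/Hz" names a
  density while describing band power; band-integrated power (ms²) is
  computed and the label kept in docs.

## 4. Pupil and EEG choices

- Pupil normalization is min–max per subject across both sessions *jointly*
  (the upstream text says only "normalized between 0–1"); joint scope
  preserves condition differences, which the downstream analyses need.
  Gaps ≤ 1 s are bridged linearly before 1-s binning (common practice; the
  source is silent); bins over 50% missing are masked; 5-s smoothing is for
  visualization only and the statistics path refuses smoothed panels.
  Normalize-then-baseline-correct is the implemented order (switchable by
  applying the steps manually).
- Bad channels: flatline ≥ 5 s; SD > 4 × the median channel SD
  (operationalizing "four standard deviations of the total channel
  population"); reconstruction correlation ≤ 0.85 (inverse-square-distance
  weighted average of the other channels).
- Spherical-spline interpolation uses Perrin-style splines (m = 4, 20
  Legendre terms) on schematic unit-sphere 10–20 coordinates.
- ERSP: Hann-tapered 1-s windows hopped at 1 s (1-Hz resolution both ways),
  1–30 Hz. The source toolbox's "4 Hz moving window" is ambiguous; it is
  read here as spectral smoothing — powers averaged over a 4-bin frequency
  neighborhood — and flagged as an interpretation, not asserted as the
  original meaning. dB correction divides by the same trial's mean power
  over baseline seconds 1–40 per channel × frequency; the baseline period
  itself is summarized as raw log power.
- The EEG channel count defaults to 16 (10–20 labels, configurable);
  topographic claims are tested on designated channel groups, not
  interpolated scalp maps.

## 5. The statistical framework

At each in-scope second, a 2 (condition) × 5 (trial) within-subject ANOVA is
computed from cell means, each effect tested against its own
subject-by-effect error term; partial eta squared is
`SS_effect/(SS_effect+SS_error)`. p-values are permutation-based:

- **condition** and **interaction**: each subject's condition labels are
  swapped with probability ½ (equivalently, sign flips of the subject's
  condition-difference profile — implemented in closed form so 500–1000
  permutations per timepoint cost one small matrix product);
- **trial**: trial labels permuted within subject × condition;
- **pairwise contrasts**: sign-flip paired t, two-sided by default (the
  upstream sidedness is unstated; its text is directional, and sidedness is
  an argument).

The permutation scheme shuffles *the factor under test* so each null is
exchangeable under its own hypothesis; the upstream description mentions
only condition-label shuffling. `p_null` counts null statistics ≥ the
observed one over the number of iterations, without adding the observed
value to the null set; the ≥ comparison carries a 1e-9 relative tolerance
so that a permutation which regenerates the observed statistic exactly
(e.g. the identity sign pattern) counts as a tie regardless of
floating-point route. With this convention the chance of `p_null < 0.05`
at 500 permutations is 25/501 ≈ 0.0499 — slightly conservative.

The *raw* analysis covers seconds 0–64 (anticipatory effects); the
*baseline-corrected* analysis subtracts each trial's mean over the final
15 s of baseline (seconds 25–39) and covers seconds 65–194 (evoked
effects). Pairwise contrasts T1vT5 / T1vT3 / T3vT5 are computed per
condition only at timepoints where the interaction's `p_null < α` (gating,
asserted by construction and by test). No correction across timepoints is
applied — inference rests on consistent runs, not single seconds — and an
optional minimum-run-length contiguity filter (default off) is provided.
Timepoints with more than 25% of subjects masked are excluded; otherwise
incomplete subjects are dropped listwise at that timepoint. One master seed
drives everything; per-timepoint streams are derived deterministically so
tracks are reproducible and timepoints independent.

The three-way baseline-shift analysis pairs each subject's pre-exposure
baseline mean with a trailing 15-s moving average at each second 65–140 and
runs a 2 × 2 × 5 within-subject ANOVA; condition-bearing effects are
permuted by condition swaps, baseline-bearing effects by pre/during swaps,
and the trial main effect by trial permutation.

Scalar analyses reuse the same machinery: pain (2 × 5, contrasts skipped
for a condition with near-zero difference variance, mirroring floor-level
control ratings), pupil averaged over immersion seconds 66–155, EEG bands
per electrode with follow-up contrasts averaged over the electrodes that
contributed a significant interaction, and cortisol as a mixed 2 (condition)
× 3 (sample) ANOVA with AM/PM start time between subjects (group effects
permuted by group-label shuffles). One upstream mention of a "rank order
analysis" has no referent elsewhere and is not implemented.

## 6. Numerical and engineering notes

- Zero-error-SS ANOVA cells yield `F = Inf` when the effect SS is positive
  and `F = 0` when it is zero.
- All filters are zero-phase FFT constructions (offline pipeline).
- The ANOVA engine is validated two ways: a brute-force loop-coded
  sums-of-squares oracle (to 1e-10 relative error on random tables) and
  `stats::aov` with the matching `Error()` strata; the vectorized sign-flip
  formulas are checked against the observed F under the identity
  permutation, and Monte-Carlo paired-t p-values against exhaustive
  enumeration at n = 5.
- Runtime scaling: the acceptance calibration (500 studies × 90 immersion
  seconds × 500 permutations) runs the condition effect only, via the
  closed-form sign-flip path (~4 min on one CPU). Trial-label permutation
  is the loop-bound slow path and is exercised at full scale in the
  criterion-6 power run and at reduced `n_perm` elsewhere.

## 7. Known limitations

HDF5 and EDF containers are not read (no reader in the supported
dependency set); CSV containers are. ICA-based artifact rejection is out of
scope; the three upstream acceptance constants for component retention are
documentation for users who pre-clean externally. The B-point rule is an
automated substitute for human scoring and has only been validated against
the package's own renderer. Cortisol values mirror the qualitative pattern
(session decline, AM > PM) without targeting published magnitudes. The
split-plot cortisol ANOVA assumes (near-)balanced AM/PM groups, which the
generator's alternation guarantees for even n.
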