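---
title: "Tracking hemorrhage and resuscitation from the arterial waveform"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking hemorrhage and resuscitation from the arterial waveform}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Hemorrhagic shock is the leading cause of preventable trauma death, and the
vital signs clinicians watch — mean arterial pressure (MAP) above all — are
late indicators: the circulation defends MAP through vasoconstriction and
tachycardia until a large fraction of the blood volume is already gone.
`hemotrace` implements a pipeline that estimates *how much* blood has been
lost, and how far resuscitation has progressed, from beat-to-beat morphology
of the arterial pressure waveform rather than from its mean level.

The pipeline has five stages, each a package module with its own tests:

1. **Synthetic data** — a controlled swine hemorrhage/resuscitation
   generator and a stepwise lower-body-negative-pressure (LBNP) generator.
2. **Waveform processing** — resampling to 100 Hz, a 512th-order FIR lowpass
   at 6 Hz, optional 5th-order polynomial detrending, and beat segmentation
   with five pulse landmarks.
3. **Feature bank** — more than 4200 named per-beat features.
4. **Ground-truth metrics** — BLVM, PEBL, HemArea, CRM.
5. **Modeling and evaluation** — MRMR feature ranking, gradient-boosted
   regression trees, leave-one-subject-group-out (LOSO) cross-validation,
   and percentile-sweep ROC / detection-time / resuscitation statistics.

## The simulator: what it emulates, and what it does not

Real records of this kind live in restricted databases, so the package
ships a generator whose outputs have the statistical structure the analysis
needs. The protocol it emulates per subject:

* **baseline** — 600 s of stable recording (long enough to estimate
  5th-percentile baseline thresholds and 5-minute windows);
* **hemorrhage** — a proportional feedback bleed (bounded by 30–200 mL/min,
  evaluated every 5 s, the volume-log cadence) until the windowed MAP
  reaches the 35 mmHg target;
* **hold** — 300 s at the target with small corrective bleeds, a
  fixed-duration stand-in for a lactate-triggered endpoint (lactate itself
  is not modelled; the trigger only sets the hold length);
* **whole-blood resuscitation** — proportional infusion until MAP reaches
  65 mmHg, held to the end of the record (at least 330 s), with the total
  infusion capped at 80% of the shed volume so the final blood balance
  stays below its pre-hemorrhage value (final BLVM < 1).

Waveform morphology is driven by the blood-volume **deficit fraction**
`d = (shed − infused) / (60 mL/kg × weight)`: pulse pressure falls linearly
in `d` (floored at 25% of baseline), heart rate rises linearly in `d`, and
MAP follows a *compensated-shock* response — flat until `d` exceeds a
dead-zone of 0.08, then falling linearly. The dead-zone is the textbook
physiology of compensated hemorrhage (baroreflex defence of MAP) and is the
mechanism by which morphology-based metrics can flag blood loss before MAP
moves. Weights are drawn uniformly from 40–60 kg, typical for research
swine; subject-level jitter (±2 bpm, ±1.5 mmHg pulse pressure, ±2 mmHg MAP)
provides between-subject variability, which the source protocol does not
quantify — these variances are free choices of the generator.

Each beat is a sum of a half-cosine systolic upstroke, a concave quadratic
diastolic decay, and a Gaussian dicrotic wave. The concave decay is
deliberate: with the dicrotic lobe present the downstroke has a genuine
second-derivative zero crossing (the "first inflection point" landmark);
with the lobe suppressed (`dicrotic_amp = 0`) there is none, which
exercises the half-drop fallback in landmark detection. Additive slow
sinusoidal drift (1.5 mmHg, 600 s period) and white noise (1 mmHg SD)
emulate baseline wander and measurement noise.

What the generator does **not** emulate: arrhythmias and motion artifacts,
lactate chemistry and anesthetic depth, re-bleed or crystalloid phases
after whole-blood resuscitation, and the hardware controllers' internal
decision tables (only their MAP-target behaviour matters here). Passing
tests on this cohort therefore demonstrate that the pipeline's machinery is
correct and self-consistent at realistic signal scales — not that the
trained models would transfer to in-vivo data.

## Signal processing choices

* Analog pressure (500 Hz) is downsampled to 100 Hz behind an anti-alias
  lowpass; volume logs (one tick per 5 s) are upsampled to 100 Hz by linear
  interpolation.
* The 512th-order FIR lowpass (6 Hz cutoff) uses a Hamming window — the
  conventional default where only "window lowpass" is specified — with
  coefficients normalized to exact unit DC gain. Group-delay compensation
  (a 256-sample shift) with reflective edge padding keeps the output
  time-aligned and equal-length; this preserves the specified order and
  linear phase, where forward–backward filtering would square the response.
* Filtering precedes detrending and landmark detection in both signal
  variants; the detrended variant subtracts a least-squares 5th-order
  polynomial fit over the full record.
* Beat feet are local minima preceding steep upstrokes, found with a
  blockwise-adaptive slope threshold (0.35 × the local 10 s maximum slope,
  so detection survives the shrinking pulses of deep shock) and a 0.25 s
  refractory period (caps detectable heart rate at 240 bpm, above any
  simulated value). The inflection search excludes the two samples next to
  the following foot, where the slope corner would otherwise fake a
  second-derivative sign change. Malformed beats (non-monotone landmark
  order or pulse pressure below 1 mmHg) are skipped and counted.

## The feature bank

The original feature list at this scale is proprietary; the bank here is a
documented reconstruction of the same categories and size, and the
analysis depends on the pipeline's shape and scale rather than on any
specific column:

| layer    | count | content |
|----------|------:|---------|
| base     |    48 | landmark amplitudes and relative times, all pairwise amplitude differences and time intervals, chord slopes, trapezoidal areas above the foot, beat duration/heart rate/pulse pressure, sample moments, extreme slopes |
| pairwise |  4512 | all C(48,2) differences and products, all 48×47 directed ratios (denominators below 1e-9 yield 0 rather than losing the beat) |
| spectral |    16 | magnitudes and phases of the first 8 DFT harmonics of the mean-removed, duration-normalized beat |
| trailing |   288 | trailing mean/SD/slope of each base column over 10- and 50-beat windows (edges use available history) |

Total: 4864 named columns, identical across subjects by construction, so
train and test matrices align by name. Non-finite entries are imputed with
the previous valid beat's value (0 when none exists) and counted.

## Ground-truth metrics

* **BLVM** (blood loss volume metric, 0–1): `1 − shed(t)/total_shed` while
  blood is being lost; from the point of maximum loss onward the infused
  whole-blood volume is *added*, so the balance recovers during
  resuscitation. The infusion cap keeps the final value below 1. The
  "point of maximum loss" is the global maximum of the shed curve; small
  corrective bleeds during the hold therefore accrue to the loss term, not
  the recovery term.
* **PEBL** (percent estimated blood loss): net balance over the estimated
  blood volume, 60 mL/kg for swine (80 mL/kg is the canine constant and is
  available as a parameter). Net balance — infusion "gives back" shed
  blood — is what lets PEBL fall during resuscitation.
* **HemArea**: the running time-integral of net blood loss (mL·min),
  computed directly; the legacy indirect form (summing `|BLVM − 1|·Δt`)
  is also provided and equals the direct integral divided by the total
  shed volume, an identity the tests verify.
* **CRM** (compensatory reserve): `1 − LBNP/LBNP_HDD` on the LBNP cohort.
  No swine CRM ground truth exists (decompensation is undefined in this
  protocol), so the swine-side CRM evaluation is trend-only.

Predictions are smoothed with a 50-point *trailing* moving mean — a
centered window would use future data in a would-be real-time metric — and
smoothing is applied to predictions only, not to ground truth. Metrics are
computed at 100 Hz and sampled at beat (foot) times so that targets align
with per-beat features.

## Modeling choices

* **MRMR variant**: mutual-information quotient (MIQ) — relevance
  `MI(f, y)` divided by mean redundancy against the already-selected set —
  with plug-in MI on 16 equal-frequency bins, ties broken by lexicographic
  feature name. The upstream toolbox's exact estimator is unpublished, so
  the tests pin this implementation to an independent brute-force greedy
  oracle on dozens of random instances instead.
* **Boosted trees**: least-squares gradient boosting — mean initialization,
  each cycle fitting a depth-6, minimum-leaf-8 regression tree (rpart,
  `cp = 0`) to the residuals, shrunk by a 0.1 learning rate, 30 cycles.
  The per-cycle training RMSE is logged and is provably non-increasing for
  shrinkage below 2. Depth 6 is a choice; the leaf size, rate and cycle
  count are the protocol constants.
* **LOSO**: 4 groups of 3 subjects; for each fold the three training
  groups are concatenated, MRMR is rerun *on the training groups only*
  (ranking on pooled data would let the held-out subject bias the feature
  list), the top 20 features are fixed, and each held-out subject is
  blind-tested separately — 12 records per metric. Equal-frequency bin
  boundaries for MI are likewise computed from training rows only.

## Evaluation choices

* ROC curves sweep 100 thresholds across the 5th–95th percentile of the
  metric over baseline + initial hemorrhage (the hold and resuscitation
  are excluded), computed per subject and then averaged. Orientation is
  fixed a priori by physiology: BLVM, CRM and MAP fall under hemorrhage;
  PEBL and HemArea rise.
* Detection time: the 5th percentile of the baseline readings (95th for
  rising metrics) must be exceeded for 100 consecutive beat-level
  readings; "readings" are per-beat smoothed predictions, so 100 readings
  is roughly a minute at simulated heart rates. Non-detecting records
  score the full hemorrhage-window duration (hemorrhage onset to
  resuscitation start).
* Resuscitation responsiveness: mean over the final 5 min of whole-blood
  resuscitation divided by the mean over the 5 min before it;
  resuscitation-region goodness of fit is reported trend-only. The
  coefficient of variation (100·SD/mean) summarizes the spread of the
  ratios across blind tests.
* HemArea RMSE is reported normalized by the maximum truth value over the
  whole LOSO process, since an unbounded integral has no natural scale.

## Problem sizes and determinism

The default cohort — 12 subjects, ~1900–2100 s records at 100 Hz, roughly
3–4 thousand beats each — was chosen so the full pipeline (simulation,
processing, 4-fold MRMR over the 4864-column bank, boosting, evaluation)
completes in well under half an hour on a single core, while still giving
every window-based statistic its full-length inputs. All randomness flows
from one master seed through per-subject seeds; rerunning any stage with
the same configuration reproduces its outputs bit for bit.

## Known limitations

* The feature bank reconstructs categories and scale, not the proprietary
  list; selected-feature identities are therefore not comparable to the
  original study, only the pipeline's behaviour is.
* Because every simulated quantity is ultimately a function of the deficit
  fraction plus noise, blind-test R² on synthetic cohorts is higher than
  could be expected on in-vivo data; the acceptance checks treat these as
  lower-bound sanity thresholds, not as performance claims.
* CRM transfer is evaluated only against MAP trends — exactly the
  situation with real swine data, where decompensation is undefined.
* The half-drop fallback fires rarely on filtered full-pipeline beats (the
  6 Hz lowpass smooths most dicrotic suppression back into an inflection);
  it is exercised directly on raw template beats in the tests.

## Reproducing the numbers

`scripts/acceptance.R --seed <s> --out <path>` reruns the whole pipeline —
cohort simulation, processing, LOSO training for BLVM and PEBL, the LBNP
CRM transfer — and writes the headline quantities as JSON. The
`analysis/` directory holds the same computation split into numbered,
narrated stages that persist intermediate tables under `results/`.
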