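---
title: "Multi-domain features and progressive-learning fusion for hybrid EEG-fNIRS decoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-domain features and progressive-learning fusion for hybrid EEG-fNIRS decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The decoding problem

Hybrid brain-computer interfaces record electroencephalography (EEG, scalp
potentials with millisecond resolution) simultaneously with functional
near-infrared spectroscopy (fNIRS, slow cortical haemodynamics measured as
dual-wavelength light attenuation). The two modalities carry complementary
views of the same neural event: a motor-imagery or mental-arithmetic task
attenuates sensorimotor rhythms in the EEG within tens of milliseconds,
while oxygenated haemoglobin (HbO) rises and deoxygenated haemoglobin (Hb)
falls over several seconds. `hybridbci` implements a complete two-class
decoding chain for such recordings and a decision-level fusion scheme —
two-stage *progressive* (stacked) learning — that combines per-modality
classifier outputs instead of raw features.

The classification unit throughout is the **1-second subtask**: each trial
contributes a 2-s visual instruction, a 10-s task-execution period cut into
ten half-open 1-s windows, and a 15–17 s rest. With the standard protocol of
3 sessions x 20 repetitions this yields 200 subtasks per session and 600 per
subject.

## Preprocessing chains

EEG: common average reference, then a forward-only 4th-order Chebyshev
type II band-pass with 40 dB stop-band attenuation and stop-band edges at
0.25 and 60 Hz (pass band 0.5–50 Hz), then decimation to 200 Hz, epoching
`[0, 12)` s from instruction onset, and subtask segmentation. EEG epochs are
*not* baseline-corrected; only the fNIRS chain is, because a chromophore
trace is a change measure with an explicit reference period while broadband
EEG is already zero-mean after band-passing.

fNIRS: decimation to 10 Hz, conversion of the dual-wavelength intensities to
HbO/Hb concentration changes (micromolar) by the modified Beer–Lambert law
(MBLL), a 3rd-order **zero-phase** Butterworth band-pass at 0.01–0.09 Hz
that suppresses cardiac (~1 Hz), respiratory (~0.2 Hz) and Mayer-wave
(~0.1 Hz) oscillations, epoching, baseline correction over the 2-s
instruction period, and subtask segmentation. Zero-phase filtering matters
here because the analysis windows are short relative to the group delay a
causal narrow-band filter would introduce.

Independent-component-based ocular artifact removal is intentionally out of
scope; an optional peak-to-peak amplitude screen (`reject_amplitude()`,
default off, 150 uV when enabled) stands in as a deterministic, dependency-free
alternative.

Numerical choices worth knowing about:

* **Resampling** is done in-package: odd-reflection padding, an 8th-order
  zero-phase Butterworth anti-alias filter at `0.8 * fs_new / 2`, zero-stuffed
  upsampling by `p` and decimation by `q` for any rational ratio `p/q`.
  Off-the-shelf resamplers in the available signal stack zero-pad their
  edges, which corrupts the ends of non-zero-mean physiological signals; the
  reflection padding keeps a DC signal flat to ~1e-9.
* **Event re-indexing** after decimation uses `floor(onset * fs_new / fs)` —
  deterministic and documented rather than round-to-nearest.
* **MBLL defaults**: differential pathlength factor 6.0 at both wavelengths,
  source–detector distance 3.0 cm, extinction coefficients for 760/850 nm
  from a standard tabulation. These are configuration, not ground truth; any
  invertible 2x2 extinction matrix can be supplied.
* The forward and inverse MBLL are exact linear inverses of each other; the
  test suite asserts the round trip to 1e-9 relative error.

## Multi-domain features

**Time domain** — six statistics per channel per subtask: mean, population
variance (denominator `N`), mean absolute first difference (denominator
`N-1`), the same normalised by the standard deviation, mean absolute second
difference (denominator `N-2`), and its normalised version. `0/0` is defined
as 0 for constant windows.

**EEG frequency domain** — differential entropy (DE) over 0.5–45 Hz. For a
Gaussian source the DE has the closed form `log(2*pi*e*sigma^2)/2`; the
band-limited variance `sigma^2` is estimated as the mean Hann-tapered
periodogram power inside the band, and the entropy is reported in nats
(natural log). The estimator converges to the closed form as the window
grows; the suite checks 0.02 nat agreement at n = 1e5. A zero variance
estimate is floored at machine epsilon with a warning. A named list of
sub-bands (e.g. the canonical delta/theta/alpha/beta/gamma split) may be
supplied; the default is the single 0.5–45 Hz band because nothing in the
decoding chain requires finer resolution.

**fNIRS frequency domain** — periodogram power spectral density
`P(w) = |DFT(x)|^2 / N` averaged over 0.01–0.1 Hz for every HbO and Hb
channel. A 1-s window at 10 Hz cannot physically resolve 0.01–0.1 Hz
oscillations: its native spectral grid has no point inside the band. The
default (`psd_scope = "subtask"`) therefore evaluates the periodogram on a
zero-padded 1024-point grid, which places interpolated grid points inside
the band; the feature then measures the near-DC energy of the
baseline-corrected window, which is exactly where a haemodynamic response
expresses itself in a 1-s excerpt. The alternative `psd_scope = "epoch"`
computes the PSD once over each trial's full 10-s task period and assigns it
to the trial's ten subtasks. Note the deliberate asymmetry: the chromophore
band-pass stops at 0.09 Hz while the PSD band extends to 0.1 Hz; both edges
are configurable and the defaults keep the conventional values of each step.

**Normalisation** — features are Z-scored with population standard
deviations; constant columns map to 0. `zscore_fit()` accepts an explicit
fit partition so the normaliser can be estimated on training rows only
(leakage hygiene). The pipeline report fits globally, because its
per-condition numbers are 8-fold cross-validated and a per-fold normaliser
would change the condition definition, not the ordering the report is about.

## Feature selection by atom search optimisation

Multi-domain concatenation breeds redundancy, so the combined per-modality
matrix is pruned by a wrapper selector built on atom search optimisation
(ASO), a physics-inspired swarm method. Each atom's position in `[0,1]^D`
encodes a feature subset (coordinates above `selection_threshold = 0.5`
switch features on — plain thresholding, not a sigmoid transfer, because it
is the simplest deterministic mapping). Atoms interact through:

* a Lennard-Jones-style interaction force from the `K(t)` current-best
  neighbours, `K(t) = ceiling(N - (N-2) * sqrt(t/T))`, with depth
  `eta(t) = alpha * (1 - (t-1)/T)^3 * exp(-20 t/T)` and scaled distances
  clipped to `[1.1 + 0.1 sin(pi t / (2T)), 1.24]`;
* a bond-length constraint force toward the best atom,
  `lambda(t) * (x_best - x_i)` with `lambda(t) = beta * exp(-20 t/T)`;
* masses `M_i = exp(-(Fit_i - Fit_best)/(Fit_worst - Fit_best))`, normalised
  to sum to one, so better solutions move less and refine locally.

Defaults: `alpha = 50`, `beta = 0.2`, `N = 20` atoms, `T = 50` iterations.
One naming caveat: the decoding literature uses lambda for the learning
models while the ASO literature uses `lambda(t)` for the constraint
multiplier; in this package the former are *learners* and the latter is the
`multiplier_weight` schedule.

The wrapper objective is
`(1 - acc_cv) + fitness_penalty * n_selected / n_features`, where `acc_cv`
is the stratified 5-fold cross-validated accuracy of a fixed-seed 100-tree
random forest on the masked columns (`fitness_penalty = 0.01`). The
objective, swarm size and iteration budget are package decisions — wrapper
selection needs *some* internal classifier, and the random forest matches
the classifier used for the single-modality comparisons. Every selection is
bit-reproducible from its seed and the best-so-far trace is monotonically
non-increasing by construction.

## Progressive-learning fusion

Per modality, the selected features are split 8:2 (stratified, seeded, the
*same* split for both modalities so rows stay paired). The 80% part is cut
into `k = 8` stratified folds. Four primary learners — a 100-tree random
forest, depth-wise gradient-boosted trees, AdaBoost over decision stumps,
and leaf-wise-grown histogram gradient boosting (the LightGBM-style growth
strategy, run through xgboost's `lossguide` mode) — each produce:

* `A_t`: out-of-fold predictions for every training row, assembled in
  original row order, so no entry comes from a model that saw that row (the
  suite audits this with a memorising learner);
* `B_t`: the average of the 8 fold-models' predictions on the 20% test rows.

Concatenating EEG and fNIRS blocks column-wise gives the meta-feature
matrices (`EEG_A1..A4, fNIRS_A1..A4`), on which a logistic regression is
trained and evaluated. Primary outputs are positive-class probabilities by
default — richer meta-features than hard labels, which remain available via
`meta = "labels"`. Learner hyperparameters are library defaults with fixed
seeds, snapshotted in the result object. The reported accuracy averages
`n_repetitions = 5` independent 8:2 splits (mean and standard deviation);
repeated splits are the honest way to quote a single-subject accuracy when
the outer test set holds only ~120 subtasks. Cross-modality information
meets only at the meta level: each primary learner sees exactly one
modality's rows.

The **direct-splicing baseline** concatenates the two selected feature
matrices and classifies them with the random-forest learner under stratified
8-fold cross-validation — the conventional feature-level fusion this
framework is meant to beat.

## The synthetic generator

`generate_dataset()` emulates the statistical structure the chain is built
for, not the biophysics of a head model:

* shared trial timeline: per session, balanced class labels in random order,
  2 s instruction + 10 s task + uniform 15–17 s rest, 15 s of padding at the
  session edges;
* EEG: per-channel 1/f background plus white noise and a common 10 Hz
  rhythm whose amplitude drops by `1 - effect_size` during task windows on
  the class-dependent half of the channels (an event-related
  desynchronisation surrogate);
* fNIRS: a canonical double-gamma haemodynamic response (gamma peaks at 6 s
  and 16 s, undershoot ratio 1/6, unit peak) convolved with the class's task
  boxcar, HbO positive on the responsive channel half with `Hb = -HbO/3`
  (a typical empirical ratio), plus cardiac/respiratory/Mayer sinusoids and
  white noise, all scaled by `noise_sd`, emitted as strictly positive raw
  intensities through the forward MBLL around baseline intensity 1.0.

EEG is generated at 250 Hz by default so simulations stay light;
`paper_rates = TRUE` switches to the 1000 Hz / 12.5 Hz acquisition rates and
exercises the exact 5:1 and 5:4 decimation ratios. All randomness flows from
one seed through fixed per-stage offsets, so the two streams share an event
sequence and every run is bit-reproducible.

What the generator does **not** model: volume conduction and optode
geometry, inter-subject variability, motion and ocular artifacts,
non-stationary rhythm dynamics. Passing the end-to-end checks therefore
demonstrates that the chain recovers class structure it is designed for and
stays at chance when none exists — not that any particular accuracy carries
over to real recordings. One caveat inherited from the field's standard
protocol: subtasks of one trial share slow background activity, and splits
are drawn at the subtask level, so absolute synthetic accuracies are
optimistic in the same way subtask-level cross-validation is on real data.

## Problem sizes and degenerate inputs

The test suite and the acceptance script run desk-scale versions of every
experiment, chosen as the package's own trade-off between statistical
resolution and a single-CPU run: 8 EEG + 8 fNIRS channels for the end-to-end
cohorts (600 subtasks), an 8-atom / 8-iteration selection budget there,
3 fusion repetitions, the sphere benchmark at `N = 20, T = 100` over 10
seeds, and the planted-feature recovery task (5 informative / 20 noise
columns, n = 200) at `N = 10, T = 10` over 10 seeds. The high-signal cohort
uses `effect_size = 0.9, noise_sd = 0.5`; the null cohort sets
`effect_size = 0`.

Degenerate inputs have defined behaviour rather than NaNs: constant feature
columns z-score to 0, zero variance floors the DE at machine epsilon with a
warning, an empty selection mask is repaired to the single largest
component, folds that would be single-class are redrawn with the next seed
(at most 10 times), and a constant meta-feature matrix falls back to the
majority class. Random-forest prediction ties are broken with a pinned seed
so identical configurations reproduce reports byte-for-byte.

## Limitations

* The chain is binary; multi-class paradigms need a different meta-learner.
* Wrapper selection is the computational bottleneck (each fitness
  evaluation is a 5-fold forest fit); the swarm and iteration budget should
  be scaled to the feature count.
* The fNIRS subtask PSD is a near-DC energy measure, not a resolved
  spectrum; treat its "band" semantics accordingly.
* Loaders for vendor formats (EDF, SNIRF, MATLAB toolbox containers) are out
  of scope; the interchange format is deliberately plain CSV + JSON.
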