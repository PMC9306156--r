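---
title: "Methods: synthetic HD-EMG, channel selection and online control simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic HD-EMG, channel selection and online control simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its models and numerical
choices: what the synthetic generator emulates and what it deliberately
does not, the definition of every processing stage, the parameters that
matter with their defaults and units, and the design decisions taken where
several reasonable options existed. Nothing here states an empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## The problem

Myoelectric gesture interfaces classify surface EMG patterns into hand
gestures. Two practical factors make this hard. First, the forearm muscles
that drive the fingers also move the wrist, so rotating the wrist
(pronation/supination) shifts the spatial pattern of muscle activity under
the electrodes and inflates the within-class variability when one class
must cover all wrist positions. Second, dense electrode grids give the
spatial resolution to find informative recording sites, but a deployable
device wants few channels. The package implements the full chain needed to
study this trade-off: simulate grid recordings, extract features, select
channels, classify, quantify class separability, and simulate the online
control task that measures what offline accuracy alone cannot.

## The electrode model

`build_default_layout()` defines 256 monopolar channels on four 8×8 grids
with 10 mm pitch. Grids 2–4 ring the proximal forearm and jointly tile 24
circumferential columns; grid 1 sits on the distal ventral forearm. The
cylinder has circumference 24 × 10 mm (radius ≈ 38.2 mm); θ advances by
2π/24 per ring column and z grows by 10 mm per row toward the elbow.

Three conventions are fixed, documented constants rather than empirical
claims, because the physical montage admits several equally valid
indexings:

* row 1 of each grid is its distal edge, so "row 4" of the proximal grids
  counts from the distal edge and "immediately below" a row-4 channel
  means row 5 of the same column (one row toward the elbow);
* ring column 1 is anchored at grid 2, column 1. Any fixed anchor
  preserves the equidistance of the circumferential selection;
* grid 1 shares grid 2's θ-arc and occupies z ∈ [−80, −10] mm.

The circumferential placement (`circ_select()`) takes every third ring
column of row 4 — eight channels 30 mm apart. A corrupted member is
replaced by the channel immediately below; only this single fallback level
exists, so two stacked corrupted channels are an error rather than a
silent re-selection.

## The signal generator

`simulate_task()` synthesises one task recording as

    x_c(t) = Σ_k w_ck · s_k(t) · a(t) + b · n_c(t),

where the sum runs over the gesture's hot spots, `s_k` are independent
unit-RMS Gaussian sources band-limited to 10–500 Hz, `a(t)` is the
activation profile (fraction of MVC), `b` is the baseline noise RMS and
`n_c` is band-limited unit-RMS channel noise. The spatial weights are
Gaussian in the geodesic cylinder distance, w_ck = A_k exp(−d(c,k)² /
(2σ²)). Corrupted channels carry 20 × baseline noise instead of signal.
Because nearby channels share sources, their signals are correlated — this
is what makes channel selection a non-trivial problem, as one channel can
stand in for its neighbours.

Defaults, chosen once for physiological plausibility:

| parameter | default | meaning |
|---|---|---|
| `fs` | 2048 Hz | sampling rate |
| `baseline_noise` | 2 μV RMS | instrumentation/rest noise floor |
| `snr` | 150 | hot-spot RMS at MVC over baseline RMS (≈300 μV at MVC) |
| `spatial_sigma` | 15 mm | spatial spread of a hot spot (1.5 electrode pitches) |
| `wrist_dcol`, `wrist_dz_mm` | +2 columns, −10 mm | hot-spot shift under pronation (mirrored for supination) |
| `corrupted_gain` | 20 | corrupted-channel noise multiple |
| `jitter_col_sd`, `jitter_z_sd` | 0 | per-session hot-spot jitter ("subject anatomy") |

The `snr` default deserves a comment: surface EMG at maximal contraction
reaches a few hundred μV RMS against a noise floor of a few μV, and the
segmentation rule below thresholds at 10% of the measured MVC. That rule
is only meaningful when 10% of the channel-averaged MVC amplitude exceeds
the noise floor, which constrains realistic `snr` values to roughly ≥100.
The hot-spot table (`default_gesture_model()`) gives each of the seven
active gestures three spots — flexor-side columns for the grasps,
dorso-lateral columns for pointing and hand-open, a few spots on the
distal grid — such that every gesture pair differs in at least one spot.
Rest has none.

The activation profile (`make_activation_profile()`) is two trapezoids —
1-s ramps, 4-s plateaus at 30% and 60% MVC, 5-s separation, 17 s in total.
MVC recordings are 3 s of sustained full activation; the session MVC is
*measured* from them by `compute_mvc()` (mean channel-averaged 250-ms RMS),
not copied from the configuration, mirroring how MVC is obtained in
practice.

What the generator does **not** model: motor-unit physiology and
recruitment, fatigue, force-feedback dynamics, electrode shift between
sessions, and — most importantly for interpreting the online results — an
adaptive subject. Passing tests on this benchmark therefore demonstrate
that the pipeline recovers the structure the generator encodes (spatially
distinct, wrist-shifted, amplitude-scaled sources); they do not establish
performance figures for real recordings.

## Preprocessing

Offline filtering is a zero-phase (forward–backward) 2nd-order Butterworth
band-pass, 10–500 Hz, so that group delay does not bias onset detection;
the causal single-pass variant exists for streaming use. The envelope is
the per-channel RMS over 250-ms windows plus its cross-channel average,
which doubles as the muscle-activation estimate.

Segmentation finds contractions where the channel-averaged envelope
crosses 10% of the MVC. The envelope hop is 125 ms (half-window): the
protocol fixes only the window length, and a half-window hop is the
natural resolution of the subsequent feature windowing. The contraction
*offset* is not defined by the protocol; the package ends a contraction at
the first window after which the envelope stays below threshold for two
consecutive windows — a hysteresis that ignores single-window dips. The
two segments of a task are labelled low/moderate by order, matching the
profile design. Rest recordings contribute one 4-s segment (taken from 1 s
onward, away from the recording edge).

## Features and splitting

Per 250-ms window and channel, five time-domain features: MAV, ZC, SSC,
WL, LogVar (natural logarithm of the variance, floored at 10⁻¹² μV² so
constant windows stay finite). The ZC/SSC counts use an amplitude deadband
ε; the protocol literature uses a noise deadband without giving a value,
so the default is 1% of the window RMS, and ε = 0 recovers the plain
analytic definitions used in the unit tests. Windows overlap 50%, and the
window count for a segment of L samples is ⌊(L−W)/H⌋+1.

Class labels are the gesture only — windows of the same gesture at
different contraction levels, and (in combined mode) wrist positions,
share one class. The 70/30 holdout split stratifies on the composite
(gesture × wrist × level) stratum, so each merged class's sub-conditions
are covered proportionally on both sides.

## Shrinkage LDA

The classifier is Gaussian with shared within-class covariance; class k
scores δ_k(x) = xᵀΣ̂⁻¹μ_k − ½μ_kᵀΣ̂⁻¹μ_k + ln π_k, equal priors by default
(the design is balanced). The pooled covariance is shrunk toward its own
diagonal, Σ̂ = (1−λ)S + λ·diag(S), with λ = 10⁻³ raised automatically by
factors of 10 (up to 0.1) if factorisation fails; an explicit λ = 0 fails
hard with advice instead.

The diagonal target is a deliberate design decision. The five time-domain
features live on wildly different scales — waveform length of an active
channel is of order 10⁴ μV while log-variance is of order 1 — and a ridge
toward a *scaled identity* adds the same variance to every coordinate,
which drowns the small-scale features entirely (on the default benchmark
this single choice is the difference between ~72% and ~99% test accuracy
with the same information available). Shrinking toward diag(S) is
equivariant under per-feature rescaling, so no feature normalisation is
needed anywhere — consistent with LDA's affine invariance.

## Sequential forward selection

The SFS wrapper greedily adds one *feature column* per step, the one
maximising mean 10-fold cross-validated LDA accuracy of the
selected-so-far set plus that candidate. Details that the protocol leaves
open, fixed as follows:

* the candidate pool is every not-yet-selected feature column; the CV
  classifier during selection uses only the selected columns. The
  all-five-features-per-channel expansion applies *after* selection —
  features are mapped back to parent channels, and a feature whose parent
  is already selected is still accepted if it wins the step (so the
  channel count can lag the feature count), with steps continuing until
  the requested number of distinct channels is reached;
* folds are assigned once per run, stratified by gesture class, seeded;
  they are not reshuffled between steps, so traces are reproducible and
  prefix-nested;
* ties in CV accuracy break toward the lowest (channel, feature) column
  index, with no floating-point tolerance.

The candidate scoring loop is compiled (RcppArmadillo): each step scores
~1280 candidates × 10 folds. A full 8-channel selection on the default
benchmark (~1400 training windows) takes seconds; everything else in the
package is plain R.

`accuracy_vs_channels()` evaluates SFS prefixes (or CIRC) across channel
counts, always with the all-five expansion and a freshly fitted LDA. In
single-wrist mode the whole procedure runs per wrist and reports the mean
of the three accuracies. CIRC is defined at n = 8; other counts are only
available behind an explicit flag that generalises to n equidistant ring
columns.

## Separability

Class separability uses the Bhattacharyya distance between class
Gaussians, D = ⅛ ΔμᵀΣ̄⁻¹Δμ + ½ ln(det Σ̄ / √(det Σ_a det Σ_b)) with
Σ̄ = (Σ_a+Σ_b)/2, averaged over all 28 unordered gesture pairs. Class
covariances are regularised with the same diagonal-target shrinkage as the
LDA so both operate in one conditioning regime; determinants are computed
as Cholesky log-determinants to avoid overflow. The index is evaluated on
the *individual features the SFS actually selected* (typically 8–12
columns), not on the 40-column channel expansion: per-class covariances on
single-wrist subsets (~80 windows per class) are then well conditioned,
and this reading matches "the selected feature space" most directly. The
wrist-condition report computes the index per single wrist (P, N, S) and
for all wrists combined.

## Online control simulation

`run_trial()` reproduces the trial state machine: every 125 ms the newest
125 ms of signal is concatenated with the previous 125 ms, featurised on
the active channel set (channels in ascending order, matching the training
column order), and classified. Predictions count toward the dwell only
while the activation lies inside the gating window — 10–35% MVC for
low-force and 45–75% MVC for moderate-force trials. Sixteen consecutive
valid target predictions (2 s) complete the trial; 10 s is the timeout.

Decisions taken where the protocol is silent or the simulation needs a
stand-in:

* **dwell resets**: any non-target prediction *or* out-of-window tick
  resets the counter — "continuously" is taken literally, no grace ticks;
* **completion time** runs from target display to the tick completing the
  dwell, *inclusive* of the 2-s dwell (16 ticks ≡ 2 s by construction);
* **dwellings** count prediction changes between consecutive in-window
  ticks only; an out-of-window gap does not itself count as a change;
* **rest targets**: a block covers all 8 gestures × 3 wrists × 3 channel
  sets, including rest. A force-gating window is meaningless for rest, so
  rest trials gate on *inactivity*: activation in (0, 10%] MVC;
* **the synthetic subject** (`subject_policy()`) is open-loop: after a
  reaction delay (default 0.25 s) it holds the gating-window midpoint with
  multiplicative noise (default σ = 0.08) and occasionally produces a
  wrong gesture's spatial pattern for one window (default probability
  0.03 per tick). It does not react to feedback. This is the main fidelity
  gap: human subjects correct themselves mid-trial, which is precisely the
  mechanism behind offline/online performance dissociations, so the
  simulated outcome measures characterise the *pipeline*, not human
  performance. With the default noise the synthetic subject is also far
  more stable than a human — dwelling counts are near zero at both force
  levels;
* **measured activation**: the gating logic sees the activation the policy
  produced rather than re-estimating it from the synthetic signal; the
  channel-averaged RMS estimator is unbiased with negligible variance at
  these window sizes, and skipping it lets a trial generate only the
  channels its classifier needs.

## Problem sizes

The default benchmark session is the full protocol: 24 task recordings of
17 s plus 24 MVC recordings at 2048 Hz × 256 channels, streamed task by
task so memory stays bounded (~75 MB per task). It yields ≈2000 feature
windows × 1280 columns; building it takes ≈3 min on one CPU and the
8-channel SFS a few seconds more. The test suite re-uses one cached
benchmark for the end-to-end checks and runs its generator-level property
checks (signal-to-noise monotonicity, the cost of wrist shifts in
channels, class-structure margins) on reduced task subsets — 4–5 gestures,
fixed seeds — cutting segments at the known profile timings where a
property must remain valid below the SNR range in which the 10%-MVC onset
rule operates.

## Known limitations

* The generator's hot-spot geometry, amplitudes and wrist-shift magnitudes
  are plausible but invented; no quantitative correspondence to any real
  forearm is claimed, and the wrist-shift magnitude in particular is a
  free parameter.
* The grid-1 cylinder approximation ignores forearm taper.
* The open-loop subject policy makes online completion rates optimistic
  and dwelling counts pessimistically clean (see above).
* Inferential statistics over subjects (normality tests, repeated-measures
  comparisons) are out of scope; the package computes per-session
  quantities only.
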