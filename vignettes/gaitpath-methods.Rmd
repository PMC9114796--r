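---
title: "Methods: stride-level foot-trajectory estimation and spatial gait features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stride-level foot-trajectory estimation and spatial gait features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitpath)
```

## The problem

A shank-worn inertial measurement unit (IMU, tri-axial accelerometer +
gyroscope, 100 Hz) just above the ankle observes specific force and angular
velocity in its own moving frame. From those two signals, gaitpath
reconstructs the 3-D path of the ankle point for every stride of a corridor
walk, reads six spatial features off each path, and runs the group-level
statistics used to phenotype Parkinsonian gait: mild Parkinson's disease
(PD) walkers lift the foot *higher* but carry it *less far forward* than
healthy older controls, and those two effects live on nearly orthogonal
axes of the feature space.

The six features are forward (F) and vertical (V) displacements of the
ankle point from the stride origin, read at three in-stride events:
toe-off (F1, V1), maximum clearance (F2, V2), and the change of supporting
leg (F3, V3). F3 is essentially stride length; V2 is peak foot clearance.

## Trajectory estimation

Per stride, independently (so error cannot accumulate across strides):

1. **Heel-strike detection.** Ground contact produces a sharp transient
   ("spike") in the sagittal gyro channel. The channel is zero-phase
   band-pass filtered (default 8–25 Hz, i.e. *above* the locomotor band so
   the adaptive threshold tracks noise rather than gait amplitude), local
   maxima of the absolute filtered signal above `k_mad` = 4 times the MAD
   are collected, and a refractory rule (`min_stride_time` = 0.6 s) keeps
   the largest peak per neighbourhood.
2. **Despiking.** The same impact transient is rotational noise for
   strapdown integration, so all gyro channels are linearly interpolated
   across ±0.10 s around each detected heel strike before any integration.
3. **Windowing.** Integration windows run from one *mid-stance* to the
   next (`segmentation = "midstance"`), the instant when the foot is flat
   and the shank steadiest. This is where the zero-velocity, zero-height
   boundary assumptions are physically true; each window then contains one
   complete swing, its terminal heel strike, and the following support
   change. The anchor is found by minimizing |pitch rate| *plus* the
   smoothed gravity residual ||a| − g| over a 5–50 % stance search window:
   the accelerometer term pins the anchor to true foot-flat even where the
   shank happens to be rotationally quiet while the ankle still descends.
   A heel-strike-to-heel-strike mode (`"heelstrike"`) is available; note
   that under it the support-change instant clamps to the window end and
   V3 degenerates to 0 by construction.
4. **Orientation.** At the anchor the accelerometer reads gravity only
   (norm checked within ±20 %); the minimal rotation mapping the measured
   vector to (0, 0, +g) initializes the attitude (yaw is unobservable and
   set by convention; it cancels later). Orientation is propagated outward
   with a first-order rotation-vector exponential per sample and
   renormalization.
5. **Integration.** Acceleration is rotated to the world frame, gravity
   subtracted, and integrated both forward (v(0) = 0) and backward
   (v(T) = 0); the reported velocity is the blend
   v = (1 − w) v_f + w v_b with the linear ramp w(t) = t/T, which cancels
   any constant accelerometer bias exactly. Position integrates the
   blended velocity; the vertical channel is linearly detrended so
   vertical(T) = 0 — the minimal correction consistent with the
   zero-height assumption (whether the original method detrended linearly
   is not known; this is our choice).
6. **Stride frame.** The forward axis is the direction of net horizontal
   displacement, so every reported feature is invariant to world yaw; a
   net displacement below 1 mm marks a degenerate (standing/turning)
   stride. Yaw drift within a stride is left uncorrected — the
   net-displacement frame absorbs it.

Event conventions (all recorded in the output): toe-off defaults to the
negative sagittal-gyro peak preceding the swing peak — the vertical-
velocity zero-crossing alternative finds the *onset of lift*, where the
vertical displacement is still ~0, which would make V1 vacuous. The change
of supporting leg defaults to the first contralateral toe-off after the
terminal heel strike (fallback: the terminal heel strike itself when no
contralateral stream exists). Neither physical definition is documented in
the source study; both are exposed as config enums.

Stride selection follows the corridor protocol: drop the first and last
five strides per leg, drop direction-change (turn) and failed strides,
keep the first 20 remaining per leg — 40 strides per participant.
Turns are flagged by stride azimuth: anything deviating more than 30° from
the dominant corridor axis (double-angle circular mean).

## The synthetic world

Real recordings of the study cohort are not shareable, so the package
ships a ground-truthed generator and every quantitative claim in the test
suite is against *its* truth. What it emulates:

* Closed-form stride kinematics: flat-stance/raised-cosine vertical
  profile passing through `toe_off_height` at the stance fraction, peaking
  at `max_clearance` at the clearance phase, landing at `terminal_height`;
  quintic-smoothstep forward progression starting a fixed 0.15-stride
  heel-rise lead before toe-off. Acceleration is the exact analytic second
  derivative of each segment.
* A lobed shank pitch-rate waveform (loading, terminal-stance, toe-off and
  swing lobes) whose areas balance so pitch is periodic, with its unique
  quasi-static minimum at mid-stance and quiet zones around ground
  contact.
* Rendering: sensor accel = orientation-inverse of (world acceleration +
  gravity 9.80665 m s⁻²); gyro = discrete body rates (rotation-vector log
  of successive attitudes, so a first-order integrator reproduces the
  attitude exactly); heel-strike transients as Ricker wavelets — symmetric
  about the true contact instant, zero net rotation *and* zero net
  velocity impulse — with amplitude scaling with stride speed; white
  noise, constant biases.
* Corridor sessions: > 60 strides with a mid-session turn block rendered
  as short, low-amplitude strides that reverse the heading; both legs
  share per-stride durations (bipedal timing coupling), keeping the
  half-cycle phase offset stable.
* Group profiles for mild PD, advanced PD, healthy older and healthy
  young walkers that realize the reported orderings — forward extent
  young > older > mild > advanced, vertical displacements
  mild > young > older > advanced — with between-subject spread large
  enough that group clouds overlap as in the published bar charts.

Structural choices that matter for the statistics (chosen by forward
design against the reported orderings and the published two-factor
eigenstructure, then frozen): forward and vertical parameters vary
independently within a subject; the three heights share only a weak
common per-subject scale factor (sd 0.04) on top of per-feature jitter,
mirroring the observation that the three vertical loadings differ; group
mean gaps are moderate (≈ 0.7–2 within-group SD). Together these produce a
feature table whose correlation matrix has a tight forward block, a looser
vertical block, and small cross-block coupling — so PCA yields a
forward-dominated first component and a vertical-dominated second one and
parallel analysis retains exactly two components.

What a green test does **not** establish: fidelity to the real cohort's
numbers. The generator makes no claim that its feature magnitudes match
the unpublished per-group means (the source figures are bar charts), that
real sensors behave like white noise + constant bias, or that real turns
look like scaled-down strides. Classification accuracies on synthetic
cohorts are artifact-internal quantities, not replications of the
published accuracy table. The one number carried over from the literature
is the stride-length estimation fidelity (coefficient of determination
≈ 0.98 against optical capture), which the pipeline must meet against
synthetic truth under default noise.

## Statistics

* **ANOVA**: classical one-way between/within decomposition per feature.
* **Shaffer post hoc**: all pairwise pooled-variance t tests (Welch by
  config), p-values ascending, step j tested at α / t_j where t_j is the
  largest number of pairwise hypotheses simultaneously true given j − 1
  false — computed from achievable counts Σ C(b,2) over integer partitions
  of the group count (for 4 groups: 6, 3, 3, 3, 2, 1). Adjusted p = running
  max of p_j · t_j, capped at 1. Variables are treated independently (the
  source analysis reports no cross-variable multiplicity handling).
* **PCA** on the correlation matrix (forward and vertical features differ
  by an order of magnitude); loadings reported as component–variable
  correlations; sign fixed so each component's largest loading is
  positive.
* **Parallel analysis**: observed eigenvalues against the 95th percentile
  of eigenvalues from 1000 standard-normal datasets of the same shape,
  retention stops at the first rank that fails.
* **SVM**: soft-margin kernel SVM (RBF default, C = 1, bandwidth = median
  pairwise distance), solved by a deterministic SMO — implemented
  in-package because no SVM library is available in the target
  environment. Stratified 10-fold cross-validation; features standardized
  with training-fold statistics only; accuracy = unweighted mean of fold
  accuracies. One vector per participant (subject-level, no stride
  instances shared across folds). The PC plane used for classification is
  the full cohort's PCA (`pca_scope = "full"`): one plane for all
  subjects, as in the published scatter plots; computing it on the pooled
  data before fold splitting mirrors the original design and is a known
  leakage caveat. ROC by threshold sweep; AUC equals the normalized
  Mann–Whitney U (ties half-weighted).

## Numerical choices and degenerate inputs

Trapezoidal cumulative integration at 100 Hz (closed-form check: a
sinusoidal acceleration recovers its double integral within 1e−4 m);
quaternions renormalized every step; tie-breaks: earliest sample wins the
clearance argmax; strides failing the quasi-static anchor check, with no
detectable lift, or with < 1 mm net displacement are dropped and logged
with a reason; selection shortfalls warn and never pad; fewer subjects
than folds degrade to leave-one-out.

## Known limitations

* The anchor/event conventions are choices among physically reasonable
  alternatives the source text does not pin down; every output records
  which convention produced it.
* V3 is small (≈ half the terminal landing height) and the most
  estimation-sensitive feature; under heel-strike windowing it is 0 by
  construction.
* The mild-vs-advanced contrast in this synthetic world has a strong
  vertical component (all six displacements shrink with progression), so
  its decision boundary need not be forward-dominated.
* No freezing-of-gait, tremor, or assisted walking; no magnetometer; no
  real-device axis remapping beyond a config-level permutation.
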