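---
title: "Simulating and analyzing ERP responses to point-light biological motion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analyzing ERP responses to point-light biological motion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`bmerp` re-creates, as a tested pipeline, a complete EEG/ERP study of the
direction of biological motion: point-light walker stimuli and their
momentum-preserving scrambled controls, a calibrated multi-subject epoch
simulator, offline preprocessing, component statistics, topographic
microstate segmentation, and a miniature standardized source-localization
stage with permutation inference. This vignette documents the models, the
tunable parameters, and the design decisions taken where a published
description left the choice open.

## The experiment being emulated

Observers view 1000 ms point-light displays of three classes (walker,
scrambled walker, cyclist), moving either in the frontoparallel plane
("lateral": leftward/rightward) or in depth ("radial":
approaching/receding), in 7 blocks of 144 trials (24 repetitions x 6
conditions; 168 trials per condition). The cyclist is a behavioral target
(direction discrimination by key press); walker and scrambled trials require
no response, and trials with an (incorrect) response are excluded from the
EEG averages. EEG is recorded from 64 channels (BioSemi 10-10 labels) at
1024 Hz; epochs span -100..1000 ms around stimulus onset.

Analysis targets three posterior components: the P1 (signed maximum of the
ROI-averaged waveform within 80-150 ms), the N1 (signed minimum within
170-200 ms), both measured over left (P5, P7, PO7) and right (P6, P8, PO8)
ROIs, and an early sustained negativity (ESN) measured as the 210-360 ms
mean over left (P9, P7, P5, PO7), central (O1, Oz, O2, Iz) and right (P10,
P8, P6, PO8) ROIs. (The source description of the ESN ANOVA once calls this
"the 70 ms time window"; the windows section of the same description defines
the ESN as 210-360 ms, which is what the package implements.)

## Stimulus generation

The original stimuli were driven by motion-capture coordinate files that are
not redistributable; `gait_model()` replaces them with a parametric
sinusoidal gait: 13 markers (head, shoulders, elbows, wrists, hips, knees,
ankles), legs as two-segment pendula in antiphase, arms counter-swinging,
with a small double-frequency vertical bob. All joint angles are periodic in
the gait cycle, so marker trajectories have period `1/cadence` exactly --
the property the tests exploit. The cyclist uses the same machinery with
circular pedal trajectories and quiet arms; it exists only so the behavioral
task and its exclusions can be simulated.

`scramble()` draws, per marker, one translation such that the marker's
first-frame position is uniform inside the axis-aligned bounding box of the
original first frame, and applies that same translation to every frame.
Frame-to-frame displacements are therefore preserved exactly ("the same
total momentum"). Scrambling operates in 3-D body space before projection;
whether the original procedure scrambled in 2-D screen space is unknowable
from the description, and the choice does not affect any measured quantity
downstream. Re-scrambling a scrambled sequence is refused, since it would
translate points outside the walker-defined area.

`project_view()` projects orthographically (sagittal view for lateral
motion, frontal view for radial) and rescales every frame so the vertical
angular extent follows the size trace: constant 2 (small) or 4 degrees
(big) for lateral motion, and a ramp 1-3 or 3-5 degrees for radial motion
(reversed when receding). The ramp is linear in frame index -- the
description states only the endpoint sizes, and linearity is the minimal
assumption that also makes the radial/lateral mean-size equality exact.
Lateral stimuli keep their centroid fixed at the screen center (treadmill
convention).

## The synthetic EEG generator

Each trial is a noise-free condition template plus structured noise. The
template is a sum of components, each a temporal waveform times a scalp
topography:

* **P1**: Gaussian (SD 14 ms) peaking at 112 ms (biological) or 118 ms
  (scrambled), positive over lateral occipital sites.
* **N1**: Gaussian (SD 13 ms) at 186 ms, negative over
  occipito-parietal sites.
* **ESN**: an edge-smoothed plateau (edge SD 10 ms) from 210 to 500 ms,
  implemented as three consecutive sub-periods (210-310, 310-400,
  400-500 ms) with distinct posterior topographies. Together with the P1
  and N1 maps this plants five quasi-stable topographies in the 80-500 ms
  analysis span of every condition -- the ground truth the microstate
  stage is tested against.

Topographies are sums of spherical Gaussians on the montage, average
referenced, and normalized so that the mean over the component's measurement
ROI equals one. Component amplitudes are therefore calibrated *in measurement
units*: the configured amplitude is what the measurement stage should read
out. Plateau waveforms are additionally normalized so that the 210-360 ms
window mean of the summed ESN sub-components is exactly one (compensating
the onset-edge loss).

Amplitude cells reproduce the reported statistics of the emulated study
exactly at the specification level: the four printed P1 cell means; N1 cells
built additively from the printed motion marginals (-2.84 biological, -2.41
scrambled) and direction marginals (-2.93 radial, -2.32 lateral); ESN cells
from the printed motion marginals (-3.74, -2.18). No interaction terms are
introduced beyond those implied by the printed cells, the minimal model
consistent with every printed number. Two further reported effects are built
in:

* an approach/recede N1 modulation on radial trials, implemented as a
  symmetric +/-0.275 uV split (the printed receding-minus-approaching
  difference of 0.55 uV) around the radial cell mean. The printed absolute
  pair (-3.75/-3.2 uV) is inconsistent with the printed N1 marginals (their
  mean is not the marginal-implied radial-BM cell); the package honors the
  marginals and the difference, not the absolute pair.
* a right-lateralized enhancement of the biological-minus-scrambled ESN
  difference, implemented as an antisymmetric right-minus-left pattern
  (zero total and zero ROI-union mean, so no marginal is disturbed) added
  on biological trials with weight -0.6 uV.

Between-subject variability multiplies each component by a subject-level
amplitude offset and shifts its latency, with SDs equal to the printed SEMs
scaled by sqrt(15) (P1: 1.16 uV, 12.1 ms; N1: 1.98 uV, 7.7 ms; ESN: 1.47 uV;
the three ESN sub-periods share one offset). A simulated 15-subject study
therefore reproduces the printed dispersion, and its grand means scatter
around the printed means with SE roughly equal to the printed SEMs. Offsets
are shared across conditions within subject, so within-subject condition
differences carry only trial-level noise; repeated-measures F statistics on
the synthetic data are consequently larger than the published ones -- the
generator targets the means and dispersions, not the error terms.

Noise is spatially correlated 1/f-plus-white noise: a single complex
spectrum shaped as sqrt(pink^2/f + white^2), inverse-FFT'd (two independent
series per complex column), then mixed across channels by the Cholesky
factor of an exponential great-circle-distance kernel (e-folding scale 0.8
rad). Defaults are pink 3 uV RMS and white 1.5 uV RMS per channel -- chosen
once as a realistic post-acquisition noise floor that leaves the residual
ERP noise after ~134 retained trials near 0.2-0.3 uV, comparable to the
printed SEM scale. Blink artifacts (Gaussian time course, SD 40 ms, frontal
topography peaking at 150 uV) contaminate each trial with probability
0.195, calibrated so that +/-100 uV rejection retains ~80.5% of trials, the
reported retention. Behavior: target trials are answered correctly with
probability 1 - 0.014 and non-target trials draw false alarms with the same
rate, so the expected percent correct is the reported 98.6%.

What the generator does *not* emulate: ocular/muscle artifacts other than
blinks, bad channels, line noise, non-stationarities across blocks,
latency jitter across trials within a subject, and subject-by-condition
random interactions. Passing recovery tests on this synthetic data shows the
pipeline is internally consistent and calibrated -- not that it would
reproduce the published group statistics from real recordings.

## Preprocessing

The pipeline applies, in the standard offline order: zero-phase band-pass
(0.17-30 Hz), average reference, -100..0 ms baseline correction,
+/-100 uV rejection, optional bad-channel interpolation, then averaging of
retained, behaviorally correct, non-target trials.

The band-pass is a Butterworth cascade (order 2 high-pass, order 4
low-pass) applied forward and backward, giving a zero-phase squared
magnitude response: 10 Hz passes within 5%, 50 Hz is attenuated by more
than 20 dB. Each pass starts from the filter's steady state for the
segment mean. With the 0.17 Hz high-pass the filter's impulse response is
far longer than one epoch, and padding schemes that extrapolate the edges
(odd extension) inject low-frequency content that the slow poles turn into
epoch-long transients; the mean-steady-state initialization without
extension empirically leaves the smallest edge transients at this epoch
length, and the tests pin the resulting response. Peak amplitudes of
14 ms-SD components are attenuated by about 2% -- visible in the zero-noise
round-trip tolerance.

Rejection is strict: a trial is lost only when |V| exceeds 100 uV
(a sample at exactly 100 uV is kept). Interpolation is the Perrin
spherical-spline scheme (stiffness m = 4, 50 Legendre terms, ridge 1e-5).
Leave-one-out error on a smooth low-order field is below 5% of the map GFP
for all electrodes inside the sampled cap; the three lowest sites (P9, P10,
Iz) sit below every other electrode, where leave-one-out becomes
extrapolation and errors grow to ~18% -- a known property of spline
interpolation at the cap boundary, not exercised by the rejection pipeline
(interpolation targets interior bad channels).

## Component statistics

`rm_anova()` implements the fully within-subject ANOVA from orthonormalized
contrast scores. For each effect, F is the ratio of the between-subject mean
square of the contrast means to the subject-by-contrast mean square;
Greenhouse-Geisser epsilon comes from the covariance of the contrast scores,
so two-level effects have epsilon exactly 1 and the F = t^2 identity holds
against a paired t-test. The implementation is cross-checked in the tests
against `car::Anova` (multivariate idata route) as an independent oracle.
`tukey_hsd()` compares the cell means of an effect using the studentized
range with that effect's own error term and n = subjects; for two cells it
reduces exactly to the paired t-test (q = sqrt(2) |t|).

The point-wise test computes paired t statistics per electrode and sample,
thresholds two-sided at alpha/64 (Bonferroni over electrodes -- the
simplest reading of "corrected for the number of electrodes"), and groups
same-sign suprathreshold points into spatiotemporally connected clusters.
Electrode contiguity uses a montage-derived adjacency: neighbors are pairs
closer than 1.3x the median nearest-neighbor great-circle distance, a
standard testable rule since the original criterion never defines
contiguity. Clusters count only if strictly longer than 10 ms (at 1024 Hz,
at least 12 samples) and strictly wider than 3 connected electrodes (at
least 4) -- the literal strict inequalities. Under the null
(1000 simulations with the generator's correlated 1/f noise), the
family-wise false-positive rate of this deterministic criterion is well
below 0.05; the criterion is conservative by construction, and the test
asserts only the upper bound.

## Microstate segmentation

Scalp maps are GFP-normalized (topography separated from strength) and
clustered with polarity-sensitive k-means -- maps and their inversions are
*not* identified, as appropriate for event-related (rather than
spontaneous) data. `microstate_segment()` takes the best of 100 restarts
per K (seeded, hence reproducible); `select_k()` minimizes the predictive
residual criterion CV(K) = sigma2_K ((C-1)/(C-1-K))^2 with C = 64 channels.
The four conditions' grand averages are concatenated over the 80-500 ms
span and segmented jointly, yielding one shared template set; whether the
original analysis concatenated or weighted conditions is not stated, and
concatenation is the simplest faithful choice. `backfit()` assigns each
timepoint to the template with the highest signed spatial correlation,
merges segments shorter than 20 ms into the better-correlated neighbor,
and scores GEV = sum_t (GFP_t corr_t)^2 / sum_t GFP_t^2.

## Source localization

The forward model is the analytic concentric three-shell sphere (radii
0.87/0.92/1.0, conductivities 0.33/0.0042/0.33 S/m -- canonical values, as
only "a three-shell head model" is specified). For each Legendre degree up
to 60 the radial boundary-value problem is solved directly (continuity of
potential and radial current at both interfaces, zero current through the
scalp), which reduces to the textbook (2n+1)/n factor when all
conductivities are equal -- a closed form the tests verify. The source
space is a cubic lattice clipped to radius 0.8 r1 (default spacing 0.1,
about 2000 nodes; configurable toward the published 6239-voxel resolution).
A real cortical grid requires anatomical data that is out of scope; the
algorithmic properties under test (linearity, reference invariance,
localization) are geometry-independent.

`sloreta_inverse()` computes the Tikhonov-regularized minimum-norm estimate
and standardizes each node's 3-vector by the corresponding 3x3 resolution
block. This standardization has zero localization error for noiseless
single-dipole fields -- the defining property, verified by brute force over
100 random nodes. The default alpha is 1e-3 x trace(KK')/channels.

`snpm_paired()` runs the sign-flip max-statistic permutation test: the
corrected threshold is the 1-alpha quantile of the maximum |t| over
randomizations (5000 by default; exhaustive enumeration whenever
2^subjects does not exceed the requested count, and the Monte-Carlo p
equals the exhaustive p exactly at n = 5). Surviving nodes are grouped by
6-neighbor lattice adjacency and clusters below 30 nodes (default) are
discarded. The published tables label their statistics "T_15" with 15
subjects; the package uses the conventional df = n - 1 = 14.

## Problem sizes and reproducibility

Every stochastic stage takes an explicit integer seed, and stage seeds are
derived deterministically from one top-level seed; identical seeds give
bit-identical epochs, segmentations and permutation results. The test suite
runs the full-scale recovery study (15 subjects x 1008 trials x 64
channels at 1024 Hz) once; calibration suites use reduced problem sizes
chosen to keep the whole suite in the tens of minutes on one core: 1000
null simulations of 300-sample epochs for the cluster-test FWE, 5000 null
draws for the ANOVA type-I rate, a ~2000-node grid with 100 dipole draws
for the localization suite, and few-hundred-node grids for the permutation
unit tests. The acceptance script (`scripts/acceptance.R`) re-simulates the full
study from scratch at the given seed and reports the recovered grand means.

## Known limitations

* The gait model is a stylized pendulum, not motion-captured kinematics;
  stimulus realism matters only insofar as the design counts and
  size-control invariants are exercised.
* The montage is the idealized spherical 10-10 layout, not digitized
  positions.
* Generator F statistics exceed the published ones (no subject-by-condition
  random interactions), so only the direction and significance of effects
  -- not their F magnitudes -- are recoverable.
* The published anatomical attributions (Talairach coordinates, Brodmann
  areas) are outside scope: the toy spherical grid has no anatomy.
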