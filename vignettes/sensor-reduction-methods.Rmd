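---
title: "Methods: synergy-based sensor reduction for hand kinematics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synergy-based sensor reduction for hand kinematics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(handsyn)
```

## The problem and the model

Hand motion during everyday activities is strongly coordinated: finger
flexions co-vary through mechanical and neural couplings. `handsyn`
exploits this to answer a measurement-design question: *which subset of
the 16 canonical hand angles must be physically recorded so the rest
can be reconstructed acceptably?*

The statistical model has three layers.

**Synergies.** For one subject, let $Z$ be the $16 \times N$ matrix of
z-scored angles over all activities (each activity resampled to the
same frame count so it weighs equally). PCA of the correlation
structure of $Z$ yields components; the smallest $k$ whose cumulative
variance reaches the retention threshold (default 0.95) is kept, and
the loading matrix — eigenvectors scaled by the square roots of their
eigenvalues, so entries are correlations between component scores and
angles — is Varimax-rotated. Rotation is applied after $k$ is fixed; it
redistributes variance among retained components but cannot change
their total, which the test suite asserts to $10^{-9}$.

**Shared structure.** Rotated components of all subjects are pooled and
compared with the angle between loading vectors,
$d(u,v) = \arccos\left(|u \cdot v| / (\lVert u\rVert \lVert v\rVert)\right) \in [0^\circ, 90^\circ]$.
The absolute value makes the distance blind to the arbitrary sign of a
principal component. Complete linkage builds the hierarchy, and the cut
is chosen by a structural rule rather than a height threshold: the
*minimum number of clusters* such that no cluster contains two
components of one subject. The rationale: one subject's rotated
components are mutually orthogonal, so two of them in one cluster means
the cluster conflates distinct coordinations. The cut height is
reported (rounded to whole degrees) as the smallest merge undone by the
selected partition, but selection itself is count-based.

**Affine reconstruction.** Given a representative set $R$ of recorded
angles, every other angle $j$ is modeled per frame $i$ as
$\hat y_{ji} = \beta_{j0} + \sum_{k \in R} y_{ki}\,\beta_{jk}$,
with coefficients minimizing the sum of squared differences over all
pooled frames. Because the model is affine, the least-squares problem
is solved in closed form (QR) rather than iteratively; tests verify
equivalence with a normal-equations oracle to $10^{-8}$ and local
optimality under $\pm 10^{-3}$ coefficient perturbations. Fitting is on
raw degrees — intercepts are physical angles — and pools all subjects
into one global model; per-subject estimators are out of scope.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `cutoff`, `order` | 5 Hz, 2 | Hz, – | Hand motion in daily activities lies below ~5 Hz; two-way application gives zero phase lag. |
| `vel_threshold` | 2 | deg/s | A hand holding a posture drifts below ~2 deg/s on every joint; genuine motion exceeds it on some joint. |
| `min_run` | 0.2 | s | Only sustained stillness is trimmed; shorter lulls occur inside real movements. |
| `n_frames` | 1000 | frames | Equalizes activity weights in the PCA ensemble. |
| `var_threshold` | 0.95 | fraction | High retention keeps small-range joints (abductions, palmar arch) in the synergy space. |
| `fixed_k` | `NULL` | – | Optional override to pin the component count when reproducing analyses that fixed it. |
| `min_subject_fraction` | 0.10 | fraction | Coordinations present in fewer than ~1 in 10 subjects are idiosyncratic strategies, not population structure. |
| `cc_high`, `cc_low`, `cc_candidate` | 0.8, 0.3, 0.4 | \|CC\| | Single-DoF dominance, absence elsewhere, and candidate membership; read on absolute values (component sign is arbitrary) and as strict inequalities. |
| `max_condition` | 1e10 | – | Design matrices beyond this condition number indicate collinear representative angles; the fit aborts rather than returning unstable coefficients. |

## Numerical choices

- **Filter edges.** Two-way filtering uses odd-reflection padding whose
  length scales with the filter's settling time (about nine cutoff
  periods, capped at the recording length). Short fixed pads leave a
  zero-state transient of a few percent at the edges, which inflates
  the apparent rank of low-rank recordings and breaks the exactness of
  affine relations; the chosen pad drives the remnant below $10^{-12}$
  relative, so a constant signal passes through unchanged and filtering
  commutes with affine structure to machine precision.
- **Repeated filtering.** Filtering is not idempotent: each pass
  multiplies the passband magnitude again, so even in-band amplitudes
  shrink by up to ~2 % per extra pass near the cutoff. Trimming and
  resampling *are* idempotent on conditioned output and are tested as
  such; pipelines should filter once.
- **Resampling** is linear interpolation on a uniform grid — the signal
  is already band-limited to 5 Hz, so higher-order interpolants add
  nothing; endpoints are preserved exactly and monotone traces keep
  their extrema.
- **Varimax** uses the Kaiser row-normalized flavor (`stats::varimax`,
  tolerance $10^{-8}$), the common default in factor-analysis practice.
  Reported loadings fix each component's sign so its largest-magnitude
  entry is positive; all downstream computations are sign-invariant
  regardless.
- **Angle distance near collinearity.** $\arccos$ is ill-conditioned at
  1, so collinear vectors can return angles of order $10^{-5}$ degrees
  instead of exactly 0; the cosine is clamped to $[0, 1]$ and tests use
  matching tolerances.
- **Ties.** Combination scoring breaks ties by enumeration order
  (groups in discovery order, candidates in canonical DoF order, last
  group fastest). Exact ties between distinct partitions of a strict
  hierarchy cannot occur with continuous distances.
- **Degenerate inputs** fail loudly: a zero-variance DoF in the
  standardization (a disconnected sensor would otherwise corrupt the
  fixed 16-label contract), a zero-range DoF in the RoM table, an
  all-static recording, identical same-subject components (unseparable
  under any cut), collinear designs.

## Design decisions where the method was open

- **Trimming order and thresholds.** Static-segment detection is
  applied after filtering (matching the conditioning order of the
  acquisition protocols this mirrors) with the velocity/duration
  defaults above; both are exposed because glove noise floors differ.
- **Demotion rule.** A cluster dominated by a single DoF is *not*
  independent if that DoF also appears among a coordination cluster's
  candidates; it is absorbed into that coordination group, and
  coordination groups whose candidate sets overlap are merged. This
  formalizes "also appears coordinated elsewhere" as candidate-set
  overlap; other formalizations exist, and with real data the outcome
  can be sensitive to loadings near the 0.4 threshold. The synthetic
  generator plants disjoint blocks, so the rule is unambiguous there.
- **Angles on CC vectors.** Inter-component distances are computed on
  the correlation-coefficient loadings (the only loading form the
  pipeline defines). Unscaled eigenvectors would give slightly
  different angles; results near the cut height can be sensitive to
  this choice.
- **Evaluation at native frame rate.** Resampling exists to equalize
  activity weights in PCA; error reporting should instead weigh
  activities by their true duration, so held-out evaluation never
  resamples, and the global RMSE pools all frames (one value per
  joint), which decomposes exactly into the frame-weighted mean of
  per-activity squared errors (tested to $10^{-9}$).
- **RoM denominators** pool both datasets' extremes; a single-dataset
  fallback exists for synthetic runs.
- **Command-line surface.** The exported stage functions plus
  `run_pipeline()` are the per-stage interface; the shell wrapper only
  adds `simulate` and `run-all`, since every intermediate artifact is
  already a CSV that any stage function can re-read.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` builds each subject's angles as
*loadings × band-limited activations* plus independently driven single
DoF, a fixed postural baseline, Gaussian measurement noise, and exact
posture holds at both ends. Defaults describe the intended study
conditions: 8 subjects, 6 activities of 5 s at 100 Hz, two planted
coordinations (a 3-DoF PIP block and a 7-DoF MCP block, ≥ 60° apart so
the planted partition is recoverable at the usual cut), six independent
DoF, 5° of per-subject loading jitter, 1° noise, 0.5 s pads.
Activations are white noise low-passed by the same 5 Hz Butterworth the
pipeline uses, keeping synthetic energy inside the passband.

Passing tests on these cohorts establish *mechanical* correctness:
exact recovery at zero noise (planted cluster count, residuals below
$10^{-6}$ degrees), graceful degradation with noise (coefficient
recovery within 0.05 at the default jitter/noise; monotone error growth
with noise), and exact error bookkeeping. They do **not** establish
that real hands satisfy the model: real coordinations are not exactly
affine, loading structure drifts within a task, noise is not white, and
joint limits induce nonlinearities near extremes. The generator also
makes no attempt at biomechanical realism (no tendon coupling, no
grasp taxonomy); amplitudes are calibrated to plausible excursion
scales, not to specific activities. Results on real recordings should
therefore be validated against the held-out %RoM tables, not inferred
from synthetic performance.

One consequence of expressing loadings as correlations is worth
noting: a block driven by a single activation correlates ~1 with its
component on *every* block DoF, regardless of the planted weights.
Recovery tests therefore compare extracted loadings against the
normalized support of a planted block, not its weight vector.

## Problem sizes

The test suite and `scripts/acceptance.R` run at desk scale by design:
cohorts of 2–8 subjects, 2–6 activities, 200–600 frames per activity,
resampling to 250–1000 frames, brute-force clustering oracles up to 20
pooled components, and OLS oracles up to 1000 frames. The full-data
entry point (`reproduce_study()`) expects the two public archives
(22 subjects × 26 activities for training; 20 subjects × 33 activities,
right hand, for evaluation) as local delimited-text exports.

## Known limitations

- The subject-uniqueness cut rule assumes rotated components are
  orthogonal within subject; loadings that are nearly collinear across
  *different* coordinations (possible with heavy cross-loading on real
  data) can force more clusters than coordinations.
- Classification thresholds (0.8/0.3/0.4) are inherited conventions;
  clusters with loadings near these values flip categories under small
  perturbations. The classification table in `run_pipeline()` output
  makes the inputs to every such decision inspectable.
- The estimator is a single global affine map; subject-specific,
  time-lagged or regularized variants are deliberately out of scope.
- `pc_angle` treats loading vectors as directions in DoF space; it does
  not model uncertainty in the loadings themselves.
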