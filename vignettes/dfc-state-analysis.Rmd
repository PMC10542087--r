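---
title: "Dynamic functional connectivity states: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic functional connectivity states: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The analysis in one page

`dfcstates` implements a sliding-window dynamic functional connectivity
(dFC) analysis for two-group cohorts of parcellated resting-state fMRI
time series, together with the group statistics usually reported with it.
A subject enters the pipeline as a T x N matrix (T volumes, N regions,
e.g. an AAL-90 parcellation).  The stages are:

1. **Temporal preprocessing** — drop the first volumes (scanner
   equilibration), remove per-region linear trends, band-pass 0.01–0.08 Hz.
2. **Windowed connectivity** — Pearson correlation of every region pair
   within sliding windows (default 30 volumes = 60 s at TR 2 s, step
   3 TR = 6 s), Fisher-Z transformed.  With 230 retained volumes this
   yields 67 windows per subject; the across-window SD of each edge's Z is
   the dFC variability map.
3. **Connectivity states** — K-means over all subjects' window vectors
   (upper-triangle Fisher-Z, squared-Euclidean distance).  Recurring
   whole-brain patterns become state centroids; each window gets a state
   label.  Per subject we compute mean dwell time (MDT), fractional
   windows and the number of transitions, and contrast them between groups
   with age, sex and education as covariates.
4. **Per-state edgewise contrasts with NBS correction** — for each state,
   the subject-wise mean connectivity in that state is compared edge by
   edge (`z ~ group + covariates`); family-wise error over the 4005 edges
   is controlled by the network-based statistic: threshold edges, find
   connected components, and compare each component's edge count against a
   permutation null of the maximal component size.
5. **Time-varying graph topology** — every windowed network is binarized
   along a sparsity ladder (0.10–0.40, step 0.01), global/nodal efficiency,
   degree, betweenness, clustering and local efficiency are computed per
   rung, integrated over sparsity (trapezoidal AUC), and the across-window
   variance of each metric is contrasted between groups with
   Benjamini-Hochberg correction across nodes.

Because resting-state acquisitions are rarely shareable, the package also
ships a **synthetic cohort generator** whose planted structure gives every
stage a ground truth to verify against.

## The generative model behind the synthetic cohort

The generator is a hidden-Markov covariance-switching model — the minimal
structure under which windowed correlation states, dwell times and a
group dwell asymmetry are all well defined:

* Each subject carries a latent state sequence from a K-state Markov
  chain.  The latent state advances once per `state_switch_step` volumes
  (default 3, the window step), so latent dwell ticks are commensurate
  with window-level labels.
* Within a dwell segment, volumes are drawn i.i.d. from a zero-mean
  multivariate normal with that state's covariance; AR(1) observation
  noise (sd `noise_sd`, coefficient `ar_phi`) is added.
* Group A ("patients") and group B ("controls") use different transition
  matrices; metadata (age, sex, education, symptom duration, JOA, NDI)
  are drawn to match the target cohort's demographic moments, with
  clinical scores structurally missing for controls.

### Default parameters and why

| parameter | default | rationale |
|---|---|---|
| cohort | 88 + 77 subjects | the target two-group study size |
| regions / volumes / TR | 90 / 240 (10 discarded) / 2 s | AAL-90 geometry, 8-min acquisition |
| states K | 4 | the number of recurring patterns the analysis targets |
| `p_self` | 0.95 per tick | mean latent dwell 20 ticks = 60 s, the scale of reported dFC dwell times |
| patient state-2 `p_self` | 0.985 | see below |
| `within_r` / inactive | 0.7 / 0.07 | strong within-network coupling for "active" networks, near-zero otherwise |
| `noise_sd` / `ar_phi` | 0.3 / 0.4 | mildly autocorrelated measurement noise at parcel-average SNR |

State covariances are block matrices over eight canonical networks (SMN,
DMN, ECN, SN, VN, AN, LN, PN): state *k* activates the cyclic half of the
modules starting at offset `floor((k-1)·m/K)`, so consecutive states
differ in several networks and distant states in all of them.  Any
non-PSD construction is shrunk toward the identity until PSD.

**The planted group difference.**  Patients get a higher self-transition
probability in state 2 only.  The value 0.985 (vs 0.95) was derived from
the dwell-time model *including* two effects a naive calculation misses:
the latent sequence is only ~77 ticks long, truncating long dwells, and
MDT is zero-inflated (subjects that never visit a state contribute 0).
With truncation accounted for, the realized window-level MDTs are ≈25
(patients) vs ≈14 (controls) — a ratio of ~1.8, the ratio characteristic
of patient-vs-control dwell asymmetries in this literature — and the
contrast is reliably detectable at the default cohort size.  A naive
"doubled dwell" choice (0.975) realizes only a 1.5x ratio after
truncation and is *not* reliably detectable; this is a property of
zero-inflated dwell statistics, not of the test.

### What the generator does *not* emulate

No haemodynamic response convolution, no physiological noise, no motion,
no spatial structure beyond the block covariances, and the state signal
is temporally white within segments (real BOLD is band-limited).  Passing
tests therefore demonstrate that the *pipeline machinery* is correct and
that planted effects of realistic size survive the pipeline's estimation
noise — not that any specific real cohort will show such effects.

## Numerical and statistical choices

**Windows** are rectangular (untapered), 0-based and half-open;
`W = floor((T - window_len)/step) + 1`.  Correlations are clamped at
`|r| = 1 - 1e-7` before `arctanh` so duplicate series cannot poison
clustering; matrix diagonals are stored as 0 and clustering uses the
strict upper triangle.

**Band-pass** is a second-order Butterworth applied forward and backward
(zero phase), so state-transition timing is never shifted; columns are
demeaned first, making the DC response exactly zero.  Note that
band-limiting to 0.01–0.08 Hz leaves roughly `2·bandwidth·window` ≈ 8
effective samples per 60-s window: windowed correlations are intrinsically
noisy at this geometry, which drives several design choices below.

**K-means** uses k-means++ initialisation, Lloyd iterations, and the best
of `n_restarts` inertias; an empty cluster is re-seeded at the point
farthest from its centroid.  States are renumbered by descending pooled
occupancy so "state 2" is stable across runs.  All window vectors enter
the clustering (no high-variance exemplar pre-selection), keeping the
procedure single-stage and directly testable.

**Choosing K.**  The inertia curve of windowed-FC data sits on a large
additive noise floor (the estimation variance above), which makes the
classic "curvature of log-inertia" elbow vanish: the log-curve's second
differences are of order 1e-2 whatever the true K.  `select_k()` therefore
locates the elbow by the chord rule — the K whose inertia lies farthest
below the straight line joining the curve's endpoints — which is invariant
to any additive offset.  The elbow depth is normalised by the total
inertia drop; a maximum depth below 0.2 flags the curve as featureless
(e.g. single-state data) and falls back to the smallest K with a warning.
The full criterion curve is always returned.  Mean silhouette width (on a
window subsample) is available as an alternative criterion.

**Temporal metrics.**  MDT is reported in windows (seconds available as
`step × TR` per window); a never-visited state has MDT 0 and the subject
stays in the group test — the zero-inflated definition is the only one
compatible with dwell-time SDs exceeding their means, which is what
two-group dFC studies report.  Group contrasts are least-squares fits of
`metric ~ group + covariates`; with no covariates this is exactly the
pooled two-sample t-test.

**NBS.**  Two-sided edge tests; component size measured in edge count;
permutation p uses the `(1 + #extreme)/(n_perm + 1)` correction so p = 0
is impossible.  With covariates, permutations follow the Freedman-Lane
scheme (permute reduced-model residuals, add back reduced fits, refit the
full model), which preserves the covariate structure under the null.
Subjects that never visit a state are excluded from that state's
comparison, with visitor counts reported; a state with fewer than two
visitors in a group is skipped with an explicit report.

**Graph metrics.**  Binarization ranks edges by `|z|` (strong negative
coupling also counts as connectivity; a positive-only mode is available),
keeps the top `floor(s·N(N-1)/2)` and breaks ties at the cut
lexicographically for determinism.  Efficiency uses the harmonic
convention (unreachable pairs contribute 0); local efficiency is the
global efficiency of the subgraph induced on a node's neighbours;
betweenness counts shortest paths with multiplicity, normalised by
`(N-1)(N-2)/2` — exactly the textbook definitions, so a brute-force
oracle can check them digit for digit.  Per-window metric values are
integrated over the sparsity ladder by trapezoidal AUC *before* the
across-window variance is taken: AUC is the standard threshold-free
summary, and taking variance after integration keeps one variance per
metric and node.

**Determinism.**  Every stochastic operation takes an explicit seed.  The
pipeline derives per-stage seeds from the master seed by stage-name
hashing, so adding a stage never changes the randomness of earlier ones,
and two runs of the same configuration are identical.

## Problem sizes used in the shipped checks

The test-suite verifies the full default geometry once (165 subjects x 67
windows = 11,055 windowed networks; state recovery and the planted dwell
contrast are evaluated on that cohort with 5 k-means restarts).  K
recovery is checked over 20 reduced cohorts (40 subjects, 30 regions);
NBS size and power over 500/50 simulated 40-subject, 30-region cohorts
with 200 permutations; graph metrics against an exhaustive oracle on 100
random graphs with at most 8 nodes.  The NBS null simulation thresholds
edges at p < 0.02 rather than the pipeline default 0.001: with 435 edges,
the 0.001 threshold leaves the maximal-component-size statistic almost
surely zero and its discrete permutation distribution cannot sit at the
nominal level — 0.02 is the least-discrete regime for that statistic at
this problem size.  The pipeline default remains 0.001.

## Known limitations

* Sliding-window correlation at 60-s windows has few effective degrees of
  freedom after band-limiting; single-edge estimates are noisy, and all
  state inference rests on pooling across the full edge vector.
* The elbow criterion assumes inertia decays roughly linearly away from
  the true K; heavily imbalanced state occupancies can bias it.
* Component-size NBS is conservative when few edges cross the threshold
  (discrete null); intensity-based statistics are out of scope.
* MDT comparisons inherit the variance of a zero-inflated, truncated run
  statistic; power at realistic effect sizes is modest, as in the
  two-group studies this package mirrors.
* Voxel-level preprocessing (realignment, normalisation, nuisance image
  regression, smoothing) is upstream and out of scope: the contract
  begins at parcellated time series.
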