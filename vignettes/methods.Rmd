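---
title: "Methods: the fallsense detection pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the fallsense detection pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model behind `fallsense`, the assumptions it
makes, every tunable parameter with its default and rationale, what the
synthetic generator does and does not emulate, and the numerical choices
that required judgment. Code chunks are shown but not executed; the
worked numbers live in the README and in `scripts/acceptance.R`.

## 1. Signal model and assumptions

The input is a tri-axial acceleration stream in units of g, sampled
uniformly at 20 Hz from a body-worn (waist) sensor. The model assumes:

- **Falls are impacts plus posture change.** A fall produces a short
  high-magnitude transient (the impact) followed by a sustained change in
  the gravity component of the signal (the subject ends up lying rather
  than standing).
- **Non-fall transients lack the posture change.** Vigorous activity
  (jumping, sitting down hard) can cross the impact threshold, but the
  pre- and post-impact gravity orientations match.
- **Routine movement stays below threshold.** Walking-level sway never
  triggers the detector; the classifier only ever sees windows that
  contain a super-threshold sample.

These assumptions shape the whole design: the detector is
threshold-*triggered* (cheap), and the classifier's job is only to
separate fall impacts from activity impacts (hard).

## 2. Windowing and features

`detect_impacts()` finds samples with Euclidean magnitude above
`threshold_g` (default **1.8 g** — comfortably above 1 g gravity plus
routine sway, below the 1.9–5 g range of genuine impacts) and debounces
them greedily with a **2.5 s** dead time so one impact yields one window.
`extract_window()` takes 100 samples covering $[\tau-2.5, \tau+2.5)$
seconds around the trigger: 2.5 s of pre-impact context and 2.5 s of
post-impact recovery at 20 Hz.

`normalize_window()` subtracts the first sample vector from every sample,
so the features measure *change* relative to pre-impact posture rather
than absolute orientation — this is what makes the posture-drift cue
visible to the classifier regardless of how the sensor was mounted.
`magnitude_signal()` collapses the three axes to the Euclidean norm.

`haar_dwt(x, levels)` applies the Haar low-pass filter
$(1/\sqrt2, 1/\sqrt2)$ and downsamples, zero-padding odd lengths on the
right; three levels map 100 → 50 → 25 → 13 coefficients. The third-order
approximation keeps the impact envelope and the post-impact level — the
two physically meaningful cues — while discarding sample-rate noise, and
13 dimensions keeps every downstream component small. The cascade is a
dozen lines and its padding convention is part of the package contract
(tested stage by stage), so it is implemented directly rather than
through a wavelet package.

## 3. Clustering by regrouping particle swarm (RegPSO)

`cluster_regpso()` searches for `n_clusters` centroids (default **8**,
enough to separate fall/exercise/routine morphologies with room for
within-class variety) by global-best PSO over the concatenated centroid
vector. The objective, `quantization_fitness()`, is the mean over
*non-empty* clusters of the mean Euclidean distance from each member to
its nearest centroid. Averaging over all clusters with empties
contributing zero would reward degenerate placements; restricting to
non-empty clusters removes that incentive.

Swarm defaults are the standard constricted-PSO constants: 20 particles,
inertia 0.72, cognitive/social coefficients 1.49. Velocities are clamped
to the per-dimension data range and positions to the data bounding box.
Particles are **initialized at randomly drawn observations** (each
particle's centroids are a random sample of data points) rather than
uniformly in the bounding box: on small instances this is markedly more
reliable, because every starting candidate already partitions the data
non-trivially.

**Regrouping.** When the maximum particle distance to the global best,
normalized by the search-space diameter, falls below `stagnation_eps`
(default $1.1\times10^{-4}$), the swarm has collapsed and is re-scattered
uniformly in a box centered on the best position. The box's
per-dimension extent is the swarm's deviation from the best, inflated by
the regrouping factor $6/(5\,\varepsilon)$ and capped at the original
range. Deviations are floored at $\varepsilon \times \text{range}$ so an
*exactly* collapsed swarm (deviation zero) still re-scatters. The global
best and its fitness are preserved across regroups, so the best-fitness
trace is non-increasing over the entire run — a property the tests
assert.

### A numerical caveat: the objective is discontinuous

The equal-cluster-weighted quantization error is discontinuous in the
centroid positions: moving a centroid so that it captures exactly one
point creates a zero-error singleton cluster and can drop the average
abruptly. On small, heavily overlapping point sets the global optimum is
often such a "needle" — a centroid placed exactly on an outlier — which
any continuous optimizer at a finite budget can miss. Two consequences
for this package:

- partition-enumeration oracles (used in the tests, with
  geometric-median centroids computed by Weiszfeld iteration, since the
  per-cluster minimizer of mean *distance* is the geometric median, not
  the mean) are only a meaningful reference on data that actually has
  cluster structure; and
- the PSO can occasionally *beat* such an oracle, because a fitness
  evaluated at median centroids is not a lower bound for a discontinuous
  objective.

The test suite therefore checks swarm optimality on genuinely clustered
instances, where the enumeration optimum is stable and the swarm attains
it; on real feature data the fitness is used comparatively (lower is
better), never as a claimed global optimum.

`finalize_cluster_model()` summarizes each cluster by its member mean and
per-dimension *population* standard deviation (divide by $n$, so
singleton clusters give $\sigma = 0$ rather than `NA`); an empty cluster
keeps its centroid, receives the global per-dimension SD, and raises a
warning.

## 4. Gaussian cluster knowledge (GCK)

At prediction time, `gck_membership()` scores a feature vector $\gamma$
against each cluster with
$\theta_i = \exp(-\lVert\gamma-\mu_i\rVert^2 / (2 s_i^2))$, where $s_i$
is the root-mean-square of cluster $i$'s per-dimension SDs (a single
scale per cluster keeps the membership a proper radial function). The
best-matching cluster (ties to the lowest index) seeds
`gck_knowledge_signal()`, a componentwise Gaussian draw
$\bar y \sim \mathcal N(\mu_I, \sigma_I)$, and `gck_fuse()` blends
$\vartheta = (A\gamma + B\bar y)/(A+B)$.

Defaults: **`n_gck = 5`** knowledge signals and **A:B = 0.8:0.2**. The
fusion weight keeps the query dominant (the knowledge signal is a
regularizer, not a replacement), and five signals give each classifier
six looks at every input — enough for a meaningful majority without
inflating prediction cost. Augmentation is applied at *test time only*;
the networks are trained on unaugmented features. A system-level test
monitors that raising `n_gck` from 5 to 10 does not buy specificity
beyond noise, supporting the default.

## 5. Classifiers and ensemble

Two networks see the feature vector:

- **MLP:** 13 → 10 sigmoid units → 1 linear output, targets fall = 1,
  ADL = 0, decision threshold 0.5.
- **ARBF:** a radial-basis layer with one Gaussian unit per cluster
  (centers $\mu_i$, scales $s_i$ floored at $10^{-8}$ to avoid division
  by zero), *frozen* from the cluster model, followed by a trainable
  `n_clusters` → 10 → 1 MLP. The frozen layer injects the cluster
  geometry as a fixed basis; only the augmentation network learns.

Both are trained full-batch with **iRprop−** (initial step 0.07, step
bounds $[10^{-6}, 50]$, increase 1.2, decrease 0.5), up to 300 epochs
with early stopping after 50 epochs without validation improvement, and
the best-epoch weights are restored. Rprop is used because its
sign-based updates are insensitive to the badly scaled gradients the
mixed sigmoid/linear architecture produces, and it has no learning rate
to tune; it is implemented in the package since no installed package
provides it. The split is stratified **4:1** train:validation per class
(`split_dataset()`), reproducibly seeded.

`predict.fall_ensemble()` pools votes from both classifiers on the
original input and its `n_gck` augmented variants —
$2(n_{\text{gck}}+1) = 12$ votes — and takes the majority, with **ties
going to "fall"**: in an alarm system a missed fall costs more than a
false alarm.

All randomness fans out from one `pipeline_config(seed = )` through
`derive_seed()` (a Lehmer-style mix), so clustering, splitting, network
initialization, augmentation, and the generator each get independent but
reproducible streams; identical seeds give byte-identical serialized
models (`write_fall_model()` uses versioned JSON with full-precision
numbers).

## 6. The synthetic generator

`gen_fall_window()`, `gen_adl_window()`, `gen_dataset()`, and
`gen_stream()` produce stylized 20 Hz signals:

- a constant gravity unit vector (random orientation) plus Gaussian
  sensor noise (SD **0.05 g**, typical of consumer MEMS at rest);
- impacts as half-sine bursts along a random direction, with the
  amplitude solved exactly so the peak magnitude hits the drawn target
  (falls **2.5–5 g**, within a ±6 g sensor range; exercise **1.9–2.8 g**
  — above threshold, below fall range; `sit_down` **1.9–2.5 g**);
- for falls only, a logistic posture drift to a new gravity orientation
  with a reduced norm (0.5–1.0 g, a lying posture seen obliquely);
- routine windows as sub-threshold sway (0.15 g) that never triggers;
- `gen_stream()` splices events at least 5 s apart into a continuous
  recording so windows never overlap.

Exercise bursts are confined to the window interior so a burst tail
cannot masquerade as posture drift. The generator emulates the *cues the
classifier uses* — impact envelope, threshold crossing, posture change —
not the full richness of human movement: no pre-fall stumble dynamics, no
soft falls that stay under threshold, no non-stationary noise, no sensor
saturation or mounting slip. Accuracies measured on this generator are
an upper bound on real-world performance and are reported as such.

## 7. Problem sizes

Benchmark sizes in the tests and in `scripts/acceptance.R` (400 training
and 400 held-out windows, 3:1 routine:exercise among ADLs; 250 swarm
iterations; 3-seed sensitivity checks) are this package's own choices,
set to exercise every code path while keeping the full suite within a
few minutes on one core. Nothing in the implementation depends on them.

## 8. Limitations

- Synthetic-only validation; no claims about real accelerometer corpora.
- The threshold trigger cannot see soft falls (syncope onto a bed).
- The quantization objective's discontinuity (§3) means the reported
  cluster fitness is a search result, not a certified optimum.
- Single-sensor, fixed sample rate; `extract_window()` requires uniform
  20 Hz spacing and errors otherwise rather than resampling.
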