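---
title: "Methods: compact 3D social pose features and ridge encoding models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compact 3D social pose features and ridge encoding models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question and the model

`socialpose3d` implements an encoding-model analysis of social scene
perception. Two-person video clips are described by one of three feature
families:

* **Dense joints** — each agent's 45 three-dimensional body joints (24
  canonical SMPL body joints plus 21 face, hand and foot landmarks),
  averaged over the clip's 90 frames and flattened to a 270-vector
  (agent-major, joint-major, coordinate-minor).
* **3D social pose** — per agent, the face position (midpoint of the two
  eye joints) and a unit facing direction (the head-center→nose and
  neck→nose vectors averaged, then normalized once), giving 12 numbers per
  clip. Per-frame features are computed first and then averaged over time;
  the time-averaged direction is deliberately *not* renormalized, the
  closest literal reading of "averaged across time".
* **2D social pose** — the same vector with the depth components (z, dz)
  dropped, with no renormalization: a raw projection that loses
  out-of-plane information by construction, 8 numbers per clip.

Each family is mapped to five behavioral ratings (spatial expanse,
interagent distance, agents facing, communicative, physical; 1–5 scale)
with ridge regression,

$$\hat w = \arg\min_w \lVert y - Xw \rVert^2 + \alpha \lVert w \rVert^2,$$

fit on standardized training data and scored as the Pearson correlation
between predictions and ratings on a held-out test split. The package's
central comparisons are (i) 3D pose vs dense joints vs 2D pose, (ii) the
relationship across a population of embedding models between how much 3D
pose information a model carries and how well it predicts social ratings,
(iii) whether adding 3D pose features to an embedding improves its
predictions (grouped ridge), and (iv) whether joints retain predictive
information after the pose features are regressed out (semi-partial
analysis).

Key assumptions: ratings are a (noisy, monotone) function of the latent
scene geometry; the mapping from features to ratings is well approximated
linearly after standardization; and the train/test split is fixed in
advance, with every statistic that influences fitting (standardization,
layer, penalty, group weights) computed from training rows only. The test
suite includes a leakage canary asserting that shuffling test ratings
cannot change any selected hyperparameter.

## Encoding framework parameters

| Parameter | Default | Units / rationale |
|---|---|---|
| penalty grid | 21 points, $10^{-10}\dots10^{10}$ | one per decade; endpoints fixed, density configurable |
| CV layout | 5 folds × 2 repeats | seeded shuffles; selection metric is the unweighted mean validation r |
| z-scoring | population (1/n) SD | any consistent convention works; fixed for reproducibility; zero-variance columns map to zeros |
| SRP distortion ε | 0.1 | Johnson–Lindenstrauss sizing `floor(4 ln n / (ε²/2 − ε³/3))`; applied only when the input is wider than the target (pose/joint features, ≤ 270 wide, are never projected) |
| grouped ridge | 200 Dirichlet draws, concentrations 0.1 and 1.0 (100 each) | γ on the simplex; each standardized group scaled by √γ; shared α grid |
| permutations | 5,000 | p floored at max(count, 1)/n, so the minimum reportable p is 1/5000 = 0.0002 |

Selection ties break toward the smaller penalty, then the
lexicographically first candidate, making every fit deterministic given
its seed. After candidate (layer) selection, the penalty reported is the
one that won jointly with that candidate in the same cross-validation —
the refit on the full training split recomputes only the standardization
statistics and weights.

Ridge solutions are computed through the SVD (`X = UDV'`,
`w = V diag(d/(d²+α)) U'y`), which is stable across the full twenty-decade
penalty range and lets one decomposition serve the whole grid and, for
multi-output fits, all outputs. The grouped-ridge search exploits that
rescaling groups by √γ only rescales the cross-product matrix
(`C_γ = D_γ C D_γ`), so each fold computes `C` once and the search costs
one small eigendecomposition per (fold, γ), shared across the α grid; a
test verifies the search collapses exactly (≤ 1e−6) to plain ridge when
the two groups are identical.

Degenerate cases are defined, not fatal: a zero-variance prediction or
target scores r = 0 with a `zero_variance` flag, and a constant feature
column standardizes to zeros.

## The synthetic generator: what it emulates, and what it does not

The generator stands in for the study conditions the analysis was designed
around: 250 clips of 90 frames, two agents each, ratings averaged over a
panel of at least 10 raters, and an 80/20 train/test split. Its latent
variables are each agent's position (camera frame, meters, +z away from
the camera), unit facing direction, and a positive scene scale.

Scene layout defaults are conventions chosen to be naturalistic and are
stated here once:

* dyad midpoint: x ∈ [−1.5, 1.5] m, y ∈ [−0.3, 0.3] m, z ∈ [3, 7] m,
  all multiplied by the scene scale s (log-uniform on [0.6, 1.8]);
* inter-agent distance: uniform on [0.6, 2.5] m, multiplied by s — people
  stand farther apart in bigger scenes;
* separation direction: anisotropic with axis SDs (1.0, 0.25, 1.6), so
  most separation variance lies in depth, and with the x and z components
  drawn sign-consistent (the nearer agent appears on the left). This
  staging convention matters: with a sign-symmetric layout, depth
  separation |Δz| is an even function of the coordinates and therefore
  invisible to *any* linear readout, which would make the 2D/3D comparison
  vacuous rather than informative. The sign convention makes depth
  information linearly decodable from 3D features while leaving it absent
  from 2D features, which is precisely the contrast the analysis probes;
* facing: each agent faces the other plus isotropic jitter (SD 0.8 before
  renormalization); exact-mutual and uniform modes are available;
* articulation jitter: 2 cm per joint per frame, the order of modern
  per-joint estimator error; detector dropout 0.0012 per frame, failing
  ≈ 10% of 90-frame videos, matching the exclusion rate such pipelines see
  on naturalistic footage. A failed frame invalidates both agents'
  detections — failures are a property of the frame, not the person — and
  any video with an invalid frame is excluded in full.

Ratings are deterministic functions of the latents — expanse = log s,
distance = ‖p₁−p₂‖, facing = mean cosine of each agent's angle to the
other, communicative = facing − 0.3·distance, physical =
max(0, 1 − distance/2 m) — affinely rescaled to [1, 5] per batch, then
perturbed per simulated rater (Gaussian, SD 0.5, clipped to the scale) and
averaged over the panel. The generative forms are inventions: the study
this emulates specifies only *which* latent quantities the ratings track,
not a generative law, so the coefficients are exposed in
`rating_weights()`.

Synthetic embedding models mix a seeded random linear map of the
standardized pose features with Gaussian noise,
`info_level·signal + (1 − info_level)·noise`, plus pure-noise filler
columns. The two endpoints are exact (0 → independent of pose, 1 → fully
linearly decodable) and decodability is monotone in between, which is what
the model-population analyses need. A literal concatenation of a rescaled
signal block would *not* behave this way — after standardization any
nonzero scaling is fully decodable — hence the convex-mixture form.
Synthetic embeddings default to 64 columns: the models carry controlled,
low-rank pose information, so JL-scale widths would add nothing but cost.
The sparse random projection still engages, and is tested, on wide inputs.

What the generator does **not** emulate: articulated motion (bodies are
rigid rest poses, so passing tests say nothing about motion dynamics),
perspective projection (2D features are metric coordinate drops, not pixel
projections), rater psychology (noise is i.i.d. Gaussian), or the
long-tailed layout diversity of real footage. Results on synthetic data
quantify the pipeline's statistical behavior under a known ground truth,
not the effect sizes real videos would produce.

## Numerical and design choices

* **Landmarks by name.** The five landmarks used by the feature extractor
  (eyes, nose, head center, neck) are named template indices, not
  hard-coded integers, because published joint orderings vary; the
  convention is auditable in `make_skeleton_template()`.
* **Skeleton poser.** The renderer applies the minimal rotation taking the
  template's facing axis onto the latent direction, pivoted at the eye
  midpoint, so face position and facing direction recover the latents
  exactly at zero noise (tested to < 1e−6 rad). Full rotation equivariance
  of the poser itself is not attainable — no continuous choice of body
  frame over the sphere of directions is rotation-equivariant — so the
  tests assert the meaningful invariants instead: rigidity, exact latent
  recovery, and translation equivariance.
* **Agent order.** Agents sort by ascending mean horizontal position
  (ties: ascending depth); deterministic and view-based, since no identity
  labels exist.
* **Residualizer penalty.** The semi-partial residualizer selects one
  cross-validated penalty shared across all 270 joint outputs, and among
  penalties whose validation score is within 0.001 of the best it takes
  the smallest. Prediction quality is flat across that range, but removal
  completeness is not: an argmax that drifts to a larger α can leave a
  percent of linearly predictable pose in the residuals, which a
  subsequent encoder will happily exploit when the target is a noiseless
  function of pose. Preferring the smallest indistinguishable penalty
  makes "removed" mean removed.
* **Model-population analyses.** The correlation between pose decoding and
  rating prediction, and the grouped-ridge improvement test, are evaluated
  on the agents-facing rating — the dimension for which the pose-based
  account is most diagnostic — with all five ratings available in the
  pipeline tables.
* **Permutation nulls rescore fixed predictions.** Shuffling the held-out
  ratings and refitting 5,000 × population-size models is neither stated
  in the procedure being emulated nor computationally sensible; the nulls
  therefore shuffle ratings (or scores) against fixed predictions. All
  four tests are verified to hold their nominal 5% level within
  [0.03, 0.07] under their own nulls, and to agree with exhaustive
  enumeration on instances small enough to enumerate.
* **Seeds.** Every random operation takes an explicit seed; the pipeline
  derives per-stage seeds from one run seed through a fixed integer
  scheme, and restores the caller's RNG state afterwards.

## Problem sizes

The shipped test suite and acceptance script run at the sizes the analyses
were designed around: 250-video datasets (the acceptance checks use 50
replicates for the feature-family comparison and 20 for the semi-partial
null, with 150-video datasets for the latter), 30 embedding models
spanning `info_level` ∈ [0, 1], 200 Dirichlet draws, and 5,000
permutations (500 for the 1,000-replicate calibration loops, where only
the rejection rate matters).

## Known limitations

Linear readouts only — ratings that are genuinely nonlinear functions of
the latents (the facing cosine, the clipped physical score) are captured
only up to their best linear approximation, a limitation shared by every
feature family compared. The grouped-ridge solver supports exactly two
groups, as used here. The 2D features are coordinate drops; a
pixel-accurate perspective model would require camera intrinsics the
pipeline does not model. HDF5 containers are not read or written; the
package uses the equivalent documented CSV layouts throughout.
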