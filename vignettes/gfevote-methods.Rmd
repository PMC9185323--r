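---
title: "Multi-perspective soft voting for grammatical facial expressions: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-perspective soft voting for grammatical facial expressions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gfevote)
```

## The problem and the model

Grammatical facial expressions (GFEs) are facial movements that carry
syntactic or prosodic meaning in a sign language: raised eyebrows mark
relative clauses, topics and yes/no questions; furrowed brows mark
wh-questions; lowered mouth corners mark negation; a slight contraction
of eyes and mouth marks interrogative doubt. The input is a stream of
100 facial landmarks per frame from a depth sensor — `(x, y)` in image
pixels, `z` in depth units — with a per-frame binary label saying
whether the expression is present. Each of the nine expressions is
treated as its own binary classification task.

The pipeline has four stages.

**1. Geometric features per frame.** Three feature families are computed
from a configured subset of landmarks (all indices 0-based):

* *Distances*: Euclidean distances in the image plane over an ordered
  pair list, $d_k = \sqrt{(x_i - x_j)^2 + (y_i - y_j)^2}$.
* *Angles*: for each ordered triple $(p_1, p_2, p_3)$, the signed acute
  angle between segments $p_1p_2$ and $p_2p_3$. The slope form
  $\arctan\!\big((s_{12} - s_{23}) / (1 + s_{12} s_{23})\big)$ is
  singular for vertical segments, so the implementation uses the
  equivalent `atan2` difference of the segment direction angles, wrapped
  into $(-\pi/2, \pi/2]$; the two coincide wherever the slope form is
  defined (this equivalence is asserted against an independent oracle in
  the test suite). Angles are kept signed.
* *Depths*: the raw $z$ of each distinct landmark in the pair list, in
  first-occurrence order. Depths are the only place the third coordinate
  enters; distances and angles are deliberately 2D.

The default pair list is formed from consecutive disjoint pairs of the
flattened landmark selection in its listed region order, and the triple
list from consecutive disjoint triples. The published landmark
selections do not pin down the exact pairings, so these defaults are a
documented convention and both lists are fully configurable.

**2. Sliding windows.** Features of `sw` consecutive frames are
concatenated frame by frame (distances, angles, depths of frame $t$,
then frame $t+1$, ...). A window's label comes from its frame labels
under a configurable policy; the default is majority with ties counted
as positive, which is the least brittle choice for prosodic expressions
that span many frames (`last` and `all` are also provided). Windows
never cross sequence boundaries.

Two stride conventions coexist in this family of methods: the formal
perspective construction indexes windows densely (stride 1, giving
`sfe - sw` windows for a sequence of `sfe` frames — a count the package
preserves exactly, including its unused trailing frame), while the
experimental protocols slide windows so that consecutive windows
*overlap by one frame* (stride `sw - 1`). The package default for
`build_windows()` is stride 1; the evaluation protocols default to the
overlap-one-frame setting. The protocol choice matters statistically:
windows that share 9 of 10 frames are near-duplicates, and random
cross-validation folds over such windows let a high-capacity classifier
score well by matching test windows to their neighbors — with
label-free data this inflates ROC-AUC from 0.5 to roughly 0.65. With
one-frame overlap the folds are honest. Both behaviors remain available
through `window_stride`.

**The doubt-expression variant.** For interrogative doubt the
distance/angle dynamics are subtle, so two shape features are added for
three landmark groups (left eyebrow, mouth, left eye): the enclosed
polygon area (absolute shoelace value, orientation-independent) and the
principal-axes ratio (eccentricity), $\sqrt{\lambda_{\max} /
\lambda_{\min}}$ of the 2×2 covariance of the group's points, reported
as major/minor so it is always $\ge 1$ and rotation/translation
invariant. Near-collinear groups, where the minor axis degenerates, are
an error by default (`collinear = "inf"` returns a sentinel instead).
And instead of concatenating frames, each windowed base feature
(distances, angles, areas, eccentricities — depths are not part of this
variant) is summarized by seven statistical descriptors: mean, standard
deviation, maximum, minimum, median, 25th and 75th percentile, in that
order. The standard deviation uses the population convention (divisor
$n$) and percentiles use linear interpolation (R quantile type 7); the
conventions are arbitrary but fixed and tested.

**3. Perspectives.** The flattened window vector is split into three
contiguous, ordered, non-overlapping slices. When `sw` is divisible by 3
these are exactly the frame-aligned thirds; otherwise the slices are as
equal as possible (longer slices first). Defining the split on the
flattened vector keeps it well defined for every window size the
protocols use (including `sw = 2`, which cannot be frame-aligned into
thirds) and for the descriptor variant. Concatenating the three parts
always reproduces the input — a property test in the suite.

**4. Soft-vote fusion.** One probabilistic random forest (the `ranger`
backend) is trained per perspective on the shared window labels. The
fused score of class $i$ is $\sum_{j=1}^{3} w_j\, p_{ij}$ and the
decision is its argmax, with ties resolved to the lowest class index so
predictions are deterministic. Weights are uniform by default and fixed;
rescaling all weights by a positive constant never changes a decision.
Forest class-probability outputs are used as-is — they are vote
fractions, not calibrated probabilities, which is acknowledged rather
than corrected. A flat-aggregation baseline (one forest on the full
concatenated vector) is provided purely for comparison.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `window_size` (`sw`) | 10 frames | window length; the cross-subject protocol uses per-expression sizes (affirmative 4, conditional 10, doubt 5, emphasis 10, relative 10, topic 10, wh 2, negative 6, y/n 10) |
| `window_stride` | 1 (builders), `sw - 1` (protocols) | frames between window starts |
| `label_rule` | majority, ties positive | window label from frame labels |
| `normalization` | z-score | per-feature standardization; fitted on training folds, applied unchanged to test folds |
| `weights` | uniform (1/3 each) | soft-vote weights |
| `classifier_params` | `num.trees = 300` | passed to `ranger::ranger()` |
| `seed` | 1 | controls balancing, folds and forest growth |

The tree count is the package's own default: 300 trees give stable vote
fractions at the study's sample sizes (a few hundred windows per task)
while keeping a full protocol run fast; the original method specifies no
forest hyperparameters, so everything else follows the library defaults.

## Evaluation protocols

Four protocols, each run independently per expression: `subj1-cv` and
`subj2-cv` (stratified 10-fold CV within one subject), `pooled-cv` (both
subjects pooled) and `cross-subject` (train on subject 1, test on
subject 2). Because the expression episodes are rare relative to neutral
frames, the larger class is subsampled uniformly at random to the
minority count before cross-validation (a per-fold option exists); the
minority class is never touched. Folds are stratified at window level
via `caret::createFolds`, metrics are computed once over the pooled
out-of-fold predictions (micro pooling, which is stable at small n), and
normalization statistics are fitted inside each training fold only — the
fold objects expose those statistics so the leakage guard is itself
testable.

Metrics are positive-class F1 ($2PR/(P+R)$, 0 when no positive is
predicted or present), accuracy, and ROC-AUC of the fused positive-class
score (midrank tie handling, via `pROC`; `NaN` with a warning when only
one class is present). F1 is reported for the expression-present class
because each task is binary.

The cross-subject protocol standardizes each subject's windows with that
subject's own feature statistics — an unsupervised calibration that uses
no labels. This choice is deliberate: statistics fitted on the training
subject cannot remove even a purely rigid offset of the test subject's
head (a constant depth shift lands the test windows many standard
deviations outside the training distribution and breaks the forests'
thresholds), whereas per-subject centering removes exactly the rigid
component while leaving genuine shape differences in place. Within
subject, fold-fitted statistics remain the strict, leak-free choice.
Classes are balanced on both sides so cross-subject F1 is computed at
the same class prior as the within-subject numbers.

## The synthetic study

`simulate_study()` generates the full input the protocols expect: two
virtual subjects × nine expressions, each a labeled landmark stream in
the package's file dialect. Defaults (chosen once, as the package's
study conditions): 2700 frames per sequence (90 s at 30 fps), one
40-frame expression episode per ~125 frames (positive-frame fraction
≈ 0.31), peak deformation 10 px, and i.i.d. Gaussian landmark jitter of
1 px — typical of depth-sensor face tracking. Episode amplitude ramps
linearly over the first and last two frames, so windows straddling a
boundary are genuinely ambiguous and exercise the label rules.

Deformation templates translate each expression's qualitative
description into landmark displacement directions: brow raises (which
also widen the eye aperture), mouth-corner lowering for negation, eye
and mouth contraction for doubt (which is what makes the area and
eccentricity features informative there), and — as in real prosodic
expressions — accompanying head motion: nods, forward/backward lean and
yaw realized as whole-face displacement and depth gradients. The head
motion matters: features between far-apart landmarks are insensitive to
motion perpendicular to their separation, so purely local brow templates
produce weak distance responses; the depth channel is where whole-head
prosody is most visible, exactly as with a physical depth sensor.

Subject 2 is viewed under a subject transform: by default a rigid offset
(translation `(15, -10, +30)` and a 0.05 rad in-plane rotation), which
distances and angles are invariant to and per-subject standardization
absorbs; optionally a strong non-rigid deformation — a short-wavelength
sinusoidal warp of the image plane (8 px at 15–20 px wavelengths)
combined with a saturating compression of the depth profile — that
distorts relationships *between* features and therefore genuinely
degrades cross-subject transfer (to an average F1 around 0.84 at the
default conditions) without destroying it. Smoother warps turn out to be
locally affine at landmark scale and are fully absorbed by per-feature
standardization; the depth compression is what creates the partial
transfer regime.

What the generator does *not* emulate: real expression co-articulation
and timing variability, correlated sensor noise and dropouts,
inter-individual differences in expression style (only in face
geometry), and the empirical difficulty of any real dataset. Passing the
packaged tests therefore shows the pipeline is correct and recovers
planted structure under realistic geometry and noise — not that it
attains any particular accuracy on real recordings.

## Numerical choices and degenerate inputs

* Angle wrapping: results lie in $(-\pi/2, \pi/2]$; collinear points
  give 0; coincident points are a validation error.
* Zero-variance feature columns are centered only (scale fixed at 1).
* Argmax ties in the soft vote go to the lowest class index.
* Balancing, fold assignment and forest growth derive independent
  sub-seeds from the master seed, so every protocol is bit-reproducible
  and sub-seeds never collide across stages.
* File round-trips write 15 significant digits; read∘write is identity
  to well below 1e-9.
* Single-class inputs: training refuses with the missing class named;
  ROC-AUC returns `NaN` with a warning.
* Sequences shorter than `sw + 1` frames are rejected by name with both
  numbers in the message.

## Problem sizes used by the packaged checks

The test suite and the acceptance script run entirely on generated data:
unit fixtures use sequences of 60–700 frames; the end-to-end
parameter-recovery and cross-subject checks use the default study
conditions above (2700-frame sequences, ~300 windows per task at the
protocol stride, ~200 after balancing), three master seeds for the
recovery medians, and 10-fold CV. A full four-protocol run takes about a
minute on one CPU.

## Known limitations

* The exact landmark pairings behind the published feature sets are not
  recoverable; the consecutive-pairs convention is a documented stand-in
  and everything is configurable.
* Forest vote fractions are used uncalibrated; ROC-AUC is unaffected but
  fused scores should not be read as probabilities.
* Soft-vote weights are fixed uniform; weight learning, stacking and
  hard voting are out of scope, as is any significance testing between
  methods.
* The window-level CV protocols measure within-recording generalization;
  with dense stride-1 windows they would partly measure memorization
  (see the stride discussion above), which is why the protocols default
  to one-frame overlap.
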