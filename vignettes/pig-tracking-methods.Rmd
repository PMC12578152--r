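---
title: "Methods: population-capped tracking of group-housed pigs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population-capped tracking of group-housed pigs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pentrack)
```

## The problem

Overhead video of a pen of group-housed pigs yields per-frame detections
(bounding box, confidence, behavior class, optionally an appearance
embedding). The task is to stitch those detections into persistent
identities. Two properties of pig pens make stock multi-object trackers
fragile: the number of animals is essentially constant, and occlusion is
frequent — pigs pile up, the detector drops the hidden animal for a few
frames, and when it reappears the tracker is tempted to mint a fresh
identity. Over a long video the maximum identity number then grows far
beyond the number of pigs, and identity switches accumulate.

`pentrack` implements the components of a detection-and-tracking pipeline
adapted to this setting: the Shape-IoU bounding-box regression loss, the
CBAM attention forward pass, a DeepSORT-style tracker with two specific
modifications (a second IoU matching round and population-capped track
creation), CLEAR-MOT / IDF1 evaluation, and a pen simulator that lets the
whole system be exercised without any video data.

## Shape-IoU loss

For a predicted box $B = (x_c, y_c, w, h)$ and a ground-truth box
$B^{gt} = (x_c^{gt}, y_c^{gt}, w^{gt}, h^{gt})$ the loss is

$$L = 1 - \mathrm{IoU} + d_{shape} + \tfrac{1}{2}\Omega_{shape},$$

with shape weights derived from the ground-truth aspect,

$$ww = \frac{2\,(w^{gt})^{scale}}{(w^{gt})^{scale} + (h^{gt})^{scale}},
\qquad
hh = \frac{2\,(h^{gt})^{scale}}{(w^{gt})^{scale} + (h^{gt})^{scale}},$$

a cross-weighted normalized center distance
$d_{shape} = hh\,(\Delta x/c)^2 + ww\,(\Delta y/c)^2$ where $c$ is the
diagonal of the smallest box enclosing the pair, and a shape-discrepancy
term $\Omega_{shape} = \sum_{t \in \{w,h\}} (1 - e^{-\omega_t})^\theta$
with $\omega_w = hh\,|w - w^{gt}|/\max(w, w^{gt})$,
$\omega_h = ww\,|h - h^{gt}|/\max(h, h^{gt})$ and $\theta = 4$.

Two notational choices deserve a note. Transcriptions of this loss
sometimes label both weight equations `hh` and write the second
discrepancy term `wh`; we follow the original Shape-IoU convention (the
one given above), under which the weights sum to 2 and all stated
invariants hold. The normalizer $c$ is likewise taken as the enclosing-box
diagonal, the convention of the Shape-IoU method; the defaults are
`scale = 0` (collapsing both weights to
1) and `theta = 4`. Degenerate boxes (non-positive width or height) are
rejected rather than clamped: clamping would silently mask simulator or
adapter bugs.

```{r shape-iou}
shape_iou_loss(box(1, 0, 2, 2), box(0, 0, 2, 2))
```

## CBAM forward pass

The attention module is implemented as pure array math on a
$C \times H \times W$ feature map: channel attention
$\sigma(\mathrm{MLP}(\mathrm{avgpool}\,f) + \mathrm{MLP}(\mathrm{maxpool}\,f))$
with a shared two-layer MLP (reduction ratio $r$, ReLU between layers),
then spatial attention $\sigma(\mathrm{conv}_{7\times7}[\mu_c; \max_c])$
with zero padding 3 so spatial size is preserved. Weights are supplied or
generated (seeded) for testing — no training happens here, and assembling
the module into a detector backbone is out of scope. Because both gates lie
strictly inside $(0,1)$, refinement strictly shrinks every nonzero entry;
the tests rely on this as a structural invariant.

## The tracker

Per frame the tracker executes: Kalman prediction for every live track;
appearance cascade matching of confirmed tracks (staleness-ordered,
Hungarian assignment on minimum cosine distance to the track's embedding
gallery, Mahalanobis-gated at the 0.95 chi-square quantile with 4 degrees
of freedom); a first IoU matching round over tentative tracks plus
confirmed tracks missed by the cascade that were updated last frame; a
second IoU round over *all* remaining unmatched tracks; population-capped
creation; and lifecycle pruning (tentative tracks die when unmatched in
their frame, confirm after 3 hits; confirmed tracks die when unmatched for
more than 30 frames).

The motion model is the de-facto DeepSORT constant-velocity filter on
$(x_c, y_c, a, h)$ with height-scaled noise (position weight 1/20, velocity
1/160), since the capped-tracking scheme itself fixes no filter constants.
Detections below
`min_confidence = 0.8` (the stock DeepSORT pipeline value) are discarded
before association.

The two improvements:

* **Second IoU round.** Round 1 deliberately excludes confirmed tracks
  stale by more than one frame (the stock convention). The second round
  offers the leftover detections to those stale tracks, recovering
  re-appearances whose corrupted embedding failed the appearance gate.
* **Population cap.** The pen population estimate $n$ is the half-up
  rounded mean of the raw detection counts of the most recent 3 frames.
  After the first frame (which creates one track per detection), a new
  track is created only while $n$ exceeds the count of alive (tentative +
  confirmed) tracks; excess unmatched detections are dropped. Counting all
  alive tracks rather than confirmed only is deliberate — a flood of
  tentative tracks would otherwise overshoot $n$. The creation routine
  asserts the invariant (never create at or above capacity) on every
  simulated frame.

`mode = "baseline"` disables both modifications, giving the stock
track-management behavior for A/B comparison. Behavior classes never gate
association; a track reports the majority label of its recent assigned
detections (window 3, ties to the most recent), since class flicker from
the detector should not fragment identities.

Where the scheme leaves details open we chose: the round-2 IoU
threshold defaults to the round-1 value (0.7 on $1-\mathrm{IoU}$ cost);
$n$ is computed from the current and two previous raw (post-confidence
filter) detection counts, before creation; both choices are exposed in
`tracker_config()`.

## Evaluation

`clear_mot()` follows the CLEAR-MOT protocol: per frame, pairs matched in
the previous frame persist while their IoU stays at or above the threshold
(0.5, the community default), the remainder is matched by minimum-cost
assignment on $1 - \mathrm{IoU}$; an identity switch is counted when a
ground-truth object's matched hypothesis id differs from its last matched
id. MOTP is reported as the mean IoU of matched pairs in percent — the
overlap form, which is what makes values like "94.9" readable; a
distance-based MOTP would live on a pixel scale. IDF1 uses the global
one-to-one id assignment maximizing identity true positives, solved
exactly by the same Hungarian solver and cross-checked in the tests against
(a) an exhaustive id-bijection oracle and (b) an independent scipy-based
reference implementation.

A worked detail: a trajectory covered half by one hypothesis id and half
by another scores IDF1 = 50, since the best assignment keeps one id
(IDTP $= T/2$, IDFP $=$ IDFN $= T/2$). The mid-sequence swap of two
perfectly tracked objects also scores 50.

## The simulator

`simulate_pen()` emulates the structure of overhead pen footage rather
than its pixels: a 2688 x 1520 px frame at 25 fps, pens of 7 (sparse) to 16
(dense) pigs, day or night, four behavior states. Pigs follow a bounded
random walk with per-behavior speeds (lying pigs do not move); behaviors
evolve by a sticky Markov chain; attacks are paired episodes in which two
pigs rush toward each other for a geometric-length burst — modeled on the
most frequent interaction subtype — rather than through the transition
matrix. The detector degradation model applies, in order: occlusion
dropouts (the rear box of a pair overlapping above `occlusion_iou` is
dropped with probability `occlusion_drop_p`; "rear" is the smaller-cy box,
a farther-from-camera proxy under an overhead view), independent misses
(multiplied by 3 at night), Gaussian localization jitter, Poisson false
positives at low confidence, and class confusion. Identity embeddings are
fixed random unit vectors per pig, re-noised and renormalized every frame.

Defaults: body 300 x 160 px (log-normal 8% per-pig spread), walking speed
8 px/frame (about 0.5 m/s at the plausible pixel scale of the arena),
eating 2, attacking 20; `miss_p = 0.02`, `fp_rate = 0.2`/frame,
`jitter_sigma = 2` px, `occlusion_iou = 0.3`, `occlusion_drop_p = 0.5`
(0.6 in the dense-night preset, which also raises the attack rate to
0.05). No quantitative occlusion or detector-noise rates exist for the
real farm; these are calibration choices that produce detector quality in
the realistic 85-95% MOTA band, fixed once and not claims about any
particular barn. One RNG stream per scene, consumed in a documented fixed
order, makes every scene a pure function of its config.

What the simulator does *not* model — appearance drift with pose and
lighting, detector-correlated misses, pen furniture, the head-contact
attack subtypes, camera distortion — bounds what a passing test means:
green tests certify the algorithmic machinery (association, capping,
metric arithmetic), not field performance on real video.

## Numerical choices

* Hungarian assignment: shortest augmenting path with dual potentials,
  deterministic (rows in index order, lowest-column tie-break); entries
  above the cost cap are replaced by a large sentinel and such matches are
  discarded afterward. Rectangular problems pad the smaller side with a
  constant, which cannot change the optimal assignment of real entries.
* Kalman covariances are re-symmetrized after every update; aspect and
  height are floored at a tiny positive value when a state is read back as
  a box. With the height-scaled noise convention, the terminal error on a
  noiseless constant-velocity target is proportional to the target's
  speed (about 0.9% of the per-frame speed after 20 cycles); tests
  therefore probe a slow drift (0.05 px/frame) plus the proportionality
  itself.
* Population rounding is half-up (`floor(mean + 0.5)`); "round" alone is
  ambiguous at .5 and banker's rounding would make the cap depend on
  parity.
* Test problem sizes (e.g. 10 dense scenes of 16 pigs x 500 frames for
  the A/B comparison; 40-frame scenes for the 20-fold metric
  cross-check) were chosen as the smallest sizes at which the compared
  statistics are stable across seeds.

## Known limitations

* Appearance embeddings are inputs; no re-identification model is trained
  or shipped. Without embeddings the cascade degrades to Mahalanobis-gated
  IoU cost (logged once).
* The evaluation implements CLEAR-MOT and IDF1 only; no HOTA, no
  multi-camera support.
* The population cap assumes a closed pen. If animals are added or removed
  mid-video the 3-frame average adapts, but tracks of removed animals
  persist up to `max_age` frames.
* The improved mode's advantage is regime-dependent. In the dense daytime
  regime (detector quality comparable to a strong modern pig detector,
  tracking error in the 90-94% MOTA band) the A/B tests show consistent
  identity-switch reductions. Under far harsher degradation (the
  `dense_night` preset: tripled miss rate, a 5x attack rate, 60% occlusion
  dropout) the second IoU round can hand a leftover detection to the
  *wrong* stale track during attack pileups — one wrong match poisons the
  appearance gallery — and the population cap converts missed
  reacquisitions into long false-negative runs, so the switch advantage
  erodes. The A/B acceptance test therefore runs the daytime dense preset,
  the regime the method is designed for.
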