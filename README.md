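# pentrack

Multi-object tracking of group-housed pigs from overhead video detections.

Automated monitoring of pig behavior (standing, lying, eating, attacking)
needs two things a detector alone cannot give: persistent identities across
frames, and robustness to the occlusion that is endemic in dense pens. When
pigs pile up, the detector drops the hidden animal for a stretch of frames;
a stock tracker then mints a fresh identity on reappearance, so identity
numbers grow far past the number of animals and identity switches pile up.

`pentrack` is an R toolkit for this pipeline, aimed at researchers in
precision livestock farming and quantitative ethology who have per-frame
detections (MOTChallenge-style CSV) and want tracks, evaluation and
controlled benchmarks:

* **Shape-IoU loss family** — the bounding-box regression loss
  `L = 1 − IoU + d_shape + Ω_shape/2`, where `d_shape` is the center
  distance normalized by the enclosing-box diagonal and weighted by the
  ground-truth shape (`ww = 2(w^gt)^s / ((w^gt)^s + (h^gt)^s)`, `hh`
  symmetric, `ww + hh = 2`), and
  `Ω_shape = Σ_{t∈{w,h}} (1 − e^{−ω_t})^θ` with `θ = 4` penalizes width and
  height mismatch. DIoU/CIoU provided as comparison baselines.
* **CBAM forward pass** — channel attention
  `σ(MLP(avgpool f) + MLP(maxpool f))` followed by spatial attention
  `σ(conv7×7[mean_c; max_c])` as pure array math, with a plain-text weight
  archive. (In the detector this module replaces the bottlenecks of the C3
  blocks — `C3 → [conv, CBAM, conv]` — but backbone assembly and training
  are out of scope here.)
* **Improved DeepSORT tracker** — Kalman motion model on `(cx, cy, a, h)`,
  appearance cascade matching with Mahalanobis gating, Hungarian IoU
  matching, plus two pen-specific modifications: a **second IoU round**
  that offers leftover detections to stale tracks, and a **population cap**
  that creates new tracks only while the rounded 3-frame average detection
  count exceeds the number of alive tracks. A `baseline` mode disables both
  for A/B comparison.
* **CLEAR-MOT / IDF1 evaluation** — MOTA, MOTP (overlap form), IDF1,
  identity switches, recall, precision.
* **Pen simulator** — 7–16 pigs in a 2688×1520 px arena at 25 fps, behavior
  Markov chain with paired attack bursts, and a detector degradation model
  (occlusion dropout, misses with a night multiplier, jitter, false
  positives, class confusion) plus noisy identity embeddings, so the whole
  system runs with no video data.

## Worked example

```r
library(pentrack)

cfg <- pen_preset("dense_day", n_frames = 500, seed = 1007)
scene <- simulate_pen(cfg)
scene
#> pen_scene: 16 pigs, 500 frames, 8000 gt rows, 7508 detections (89 FP)

baseline <- track_sequence(scene$detections,
                           tracker_config(mode = "baseline"), scene$embeddings)
improved <- track_sequence(scene$detections,
                           tracker_config(mode = "improved"), scene$embeddings)
cat("max id, baseline:", attr(baseline, "max_id"),
    " improved:", attr(improved, "max_id"), "\n")
#> max id, baseline: 19  improved: 16

compare_runs(scene$gt, baseline, improved)
#>           MOTA  MOTP  IDF1 IDS  RCLL PRCN
#> baseline 92.21 96.47 92.18   4 92.26  100
#> improved 92.22 96.45 95.96   0 92.22  100
#> delta     0.01 -0.01  3.78  -4 -0.04    0
```

Reading the numbers: the simulated detector loses ~6% of boxes to occlusion
and misses (recall 92), which caps MOTA for both trackers. The baseline
fragments occluded pigs into 19 identities with 4 switches; the improved
tracker keeps the identity count at the true pen population (16), removes
all switches, and gains 3.8 points of IDF1 — identity quality improves
while detection-limited MOTA stays put. The Shape-IoU breakdown for a toy
pair:

```r
shape_iou_loss(box(1, 0, 2, 2), box(0, 0, 2, 2))
#> Shape-IoU: loss 0.743590 (IoU 0.333333, dist 0.076923, omega 0.000000; ww 1.0000 hh 1.0000)
```

## Command line

A thin Rscript CLI wraps the same functions (`inst/cli/pentrack`):

```sh
pentrack simulate --preset dense_day --n-frames 500 --seed 7 \
    --out-gt gt.txt --out-det det.csv --out-emb emb.txt
pentrack track --dets det.csv --emb emb.txt --mode improved --out res.csv
pentrack evaluate --gt gt.txt --res res.csv --out report.json
pentrack compare --gt gt.txt --res base.csv --res2 impr.csv --out report.json
pentrack loss-table --pred pred.txt --gt labels.txt --img-w 2688 --img-h 1520
```

Every artifact gets a `.meta.json` sidecar recording package version, seed
and a hash of the effective configuration.

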