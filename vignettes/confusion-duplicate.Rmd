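---
title: "Confusion duplicate and regional drop: methods and design notes"
author: "confaug"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confusion duplicate and regional drop: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(confaug)
```

## The model

Dense instance segmentation of human round spermatids is dominated by two
error families: confident detections on debris or background texture, and
weak, low-confidence responses on true cells. `confaug` treats the
detector's own per-iteration output as a mining signal for both. After each
forward pass with ground truth $G$, image $I$ and predictions $P$ scored by
$c(\cdot)$:

* **eq1 zoo** — for every prediction with $c(P) < c_t$, the pixelwise
  intersection $G \cap P$ is tight-cropped and appended. These crops are, by
  construction, subsets of true-object pixels.
* **eq2 zoo** — for every prediction with $c(P) > c_t$ whose overlap ratio
  with each ground-truth instance is at most $\gamma$, the pixels
  $(I \setminus G) \cap P$ are tight-cropped and appended. These crops are,
  by construction, disjoint from all ground truth.

Both zoos are bounded FIFOs of capacity $T$: an update beyond capacity
evicts the first-entered element, so a zoo always holds the $T$ most recent
crops and tracks the detector's current confusion profile rather than stale
errors from early training. Before the next iteration's forward pass, each
zoo independently contributes (with probability $p_1$) a uniformly sampled
crop, pasted hard through its mask at a uniformly drawn collision-free
location. Regional drop then zeroes a $k \times k$ block inside each
informative region with probability $p_2$. The augmented stream realises the
training objective as an expectation over images, sampled zoo regions and
the augmentation pipeline; the package embodies that expectation through the
sampling loop itself (`runDemoLoop()`) rather than computing it in closed
form.

On the published naming: the prose of the source method calls the first
collection "FP Zoo" and the second "FN Zoo", yet its first update rule
collects low-confidence hits *on true objects* (classically false negatives)
and its second collects confident hits *on background* (classically false
positives). The package implements the update rules verbatim and names the
zoos after the rules (`eq1_zoo`, `eq2_zoo`), exposing `fpZoo()`/`fnZoo()`
aliases for the published names. No attempt is made to guess which naming
was intended.

## Parameters that matter

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `confidenceThreshold` ($c_t$) | 0.5 | score | strict on both sides: a score exactly $c_t$ enters neither zoo |
| `overlapThreshold` ($\gamma$) | 0.5 | ratio | intersection / prediction-area by default; IoU selectable |
| `capacity` ($T$) | 10 | crops | per zoo |
| `p1`, `p2` | 0.5 | probability | paste / drop triggers |
| `dropBlockK` ($k$) | auto | px | auto = quarter of the region's short side, clamped to ≥ 1 |
| `maxPasteOverlap` | 0.3 | IoU | placement rejection against existing instances, ≤ 10 attempts |
| `minCropSize` | 2 | px | harvested slivers below 2 px on a side carry no texture and are discarded |
| `targetSize` | 1024 | px | bilinear resize after square padding |
| `noiseScale` / `blurSigma` | 0.08 / 1.0 | intensity sd / px | common augmentations |

The source method fixes $T = 10$ and $p_1 = p_2 = 0.5$ but leaves $k$, the
block count, the overlap definition for $\gamma$ and all placement policy
unspecified. The choices above are this package's: one block per region
keeps the expected occlusion mild; the auto rule scales $k$ with the object
rather than the frame; the overlap ratio is read as "fraction of the
prediction explained by ground truth" because that is what the defining
sentence describes, with IoU available behind `overlapMode`. The colour
normalisation std is implemented verbatim as (0.299, 0.224, 0.225) even
though the first component differs from the near-universal ImageNet value
0.229 — it is overridable, and the discrepancy is deliberately not
"corrected".

Label semantics of pastes were also left open upstream: here eq1 crops
become new ground-truth instances (they are pixel subsets of real cells,
and the paste log plus instance bookkeeping keep the accounting exact),
while eq2 crops are pasted as unlabelled hard background. This is the only
assignment under which pasting "confusing" regions can sharpen the
foreground/background boundary rather than corrupt the labels.

## Preprocessing and augmentation order

The deterministic chain is alpha removal → symmetric zero-padding to square
(odd pixel to the far border) → bilinear resize (masks by nearest-neighbour,
boxes scaled analytically to avoid resampling jitter) → channel duplication
→ per-channel z-score. The training-time order is flips → noise → blur →
confusion duplicate → regional drop → colour normalisation: pasting happens
in raw intensity space so crops stay photometrically consistent, and pasting
*before* dropping makes pasted footprints drop-eligible. Gaussian blur is a
separable convolution under half-sample symmetric (reflective) padding,
which conserves the global pixel sum exactly for the symmetric kernel;
kernel radius is $\lceil 4\sigma \rceil$.

## The evaluation metric

The per-image score divides the precision-weighted sum of correct
predictions by the number of *correct* predictions (not the ground-truth
count), then averages over images. Matching is greedy in descending score
order at strict union-overlap $> 0.5$, one prediction per ground-truth
instance. Two consequences worth knowing: the metric is precision-flavoured
(a missed cell only hurts via images left with zero correct predictions,
which contribute 0), and incorrect predictions ranked below every correct
one do not lower it. The degenerate-case convention is read charitably as
"term = 0 when the denominator is 0" — the literal published statement
zeroes images with a *positive* correct count, which would annihilate the
metric and contradict the published scores. `cocoAveragePrecision()` offers
the conventional recall-normalised AP for comparison; it is never the
default. `mapScoreBruteforce()` re-evaluates everything from scratch per
cutoff and is the oracle the optimised path is tested against to 1e-12.

## What the synthetic generator emulates — and what it does not

`generateImage()` renders flat bright disks (intensity 0.75) with dimmer
nuclei (0.55) on Gaussian background noise (level 0.15, sd 0.03), plus
irregular unlabelled debris polygons. Geometry follows the imaging setup of
the motivating data: 0.212 µm/pixel, 11 µm cells, 7 µm nuclei, hence ~52 px
cell disks; diameters get ±10% uniform jitter and cells are packed without
mutual overlap (an infeasible packing is a hard error, not a silent
truncation). Intensities are plausible-looking choices, fixed once.

This is *not* phase-contrast optics: no halos, no defocus, no texture inside
the cytoplasm, no overlapping cells. Passing tests therefore demonstrate
geometric and label correctness of the operators, zoos and metric — not that
a detector trained with these operators improves on real micrographs. The
same applies to `mockPredict()`: it is an error model (miss rate, spurious
rate, jitter, Beta-distributed confidences), not a CNN. The real detector
(a cascaded region-based CNN in the motivating work) sits behind the adapter
contract of `runDemoLoop()`: any `function(image) -> list of Prediction` can
be plugged in, and contract violations fail hard with a named reason. Those
training hyperparameters that a real run would need (30 epochs, AdamW with
weight decay 0.05, eps 1e-8, betas (0.9, 0.999), 500-iteration warmup,
three cascade RoI stages) are recorded as configuration documentation, not
executed here.

## Numerical choices, ties and degenerate inputs

* Score ties in matching break by ascending prediction index (stable).
* Masks binarise at strict `> threshold` (default 0.5) on construction of a
  `Prediction`; all overlap computations run on binary masks.
* Boxes are 0-based COCO `[x, y, w, h]`; masks are full-frame logical
  matrices in memory and uncompressed column-major RLE on disk. JSON numbers
  are written at 17 significant digits so boxes and scores round-trip
  bit-exactly.
* A zero-area union yields overlap 0; empty prediction sets yield score 0;
  an empty zoo yields no paste; `p1 = p2 = 0` makes the whole augmentation
  the identity on pixels and annotations.
* Split sizes use floors with the remainder to test
  (8003 → 6402/800/801); images are assigned whole, greedily to the subset
  furthest below its instance-count target, which reproduces target counts
  whenever the per-image counts permit.

## Desk-scale problem sizes

The shipped experiments are sized for a single CPU: the end-to-end demo runs
200 frames of 256 px (per-cell geometry unchanged at ~52 px) for 200
iterations, and the paired directional comparison uses 40 frames of 192 px
for 80 iterations, ten seed-matched pairs. The directional experiment uses
`adaptiveMockPredictor()`, whose miss and spurious rates decay exponentially
with the number of labelled/unlabelled pastes it has been exposed to — a
deliberately favourable stub that turns "re-exposure to hard examples helps"
into a testable ordering on the package's own metric. It shows the loop's
plumbing transmits the augmentation signal; it is not evidence about real
detectors.

## Known limitations

* Single category only; multi-class zoos are out of scope.
* Pastes are hard copies (optional 1-px feather); no Poisson blending, no
  geometric jitter of crops.
* Compressed (LEB128-style) COCO RLE strings are not parsed — uncompressed
  integer counts and polygons are.
* The metric is the per-image precision-weighted form described above;
  scores are not comparable to COCO mAP@[.5:.95] numbers.
* Synthetic-data realism as described: geometry yes, optics no.
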