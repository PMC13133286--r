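---
title: "Skeletal tool poses and the tip-invariant keypoint metric"
author: "ToolPoseKit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Skeletal tool poses and the tip-invariant keypoint metric}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ToolPoseKit)
```

## The data model

Minimally invasive surgical instruments are slender, mostly rigid objects
seen through an endoscope: a shaft enters the circular content area of the
frame, runs to a hinge, and ends in one tip (rigid probes, hooks) or two
tips that can open (graspers, scissors). ToolPoseKit represents each
instrument instance as a four-slot skeleton:

* **EntryPoint** — where the shaft crosses the circular field-of-view
  boundary. It is a dynamic landmark of the view, not of the tool.
* **HingePoint** — the shaft–tip junction (rigid tools) or the articulation
  joint (articulated tools).
* **Tip1 / Tip2** — the instrument end points. For symmetric jaws the two
  tips form an *unordered* set, which is what motivates the metric below.

The chain edges are Entry–Hinge, Hinge–Tip1 and Hinge–Tip2. Every keypoint
carries one of three visibility states: `visible` (directly seen),
`occluded` (hidden by tissue, by the circular vignette, or lying outside the
frame, but inferable from the rigid geometry) and `missing` (physically
absent — e.g. the second tip of a rigid tool — or not inferable). Missing
keypoints are stored as a (0, 0) sentinel and excluded from all arithmetic
*by tag, never by coordinate value*. Occluded keypoints may carry
out-of-frame ("padding area") coordinates, including negative ones; this
keeps the skeleton structurally complete even when the shaft leaves the
frame. A *transition point* marks the farthest visible position along an
edge whose far endpoint is not visible.

Coordinates are continuous and 0-based, with the origin at the top-left
corner of the top-left pixel; a visible point must satisfy the half-open
bounds `0 <= x < W`, `0 <= y < H`. This convention removes any ±1 ambiguity
between the annotation dialect, the COCO-style export and the mask raster
(pixel `[r, c]` of a mask has centre `(c - 0.5, r - 0.5)`).

Two on-disk dialects are supported. The per-frame dialect
(`raw.json`) stores parallel `nodes`/`tags`/`edges`/`transitions`
structures; tags are `"ROLE:visibility"` strings, a transition node splits
the edge it sits on, and distinct instruments are distinct connected
components. Because the upstream description fixes the field names but not a
complete example, the remaining details (tag spelling, sentinel nodes for
missing slots, always writing the three chain edges) are this package's own
canonical choices, and unknown top-level fields are carried through a
parse/serialize round trip untouched. The COCO-style export flattens each
pose to four `(x, y, v)` triplets in the fixed order EntryPoint, HingePoint,
Tip1, Tip2 with `v = 2` (visible), `v = 1` (occluded inside the frame),
`v = 0` (everything else); `num_keypoints` counts triplets with `v > 0`.

## Bounding boxes and the diagonal-squared area

Per-instance boxes are derived from the keypoints with `v > 0`: their
axis-aligned extent, expanded by a 20-pixel margin on all sides, then
clipped to the frame. The margin compensates for the collapse of the raw
extent when a slender tool lies horizontal or vertical. The stored `area`
field is deliberately the *squared diagonal* `w² + h²` of that box rather
than the conventional `w·h`; the evaluator never interprets `area`
conventionally but derives its scale from the box dimensions (below), so
the two conventions cannot be mixed up silently.

## The modified Object Keypoint Similarity

For a predicted pose $p$ and a ground-truth pose $g$ with visibility flags
$v_i$:

$$\mathrm{OKS}(p, g) =
  \frac{\sum_i \exp\!\left(-\dfrac{d_i^2}{2 s^2 \kappa_i^2}\right)\,
        \delta(v_i > 0)}
       {\sum_i \delta(v_i > 0)}$$

with $d_i$ the Euclidean distance of keypoint $i$, and two deliberate
departures from the human-pose convention:

1. **Rotation-robust scale.** Instead of $s = \sqrt{wh}$, the scale is the
   root mean square of the box dimensions,
   $s = \sqrt{(w^2 + h^2)/2}$. For elongated tools $wh$ collapses in
   axis-aligned poses while the RMS form is dominated by the tool length,
   is invariant under $w \leftrightarrow h$, and satisfies $s^2 \ge wh$
   (AM–GM) with equality at $w = h$, where it reduces to the conventional
   definition. Note $s^2 = \mathrm{area}/2$ under the diagonal-squared
   area convention; the package takes the RMS form as *the* definition and
   derives $s$ from the stored box.
2. **Tip permutation invariance.** `oksTipSwap()` evaluates the prediction
   against the ground truth and against a copy with the Tip1/Tip2 triplets
   exchanged (coordinates and visibility move together) and reports the
   better value — equivalent to a bipartite matching step over the
   two-element tip set. It can never be smaller than the plain value.

Only ground-truth visibility matters: keypoints with $v_i = 0$ contribute
nothing, and predicted visibility codes are accepted on input but ignored.
All four roles share the conservative scale-normalised standard deviation
$\sigma_i = 0.107$ (the largest value in use for human keypoints,
acknowledging the annotation ambiguity of smooth metallic parts), with
falloff $\kappa_i = 2\sigma_i$. A useful consequence for testing: under
isotropic Gaussian jitter of standard deviation $\sigma_n$ the expected
per-keypoint term has the closed form
$1/(1 + \sigma_n^2/(s^2\kappa_i^2))$.

## AP/AR summaries

`evaluatePose()` and `evaluateBbox()` implement the COCO evaluation
protocol: per image, detections are sorted by score (capped at 20) and
greedily matched to the unmatched ground truth of maximal similarity at or
above each threshold in 0.50–0.95 (step 0.05); ground truths without
labelled keypoints are ignore-instances that neither reward nor penalise;
curves are accumulated over a global score ordering, precision is
interpolated on the 101-point recall grid, AP averages it, and AR averages
the per-threshold maximal recall. On exact similarity ties the matcher
keeps the later candidate, mirroring the reference implementation's
update-on-`>=` loop rather than a first-wins rule. Empty evaluable ground
truth yields the conventional −1 sentinel. The box protocol uses plain IoU
on `w·h` areas. With tip-swap disabled the whole pipeline is checked in the
test suite against an independent reimplementation of the protocol
(different data layout, candidate-set matching, max-precision-at-recall
interpolation) to 10⁻⁶ on 100 seeded scenes.

## The synthetic scene generator

Real endoscopic data cannot ship with a package, so every component is
exercised against `genScene()`. Its defaults are fixed study conditions,
not tuning knobs: 960 × 540 frames (the downsampled endoscopic resolution)
with a centred circular content area of radius 260 px; 1–3 instruments per
frame; an entry point sampled *on* the circle; a straight shaft of
0.45–1.1 FoV radii to the hinge; tips of 40–90 px opened by 0.08–0.45 rad
for articulated tools; a 12 px shaft for the mask render. Tools are
articulated with probability 2/3 and visibility follows the six protocol
scenarios (four articulated: all visible, partially occluded, closed/one
tip missing, shaft only; two rigid: all visible, shaft only), uniformly
weighted by default since scenario frequencies of the real data are not
published. Occluded edges receive a transition point with probability 0.5.
Masks render each instrument's visible segments as capsules, painted in
instance order (later tools overdraw earlier ones, emulating overlap).

`perturbPredictions()` turns ground truth into controlled detections:
unit-variance noise is drawn *first* and scaled by `noiseSd`, so at a fixed
seed displacements grow pointwise with the noise level and AP monotonicity
across noise levels is structural rather than statistical; tips are swapped
with probability `swapProb`, detections dropped with `dropProb`, scores
drawn uniformly from [0.5, 1].

What the generator does **not** emulate: photorealistic appearance, smoke,
blood, specular reflection, curved instruments (shafts are straight — the
same limitation the keypoint-derived boxes have on real data), annotation
noise, or any correlation between visibility and image content. Passing
tests therefore validate the *data model, formats and metrics*, not the
difficulty of real endoscopic imagery.

## Numerical and degenerate-input choices

* A box with `w = h = 0` has no scale; `scaleFactor()` refuses it, and the
  evaluator pads $s^2$ with machine epsilon exactly as the reference
  evaluator pads its area.
* Similarity of a detection to an ignore instance is computed from the
  distance to the doubly-expanded ground-truth box (the reference
  `k1 == 0` branch), so such detections can be discarded, not penalised.
* Serialization writes full-precision numbers; the parse/serialize round
  trip is exact to 1e-9 and double serialization is byte-identical.
* Mask PNGs are written 8-bit when all labels fit in a byte and 16-bit
  otherwise, via a small built-in big-endian grayscale PNG encoder whose
  output is read back (and thereby independently verified) by libpng.
* Problem sizes in the test suite — 1,000 pose-validity draws, 100 scenes
  for the protocol-equivalence check, 50 scenes per noise level for the
  monotonicity sweep, 10⁵ Monte-Carlo draws for the noise law — were chosen
  once as the smallest sizes at which the corresponding property is sharp.

## Known limitations

* Transition points survive the raw dialect round trip but are dropped by
  the COCO export, which has no slot for them.
* Mask instance ids and pose instance ids are independent namespaces; the
  package offers no automatic linking because the correspondence is not
  defined upstream.
* Whether released datasets store the margin-expanded or the raw-extent
  box is not decidable from the format alone; this package stores the
  margin-expanded, clipped box and derives the metric scale from it.
  `keypointBbox(..., margin = 0)` recovers the raw extent if needed.
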