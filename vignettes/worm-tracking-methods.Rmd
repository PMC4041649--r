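---
title: "Tracking an elastic worm: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking an elastic worm: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mimizutrack)
```

## The problem

Earthworms are soft-bodied animals that stretch and contract as they move:
an adult's body can extend to roughly 1.5 times its resting length during
peristaltic locomotion. Tools built for stiff-bodied animals (or for
nematodes, whose length barely changes) therefore cannot quantify the two
behavioural variables that matter most for earthworm activity studies:
where each body part is, and how long the body is, second by second.

`mimizutrack` measures both from an overhead image sequence of a single
worm in a circular dish. Per frame it produces the pixel coordinates of the
head, body center and tail, the body length in millimetres, and (derived)
the speed of each point. The pipeline is deliberately classical — every
stage is an interpretable image-processing primitive — so failure modes are
visible and auditable.

## Pipeline

For each frame:

1. **Circular ROI.** The dish interior is a circle, given directly
   (`circle_roi()`) or as the circumcircle of three rim marks
   (`circle_from_marks()`). Pixels outside are forced to background.
2. **Red channel.** Under the reference lighting the worm/background
   contrast is highest in the red channel; segmentation uses it alone
   (`red_channel()`).
3. **Threshold.** Pixels darker than a threshold become foreground
   (`binarize()`, polarity `dark_object`; a `bright_object` flag exists for
   inverted setups). `threshold = "auto"` computes Otsu's threshold over
   in-ROI pixels only — the black region outside the dish would otherwise
   dominate the histogram.
4. **Cleanup.** 8-connected components smaller than `min_fragment_area`
   (default 50 px ≈ 2 mm² at 0.2 mm/px) are removed
   (`remove_small_fragments()`), then the largest component is kept
   (`largest_component()`): one worm per dish.
5. **Thinning.** The worm blob is reduced to a one-pixel-wide centerline by
   Hilditch thinning (`hilditch_thin()`, below), and skeleton branches
   shorter than `min_spur` (default 5 px) are pruned (`prune_spurs()`).
6. **Feature points.** On the first frame the user supplies an approximate
   tail position; the tail snaps to the nearest skeleton endpoint, the head
   is the geodesically farthest skeleton pixel from the tail, and the
   center is the midpoint of the tail→head path (`init_feature_points()`).
   On subsequent frames the points are re-associated (below).
7. **Kinematics.** Body length is the geodesic tail→head distance times
   the calibration (`body_length()`); per-point speeds are forward
   differences of the coordinates (`velocities()`).

## Hilditch thinning, and one hard-won detail

A pixel `p` with neighbours `n1..n8` (clockwise from north) is deletable
when (1) `2 ≤ B(p) ≤ 6`, where `B` counts foreground neighbours — `B ≥ 2`
protects endpoints, `B ≤ 6` protects the interior; (2) the crossing number
`A(p) = 1`, i.e. the neighbourhood changes background→foreground exactly
once around the cycle, so deletion cannot split the shape locally; and
(3, 4) the classical north/east tests `n1·n3·n7 = 0 ∨ A(n1) ≠ 1` and
`n1·n3·n5 = 0 ∨ A(n3) ≠ 1`, which arbitrate two-pixel-wide ribbons.

Scheduling these tests matters more than the tests themselves:

* **Immediate sequential deletion is wrong.** If pixels are deleted the
  moment they pass the tests during a raster scan, a deletion makes the
  next row deletable in the *same* pass, and an entire two-pixel-wide limb
  can be erased end to end — we observed a vertical body segment retracting
  by 52 px in one pass. The implementation therefore fixes the candidate
  set on the start-of-pass image (all four tests), then deletes candidates
  one at a time, re-verifying `B` and `A` on the current image. Each
  deletion is then a *simple-point* deletion, which provably preserves the
  number of 8-connected components; the suite checks idempotence, the
  subset property and component preservation on hundreds of random blobs.
* **One-way scans bend the tips.** With a single scan direction the
  north/west boundary erodes first, so the skeleton end drifts toward the
  south/east boundary inside the rounded tip of the worm (≈ 4-5 px hooks).
  The scan direction is reversed on every second pass, which symmetrizes
  the erosion and roughly halves the endpoint error against synthetic
  ground truth.

## Geodesics on the skeleton

The skeleton is an 8-connected pixel graph; axial steps weigh 1 and
diagonal steps √2. All along-body measurements — farthest point, path
midpoint, body length — are single-source shortest paths on this graph
(computed with igraph, with predecessor links recovered from the distance
field for deterministic path reconstruction). A "four-neighbour" metric in
which a diagonal step counts 2 is available as
`geodesic_map(..., metric = "manhattan")` for comparison, but the chamfer
1/√2 metric is the default: on an 8-connected skeleton a literal
4-neighbour distance is undefined across diagonal steps.

Two numerical conventions are applied everywhere: ties break toward the
smallest (row, col), making every output deterministic, and the path
midpoint resolves exact ties toward the source (tail) side.

The chamfer metric systematically *over*-estimates the length of a
digitized smooth curve (by up to 8 % for straight lines near 22.5°, about
5.5 % averaged over orientations). This is partly compensated by the
capsule geometry below; residual per-frame length errors on synthetic
worms are typically +1 to +4 %.

## Frame-to-frame association

The tail moves least during peristalsis, so it is matched first: the new
tail is the skeleton endpoint nearest (Euclidean) the previous tail. The
head is the nearest remaining endpoint to the previous head; if more than
two endpoints survive pruning, distance ties resolve toward the candidate
geodesically farthest from the tail (the far end of the body). If the
skeleton has fewer than two endpoints — a partly coiled body — the head
falls back to the geodesically farthest pixel from the tail.

The center is *re-derived* as the tail→head path midpoint each frame
(default) rather than matched to the previous center; matching
(`center_mode = "match"`) is offered as an alternative, but the midpoint
definition keeps the three points mutually consistent on every frame.

Frames where no worm is segmented emit the previous coordinates flagged
`carried_forward` — never silently interpolated — and tracking resumes on
the next segmentable frame. Association assumes per-frame endpoint
displacement smaller than half the worm's end-to-end separation; faster
motion (or coiling, which collapses the two ends into one neighbourhood)
can swap labels, and appearance-based head/tail disambiguation is out of
scope.

## The synthetic worm

Real reference video cannot ship with the package, so every stage is
benchmarked against a generative model (`worm_model()`,
`generate_sequence()`) with exported ground truth:

* **Elastic length.** `L(t) = rest_length · (1 + a·sin(2πt/T))`, the
  simplest periodic stretch consistent with observed body-length
  oscillation; `a ≤ 0.5` caps the stretch at 1.5× rest length.
* **Capsule body.** The body is a tube of radius `half_width` with round
  caps whose tip-to-tip extent is `L(t)`; the centerline core therefore
  spans `L − 2·half_width`. Ground-truth head/tail are the core (medial
  axis) endpoints — what a skeleton tracker estimates — and ground-truth
  length is the tip-to-tip `L(t)`. This convention makes the chamfer
  skeleton length an approximately unbiased estimator of `L`: the cap
  shortfall (−2·half_width) offsets the chamfer over-estimation (+5 %).
* **Motion.** The head end advances along a guide path (default: a gentle
  arc of radius 32 mm inside the dish) at constant speed while the body is
  laid backward along the path. A `coil` preset wraps the worm over itself
  on a tight loop — the documented failure regime.
* **Rendering.** 640×480 frames at 0.2 mm/px with an 85 mm dish, mirroring
  the reference recording geometry; light dish (red 210) against a dark
  worm (red 60), with deliberately weaker green/blue contrast; Poisson
  speck noise below the fragment-removal threshold. Everything is
  reproducible bitwise from one seed.

Default scenario parameters were fixed analytically, before benchmarking:
the `crawl` preset (rest 100 mm, amplitude 0.1, period 45 s, speed
0.6 mm/s) keeps every endpoint's per-frame displacement at or below
2 mm = 10 px (max tail step = speed + 2·rest·a·sin(π/period) ≈ 1.99 mm),
the regime where nearest-endpoint association is unambiguous. Worm
proportions (length 60-150 mm, half-width 1-2 mm) follow the study
species' aspect ratios.

What the generator does *not* emulate: soft shadows and illumination
gradients, motion blur, partial occlusion at the dish wall, JPEG artefacts
(frames are written losslessly as PNG by default), and genuine
self-occluding postures with resolvable topology. Passing the synthetic
benchmarks therefore demonstrates the pipeline's geometric correctness,
not robustness to difficult real-world photometry.

## Problem sizes used by the test-bench

The shipped suite and the acceptance script exercise: 200 random blob
masks for the thinning invariants; 50 random simple worms for endpoint
count (expected: exactly 2 in all cases) and length recovery (within 5 %
in ≥ 95 % of cases); one 100-frame crawl sequence for label stability and
endpoint RMS (≤ 3 px); a 50-frame constant-speed sequence (2.0 mm/s) and a
40-frame amplitude-0.5 sequence for kinematic recovery (mean head speed
within 10 %; max/min length ratio within 5 % of 3.0); and oracle
cross-checks of Otsu's threshold (exhaustive 256-way search), component
filtering (flood fill) and geodesic distances (label-correcting
relaxation).

## Known limitations

* Coiled or self-crossing postures merge the skeleton's branches; the
  tracker degrades by design there (status flags stay honest, but head
  placement is unreliable). Resolving crossed topology is future work.
* Body length inherits a small posture-dependent bias from the chamfer
  metric (see above); comparisons *across* frames (stretch ratios,
  oscillation frequency) are more trustworthy than absolute millimetres.
* The automatic threshold assumes a bimodal in-ROI histogram; a worm
  covering a large fraction of a poorly lit dish would need a manual
  threshold.
* One worm per dish is assumed throughout; multi-animal tracking is out of
  scope.
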