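---
title: "Co-registering IVUS and OCT pullbacks from per-frame annotations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-registering IVUS and OCT pullbacks from per-frame annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivoctreg)
```

## The problem

Intravascular ultrasound (IVUS) and optical coherence tomography (OCT) image
the same coronary segment with complementary strengths, but the two catheters
are pulled back independently: frames do not correspond one-to-one along the
vessel, and the OCT catheter sits at an arbitrary, slowly drifting rotational
orientation relative to IVUS. Joint analysis of the two pullbacks therefore
needs a *longitudinal* correspondence (which OCT frame shows the same
cross-section as each IVUS frame) and a *circumferential* one (by how many
degrees each OCT frame must be rotated to match the IVUS orientation).

`ivoctreg` computes both, starting not from images but from per-frame
annotations that upstream segmentation tools (or human analysts) provide:
the lumen contour as a closed polygon in catheter-centered mm coordinates,
rectangular side-branch bounding boxes, and a 180-bin binary calcium arc
label (one flag per 2° of circumference around the lumen centroid). IVUS
frames carry an end-diastolic (ED) flag, because the slow IVUS pullback
(0.5 mm/s) moves back and forth with the cardiac cycle and only ED-gated
frames advance monotonically along the vessel; OCT is pulled at 36 mm/s
while acquiring 180 frames/s, giving a 0.2 mm inter-frame spacing that is
immune to cardiac motion, with every second frame analysed (0.4 mm).

## Longitudinal matching

Four features are extracted from *every* frame of each pullback
(`raw_features()`):

1. lumen area, normalized by the maximum lumen area observed in the vessel;
2. total side-branch box area, normalized by the same maximum (so branch
   prominence is measured relative to the vessel calibre);
3. calcium fraction — the proportion of the 180 angular bins flagged;
4. normalized frame position, `i/(N-1)`.

The first three channels are smoothed along the pullback with a discrete
Gaussian kernel (`gaussian_smooth()`, truncated at ±4σ and renormalized,
reflect padding at the ends). Smoothing deliberately spreads each landmark's
signature over neighbouring frames: if a branch is annotated in one modality
but missed in the other, nearby frames still carry the evidence. The
position channel is never smoothed — it must stay strictly monotone. The
default σ of 2 frames (≈1 mm on the IVUS grid) is the scale of a typical
ostium; it is a tunable of `coreg_config()`.

The sequences are then down-sampled — IVUS to its ED frames, OCT to every
second frame — and the position channel is re-normalized over the retained
frames so both modalities span [0, 1] and the channel measures relative
progress through the shared segment. Smoothing precedes down-sampling so
inter-ED information is not discarded.

Dynamic time warping aligns the two retained sequences. The local cost is a
feature-weighted Euclidean distance (unit weights by default; the weights
are exposed because their ideal values depend on the upstream feature
quality and would normally be tuned on held-out vessels). The accumulation
uses the canonical symmetric three-direction step pattern with unit slope
weights and both endpoints constrained; backtrace ties prefer the diagonal,
then the vertical predecessor, making the path deterministic. No
Sakoe–Chiba band is applied by default — aligning ~100-frame sequences is
cheap without one — but a band half-width is available in the config.

The raw DTW path may map one IVUS frame to several OCT frames. The
functional map the rest of the pipeline consumes (`expand_alignment()`)
assigns each IVUS ED frame the *mean* of its matched OCT indices, yielding
a continuous, non-decreasing OCT frame index per IVUS frame — the same
reconciliation an analyst performs when interpolating between hand-matched
sections.

## Circumferential registration

Rotation is estimated the way analysts do it: only at matched pairs that
contain distinctive anatomy, and interpolated in between.
`select_landmark_pairs()` keeps pairs in which the IVUS frame *and* its
matched OCT frame each show a side branch or calcium; requiring the feature
in both modalities avoids anchoring a rotation on evidence only one catheter
saw. If no pair qualifies (featureless segments), the single pair with the
largest summed lumen eccentricity is used instead — an oval lumen is the
only remaining rotational cue.

Each landmark frame is summarized by a circular profile
(`circular_profile()`): 180 directions in 2° increments around the lumen
centroid carrying (i) the centroid-to-boundary distance by ray–polygon
intersection, (ii) the branch box area binned at the box-center angle, and
(iii) the calcium flags. For each candidate rotation 2k° the OCT profile is
circularly shifted and a per-channel normalized cross-correlation (NCC) is
combined as a weighted mean `s`; the rotation cost is `1 − s`
(`rotation_cost_row()`), kept non-negative for the dynamic program.

Two conventions matter here. A constant channel (no branch, no calcium)
carries no rotational information and scores 0 rather than NaN. The radius
channel extends this to *constant at sampling resolution*: a radial profile
whose total variation is below 1% of its mean is indistinguishable from the
chord-sagitta artifact of resampling a polygonal contour on a 2° grid, and
because NCC is scale-invariant that artifact would otherwise be amplified
into confident-looking spurious rotation evidence. Near-circular frames
therefore contribute through their branch and calcium channels only. The 1%
floor is far below any clinically meaningful lumen eccentricity and is
exposed as `radius_floor`.

The per-landmark costs form a T×180 matrix over which
`dp_rotation_path()` finds the minimum-cost rotation path with a quadratic
penalty `λ (Δ/360)²` on the circular step Δ between consecutive landmarks,
steps capped at `max_step_deg` (default 30°). The default `λ = 150` is
anchored so that a maximal 30° step costs ≈1 — the full range of one
channel's NCC — i.e. a large inter-landmark rotation change must be backed
by about one channel's worth of correlation improvement. Backtracking runs
from the minimum of the final row; ties prefer the smaller step, then the
smaller rotation. Note that a zero-length step is always feasible, so the
feasible set is never empty for any `max_step_deg ≥ 0`; values below the 2°
bin width simply force a constant rotation, and `λ → ∞` recovers the best
single constant rotation.

Landmark rotations are finally interpolated to all matched pairs along the
shorter circular arc (`interpolate_rotations()`), with constant extension
before the first and after the last landmark. An exact 180° gap between
consecutive landmarks is traversed clockwise — an arbitrary but
deterministic tie-break. Rotations are reported in [0, 360) as the CCW
angle by which the OCT frame must be rotated to align with IVUS.

The two stages run sequentially, not jointly: a longitudinal mismatch at a
landmark can propagate into its rotation estimate. This mirrors how the
pipeline is organized and is a known limitation.

## The phantom simulator

Because real co-registered pullback pairs with ground truth are not
distributable, `simulate_phantom()` generates them. The vessel is a tapered
tube with lumen radius

    r(s, θ) = R₀ (1 − taper · s/L) (1 + ecc(s) · cos 2θ),

where `ecc(s)` is a smooth modulation bounded by `eccentricity_amp`, with a
random phase. Side branches and calcium deposits are placed uniformly at
random along the vessel without longitudinal overlap (jointly across both
event types, which keeps landmarks identifiable), each with random angular
position and extent.

The IVUS acquisition emits ED frames every 0.5 mm — a 0.5 mm/s pullback
gated once per ~1 s cardiac cycle — with zero-mean Gaussian longitudinal
jitter (sorted, since ED gating leaves positions monotone but noisy) and
additive radial contour noise. The OCT acquisition emits frames on an exact
0.2 mm grid; the raw 180 frames/s stream is not simulated frame-by-frame
because only its resulting spacing matters downstream. The OCT catheter
orientation starts uniform in [0, 360) and drifts as a Gaussian random walk
(default 1°/frame) — no physical drift model is claimed; a random walk is
simply the least structured signal that still exercises the
shape-regularized path search. Branch and calcium annotations are dropped
independently per frame with probability `feature_dropout_prob`, emulating
missed detections.

Defaults describe a realistic moderately noisy study: a 40 mm segment,
1.75 mm proximal radius tapering 40%, four branches, three calcium
deposits, 0.05 mm contour noise, 0.05 mm residual ED jitter, 1°/frame
drift, 10% dropout. What the phantom does *not* emulate: image-level
appearance and artefacts, correlated (systematic) segmentation errors,
lumen shapes beyond the smooth `cos 2θ` family, thrombus or ruptured
plaque, and non-monotone catheter motion within the ED-gated sequence.
Passing the recovery tests therefore demonstrates the correctness of the
registration machinery under known geometry — not clinical performance on
real imaging data.

## Evaluation suite

`agreement_report()` and `observer_report()` summarize any two (or three)
correspondence estimates over the same IVUS frames the way registration
studies report them: median (IQR) OCT-frame and circular angle differences,
Lin's concordance correlation coefficient (population moments, per Lin's
original definition), Spearman correlation (mid-ranks), Bland–Altman bias
with 1.96·sd limits (sample sd, the convention of that method), the
Williams Index with a delete-one jackknife CI, and a Wilcoxon signed-rank
test comparing inter-observer differences with model-vs-observer
differences.

The Williams Index uses mean absolute difference as its disagreement
kernel (circular, in degrees, for rotations); the resampling unit for the
CI is the vessel when `groups` are supplied, matching the per-vessel
structure of multi-vessel test sets. The Wilcoxon test is exact for up to
25 nonzero pairs — computed by generating-function convolution over tied
mid-ranks, equivalent to full sign enumeration — and uses the
continuity-corrected normal approximation with tie-corrected variance
beyond that.

## Numerical choices, degenerate inputs, problem sizes

* Angles are degrees, counter-clockwise from +x; bins are half-open
  `[2b°, 2b°+2°)` sampled at bin centers; frame indices are 0-based in all
  files.
* Ray–polygon intersection takes the nearest crossing; contours that are
  not star-shaped about their centroid (possible for pathological shapes)
  fall back to nearest-vertex distances with a warning flag.
* Branch-to-bin assignment puts all of a box's area in its center's bin;
  overlapping boxes are summed, not de-duplicated.
* `branch_area_norm` is clamped at 1 (a branch box larger than the largest
  lumen would otherwise break the [0, 1] contract).
* DTW requires finite costs and ≥2 frames per sequence; IVUS needs ≥2 ED
  frames; a pullback whose largest lumen area is 0 is rejected.
* CCC and Spearman are undefined (error) for constant series; the Williams
  Index for any zero pairwise disagreement; the Wilcoxon test for fewer
  than 6 nonzero differences.
* The recovery checks in the test-suite run the full pipeline on 40 mm
  phantoms (≈81 IVUS ED frames, 201 OCT frames) over 10 noiseless and 20
  moderate-noise seeds; the brute-force oracles enumerate warping paths up
  to 7×8 and rotation paths up to 4×8 — sizes at which exhaustive
  enumeration is exact and fast, so the dynamic programs are verified
  against an independent computation rather than against themselves.

## Known limitations

Sequential (not joint) longitudinal and circumferential optimization;
rotation resolution limited to the 2° bin width with no sub-bin refinement;
landmark-free segments fall back to a single eccentricity-based anchor,
where a near-circular lumen leaves the rotation essentially unconstrained;
and all results on phantoms bound algorithmic, not clinical, error.
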