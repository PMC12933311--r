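# ivoctreg

Automated longitudinal and circumferential co-registration of paired
intravascular ultrasound (IVUS) and optical coherence tomography (OCT)
coronary pullbacks, working from per-frame annotations rather than images.

## Who this is for

Studies that image the same vessel with both IVUS and OCT need every IVUS
cross-section matched to the OCT frame showing the same anatomy, and the
OCT image rotated to the IVUS orientation, before plaque measurements from
the two modalities can be fused. Doing this by hand is slow and
observer-dependent. `ivoctreg` automates both steps for anyone who already
has per-frame annotations — lumen contours (closed polygons, mm,
catheter-centered), side-branch bounding boxes, 180-bin calcium arc labels,
and end-diastolic (ED) flags for IVUS — from upstream segmentation models
or manual analysis.

## Method in brief

**Longitudinal.** Each frame yields four features: lumen area and
side-branch area (both normalized by the vessel's maximum lumen area),
calcium fraction, and normalized position. After Gaussian smoothing along
the pullback (σ = 2 frames by default) and down-sampling (IVUS → ED
frames; OCT → every second frame, 0.4 mm), dynamic time warping under a
feature-weighted Euclidean distance

d(u, v) = sqrt( Σₖ wₖ (uₖ − vₖ)² )

finds the optimal monotone alignment; the backtraced path is expanded into
a continuous, non-decreasing OCT frame index per IVUS ED frame.

**Circumferential.** At matched pairs where both frames show a branch or
calcium (landmark pairs), three circular profiles are sampled in 2°
increments around the lumen centroid: centroid-to-boundary radius, branch
area, calcium flags. For each candidate rotation 2k° the cost is
1 − s(k), with s(k) the weighted mean of per-channel normalized
cross-correlations at circular shift k. A dynamic program picks the
rotation path across landmarks under a shape-regularization penalty
λ·(Δ/360)² on the circular step Δ (capped at 30°); rotations at the
remaining frames are interpolated along the shorter arc.

A **phantom simulator** generates paired pullbacks of a tapered, smoothly
eccentric vessel with randomly placed branches and calcium, known true
frame correspondence and known per-frame OCT rotation drift — so every
stage is testable without patient data. An **evaluation suite** provides
median/IQR frame and angle differences, Lin's CCC, Spearman correlation,
Bland–Altman limits, the Williams Index with jackknife CI, and the
Wilcoxon signed-rank test.

See `vignettes/ivoct-coregistration.Rmd` for the full model description,
parameter meanings, and design decisions.

## Worked example

```r
library(ivoctreg)

pair <- simulate_phantom(phantom_config(seed = 42))
pair$ivus
#> IVUS pullback: 81 frames, 0.5 mm nominal spacing, 0.0-40.0 mm
pair$oct
#> OCT pullback: 201 frames, 0.2 mm nominal spacing, 0.0-40.0 mm

res <- coregister(pair$ivus, pair$oct)
res
#> IVUS-OCT co-registration: 81 matched ED frames, 23 landmark pairs, DTW cost 2.019
head(res$alignment, 4)
#>   ivus_frame oct_frame_continuous rotation_deg is_path_node is_landmark
#> 1          0                    0          254         TRUE       FALSE
#> 2          1                    3          254         TRUE       FALSE
#> 3          2                    6          254         TRUE       FALSE
#> 4          3                    8          254         TRUE       FALSE

truth <- true_correspondence(pair)
ref <- data.frame(ivus_frame = truth$ivus_frame,
                  oct_frame_continuous = truth$true_oct_index,
                  rotation_deg = truth$true_rotation_deg)
agreement_report(res$alignment, ref)
#> Agreement over 81 matched frames
#>   frame difference: median 0.83 (IQR 0.43-1.32) frames = 0.17 mm
#>   CCC 0.9998, Spearman r 1.0000, Bland-Altman bias 0.255 (-1.831, 2.341)
#>   angle difference: median 1.0 (IQR 0.6-2.6) deg
```

Reading the numbers: each IVUS ED frame was matched to within a median of
0.83 OCT frames (0.17 mm at the 0.2 mm OCT spacing) of the simulated truth
under the default moderate-noise conditions (0.05 mm contour noise,
1°/frame rotational drift, 10% annotation dropout), and the recovered OCT
rotation is within a median of 1.0° of the true drifting orientation.
`rotation_deg` is the counter-clockwise angle by which each OCT frame must
be rotated to align with IVUS.

## Command line

```sh
Rscript inst/cli/ivoctreg demo --out demo_run --seed 6
Rscript inst/cli/ivoctreg simulate   --out run/ [--config cfg.yaml] [--seed 3]
Rscript inst/cli/ivoctreg coregister --ivus run/ivus.json --oct run/oct.json \
                                     --out run/alignment.csv
Rscript inst/cli/ivoctreg evaluate   --alignment run/alignment.csv \
                                     --reference run/ground_truth.csv \
                                     --out run/report.json
```

Pullbacks travel as JSON annotation documents, alignments and ground truth
as flat CSV; exit status is 0 on success and 2 on any validation error.

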