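---
title: "Counting white blood cell events in nailfold capillary video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting white blood cell events in nailfold capillary video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(capcount)
```

## The measurement problem

In nailfold capillaroscopy, a magnifying optical device images the hairpin
capillary loops at the base of the fingernail. A white blood cell whose
diameter matches the vessel lumen transiently displaces the red blood
column, so it appears as a bright *visual gap* traveling along the vessel.
The number of such gap events per unit time is a non-invasive proxy for
white-cell activity. `capcount` turns a raw capillary video into
per-capillary event counts with no manual steps.

Two properties of these recordings drive the design. First, the vessel is
the only reliably localizable structure, and it is red-dominant: its green
and blue reflectances are strongly suppressed relative to the surrounding
skin while its red reflectance is comparable. Second, hand-held or
finger-mounted acquisition at high magnification turns small device motion
into large image translation, so frames must be registered before any
temporal analysis. We assume pure translation — the optics rule out
meaningful rotation or scale change over 30 s — and integer-pixel
registration, since whole-frame shifts are applied.

## Pipeline and parameters

**Equalization.** Each frame's R, G, B channels are independently
histogram-equalized over the full frame (256 bins, CDF mapping to 0–255).
The mapping is global rather than local (CLAHE-style): the scenes are small
and a local scheme would re-weight the vessel interior against its
surroundings non-monotonically. Equalization is exactly idempotent here
because re-equalizing maps every output level back to itself.

**Color-score segmentation.** The score
`s = max(0, lambda * R - (G + B))^2`, `lambda = 1.5`, is large only where
red dominates jointly over green and blue. Raw squared scores live on an
arbitrary scale (up to ~150 000), so the map is linearly rescaled per frame
so its maximum is 255; the binarization threshold (80) is then scale-free.
This normalize-then-threshold reading is a deliberate choice: a fixed
threshold on the raw squared scale would be meaningless across videos with
different exposure. A flag (`normalize = FALSE`) exposes the raw scores.

**U-Net segmentation.** The alternative segmenter is a compact U-Net
(depth 2, 8 base channels, ~36 k parameters) written in base R with im2col
matrix-product convolutions, trained with Adam (learning rate 0.001, batch
size 3) on pixelwise binary cross-entropy — the reference optimizer
settings for this architecture family. Frames are resized bilinearly to
128 × 128 for the network and the sigmoid output map is resized back;
alternatively (`input_size = NULL`) inference runs at native resolution
with reflect padding to a multiple of `2^depth`. Training images are
equalized first, so the training distribution matches what the pipeline
feeds the network at run time. The soft mask (probability × 255) is
thresholded at 150.

**Stabilization.** Translation between a reference and a frame is the peak
of their circular cross-correlation, computed with FFTs on the capillary
*labels* — graded mask intensity gives a sharper, noise-robust peak than
the raw frames, whose background texture dominates the correlation.
`get_translation_vec()` returns the *displacement* of the moving image
relative to the reference; stabilization applies the negated, accumulated
vector. Because long-range displacements grow over time, the reference is
replaced every `period_p = 50` frames by the raw mask of the current frame,
and a single accumulator — the running correction of the current reference
into first-frame coordinates — keeps the translation history. Each frame's
total correction is `accumulator - displacement(reference, frame)`. With
this bookkeeping the composition is exact: on rigid-shift videos the
per-frame vectors are bit-identical for `p = 5` and `p = T`, which is the
property that pins the accumulator semantics. A frame whose registration
fails (degenerate mask, or a peak beyond half the frame) inherits the
previous frame's vector and is flagged in the trace.

For the *manual* arm a single user-drawn mask provides the geometry, but a
static mask carries no motion information, so translation vectors are still
estimated from the color-score labels. This is the one place the manual arm
depends on the conventional segmenter.

**Ensemble mask and instances.** The stabilized soft masks are averaged
over time and binarized at the arm's threshold. Averaging suppresses
per-frame segmentation noise (including the moving gap itself, which
removes a small part of the label in any single frame). Capillary instances
are 8-connected components of the ensemble with at least `min_area = 200`
px, ranked by area and truncated to `max_capillaries = 2` — automating the
"pick the clearest loops" step an operator would otherwise do.

**Coordinate determination.** The component's closed boundary is traced
clockwise (Moore neighbor tracing) and split at the two inner corners of
the branch tips, located from the column profile of the inter-branch gap
(which must open at the bottom; a solid blob raises a geometry error
rather than producing nonsense coordinates). The arc facing the gap is the
*internal* contour, ordered from the leftmost branch's free end over the
arch; the rest is the *external* contour. The external boundary is
resampled at `n` positions equally spaced in cumulative arc length, aligned
to the internal start and oriented by minimum total pair distance.
*Intermediate* coordinates are the interior pixels of the 8-connected
digital segment of each pair. Coordinates are 1-based (row, col), row 1 at
the top. Geometry is computed once, on the ensemble mask, and reused for
all frames — this is exactly what stabilization buys.

**ST map.** Element `k` of a frame's capillary vector is the mean of one
color channel over coordinate triple `k`. The green channel is the default
scalar intensity: the vessel's equalized green level is near zero while a
plasma gap restores background-like green, giving the largest gap contrast;
red or gray are available by configuration. Columns are frames, rows are
path positions. Enhancement: 3 × 3 median filter (reflect-padded; removes
isolated specks), row zero-meaning (removes static structure along the
path — a row's baseline is constant in time), clipping at zero, Sobel
gradient magnitude (orientation-agnostic, suiting slanted lines; axis-only
derivatives are available), and a single final rescale to 0–255 so that
peak-picking thresholds are scale-free.

**Event detection.** The Radon transform maps the processed ST map to a
polar map over angles 0–179° (1° grid) and integer offsets covering the map
diagonal. Local maxima at least 0.35 of the global maximum are picked with
an 11 × 15 suppression window (±5°, ±7 px). The offset half-window is sized
to the parallel structure a *single* event generates: the Sobel edge pair
of a band whose thickness is the gap length (≈ vessel diameter, ≈ 8 px,
contributing up to `8·sin θ` ≈ 4–5 px), and the offset between the event's
two branch segments caused by the shorter arch traverse of a hairpin path
(≈ 5–6 px of same-angle parallel offset). Both must fall inside one window
or an event is counted twice — parallel duplicates can never be removed by
the crossing rule. Within-window ties (exactly equal peaks, as a symmetric
clean fixture produces) keep the lexicographically smallest (θ, z).

The *base events* are the best-populated angle group, found with a sliding
window of width 5° centered on each maximum in turn (alignment-free — rigid
bins can split the true group across a bin edge and hand the base set to an
artifact cluster); count ties go to the higher total strength. Candidates
are then admitted strongest-first if their reconstructed line crosses no
accepted line strictly inside the map (shared border points do not count;
coincident parallels within half a pixel are treated as duplicates). The
non-crossing rule is enforced within the base set too, so the final event
set is pairwise non-crossing by construction. An event's timestamp is the
time at which its line crosses the map's central row; for lines parallel to
the time axis it is undefined (`NA`). Near-horizontal "instantaneous"
events are not filtered out — they are left to the crossing rule.

## The synthetic validation surface

No capillaroscopy videos with event-level ground truth are publicly
deposited, so the package carries a generator whose defaults define the
validation conditions: a 192 × 256 scene at 30 fps with 160 frames
("desk"), one hairpin vessel (branch spacing 28 px, branch length 50 px,
tube radius 3.5 px) with gentle sinusoidal tortuosity (amplitude 3 px,
wavelength 35 px), visual gaps 8 px long moving at 3 px/frame
(≈ 180 µm/s at ~2 µm/px — mid-physiologic capillary flow), an integer
camera-jitter random walk with 3 px steps and reflecting bounds, a smooth
±4 % multiplicative illumination field, and Gaussian noise of 5 intensity
levels. A "paper" preset mirrors the nominal acquisition geometry
(640 × 480, 30 fps, two capillaries) at 10 s duration. Batch experiments
(20-video recovery, 10-video stabilization benefit) use the desk preset;
that sizing is the package's own choice for a single-CPU workflow.

Two generator choices deserve emphasis because they encode physics rather
than convenience. The vessel's red channel (235) is comparable to the
background's (200) while green/blue are strongly suppressed — a vessel that
is darkest in *all three* channels would collapse to rank ≈ 0 in every
globally equalized channel and the color score would degenerate; real
capillaries are dark because of green/blue absorption, not red. And the
tortuosity is what anchors registration along the branch axis: a perfectly
straight synthetic branch makes the correlation surface a flat ridge in
that direction, a degeneracy real (always tortuous) vessels do not have.

What passing tests do show: the numeric kernels agree with independent
brute-force oracles; the stabilization bookkeeping composes exactly; on
scenes with well-separated events at a common flow speed, counts are
recovered exactly in ≥ 90 % of seeded runs and stabilization strictly
reduces the count error under heavy jitter. What they do not show:
robustness to capillary shapes far from a single hairpin (crossed or
overlapping loops), strongly varying per-event speeds (the base-angle rule
assumes events share a dominant slope), pulsatile flow, focus drift, or
photometric effects beyond smooth illumination and Gaussian noise. Counts
on real recordings still require expert spot checks.

## Numerical choices

- **Radon discretization.** Each pixel projects onto the offset axis as the
  trapezoid `box(|cos θ|) ⊛ box(|sin θ|)`; the transform deposits each
  pixel's value into the at most three bins its footprint overlaps using
  the exact closed-form CDF. Mass is conserved exactly per angle, axis
  angles reduce to exact row/column sums, and oblique projections agree
  with a dense brute-force line integral to ≈ 0.4 % relative L2 on random
  images.
- **Median filter.** 3 × 3 via Paeth's 19-exchange sorting network (fully
  vectorized); larger odd kernels fall back to direct medians. Borders are
  reflected, as in the Sobel stage.
- **Row zero-meaning and order of operations.** The median filter runs
  before zero-meaning (median first, then background removal). Consequently only a *global*
  constant commutes exactly through the chain; a row-varying baseline
  leaks marginally through the median's row mixing, without affecting
  detected events.
- **Registration.** Integer-pixel only (`upsample_factor` reserved): shifts
  are applied to whole frames, so subpixel precision would be discarded.
  Correlation peaks are unwrapped to the signed half-range; shifts beyond
  half the frame are treated as failures. Vacated borders are zero-filled
  (edge replication available).
- **Degenerate inputs.** All-zero images refuse registration (no peak);
  all-zero ST maps yield zero events; empty ensembles yield an empty
  capillary list and a report, not a crash; non-hairpin topologies skip the
  capillary with a geometry error in the result.

## Limitations

Counting is per-capillary and relative; absolute concentration (cells/µL)
would need flow-volume calibration that video alone cannot provide. The
U-Net here is sized for the synthetic surface — for clinical imagery it
would need a larger backbone and a curated training set. Rotation and
non-rigid motion are out of scope by design. Video containers are not
decoded in-process; frames must be extracted to numbered PNG/TIFF files
first.
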