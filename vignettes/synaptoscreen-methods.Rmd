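---
title: "Methods: synapse detection, colocalization and plate statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synapse detection, colocalization and plate statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synaptoscreen)
```

## The measurement problem

Live neuronal cultures expressing a presynaptic marker (VAMP2 fused to a
red fluorophore) and a postsynaptic marker (PSD95 fused to a yellow
fluorophore) allow a mature, bipartite synapse to be read out as a pair
of spatially apposed fluorescent puncta. High-content screening images
the same sites of a multi-well plate before and after a treatment and
quantifies synaptotoxicity as the loss of colocalized puncta relative to
each well's own baseline. This package implements that computation: site
registration across acquisitions, punctum detection on each channel,
colocalization counting, and the plate-level statistics, together with a
synthetic-image generator that supplies ground truth for validation.

## Detection chain

Each field passes through a fixed sequence. All stages operate on plain
numeric matrices; coordinates are 0-based `(row, col)` and areas are in
pixels.

1. **Canonical intensity scale.** The raw image is divided by its
   maximum. Every later stage then sees identical numbers for any
   positively rescaled copy of the input, which makes the final binary
   mask exactly invariant under intensity scaling — a useful property
   when exposure settings differ between acquisitions.
2. **Flatten background** — subtraction of a morphological opening by a
   disc of radius 15 px (the protocol's "flatten, pixel size 5" times a
   3 px punctum scale). Structures wider than the disc in every
   direction — soma blobs, slow illumination gradients — are treated as
   background. The opening is computed with edge-replicated padding;
   without it the opening sees a zero exterior and the subtraction
   leaves a bright frame along the borders that the threshold picks up
   as spurious particles.
3. **No-neighbors deconvolution** — haze removal by subtracting 0.97
   times a Gaussian blur (sigma = filter size / 2 = 5 px) of the plane,
   with an optional sigma-1 pre-smoothing ("suppress noise"). The two
   convolutions are fused into one composite kernel for speed; the
   operator is identical. Clamped at zero.
4. **White top-hat** — image minus its opening by the largest disc with
   at most 50 px (a 37 px disc of diameter 7). Bright structures larger
   than the disc are levelled; puncta pass at full contrast.
5. **Contrast normalization** — percentile stretch saturating 0.3% of
   pixels (split between the tails) and mapping the remaining range to
   `[0, 1]`, the "enhance contrast + normalize" step. Applied per image;
   whether the original analysis normalized per image or per plate is
   not documented, and per image is the only choice that keeps fields
   independent.
6. **Auto-threshold** — maximum-entropy (Kapur) by default, Otsu as the
   alternative. Both build a 256-bin histogram over the image range
   (8-bit auto-threshold semantics after normalization), scan every
   split exhaustively, and break ties toward the lowest bin. Both are
   verified in the test suite against independent brute-force scans.
7. **Noise floor.** Histogram thresholds assume the image contains two
   populations. On a field with few or no puncta (a blank well, or a
   well after near-complete synapse loss) the foreground class is
   essentially empty and both criteria collapse into the noise,
   producing hundreds of spurious 2–4 px particles. The chain therefore
   never thresholds below `noise_floor_mads` (default 6) times a robust
   noise scale of the filtered image, estimated as the median of its
   positive values divided by 0.6745 (the half-normal quantile — after
   background subtraction and clamping, background noise survives as
   half-normal deviates). On signal-bearing fields the floor sits close
   to the data-driven threshold; on sparse fields it prevents the
   collapse. Set `noise_floor_mads = 0` to recover the bare protocol
   behavior. The floor actually applied is recorded in each detection's
   provenance.
8. **Particle counting** — connected components (8-connectivity by
   default; the choice is exposed because the original macro does not
   state it) with areas between 2 and 50 px inclusive, the
   particle-analyzer convention for "between 2 and 50". Edge-touching
   components are kept. Labeling is implemented over the pixel adjacency
   graph and tested against an independent flood fill.

"Voxel" in the source protocol is read as "pixel": the acquisitions are
single-plane widefield images.

## Registration and ROI logic

Serial acquisitions of one site are aligned by normalized
cross-correlation template matching: the central 50% crop of the moving
image is searched within the first-timepoint reference over integer
shifts up to `max_shift_px` (default 50 in the configuration surface; 20
in the bundled simulations, matching the generator's stage jitter of at
most 6 px). Ties are broken toward the smallest shift magnitude, then
row-major order; a flat template is a degenerate-input error rather than
a silent `(0, 0)`. Registration is integer-pixel only — downstream
counting is binary-mask based, and the acquisitions revisit
approximately the same stage position — and no rotation or scale search
is attempted. The common region of interest is the maximal axis-aligned
rectangle visible in every aligned frame; if it covers less than
`min_roi_fraction` (default 50%) of the field the site fails alignment
and is excluded with a QC record. The same shifts and ROI are applied to
both channels.

## Colocalization

A synapse is a one-to-one match between a presynaptic and a postsynaptic
component. The default criterion is pixel overlap of at least 1 px on
the binarized components, mirroring merged-channel counting; a
centroid-distance criterion is available for sensitivity analysis.
Matching is greedy by descending overlap (ascending distance), ties by
smaller ids, and is symmetric in its count. The separate
`coloc_fraction_against_reference()` statistic divides the number of
stained puncta touching any reference punctum by the number of reference
puncta with many-to-one matching allowed; it deliberately exceeds 100%
when several stained puncta map to one reference punctum, which is the
only reading under which published validation values above 100% are
coherent. An upstream plugin's own preprocessing (rolling-ball radius
0.1, maximum filter 0.2) is deliberately subsumed by this package's
detection chain: colocalization here consumes already-detected puncta
rather than reprocessing raw images.

## Plate statistics

The experimental unit is the well: the five (configurable) sites of a
well are averaged first, which avoids treating correlated sites as
independent replicates. Synapse survival is `100 x follow-up mean /
baseline mean` per well and readout; because both numbers come from the
same physical scene, punctum-placement variance cancels and the
statistic is far more precise than two independent counts would be. An
NTC-normalized version (percent of the mean control percentage) is also
emitted, since the source analyses are not fully explicit about the
normalization; the baseline-normalized number is the headline.

Treated conditions are compared against the no-treatment control with
two-sided Dunnett many-to-one adjustment after one-way ANOVA. The
equicoordinate probability `P(max|T_j| <= q)` is evaluated by
deterministic quadrature: conditional on the control-mean deviate and
the pooled-SD deviate the comparison statistics are independent, so the
probability factorizes under a 2-D integral, computed with 64-node
Gauss–Hermite (control deviate) times 48-node Gauss–Legendre on the
probability transform of the chi distribution (SD deviate). This
reproduces the Student-t tail at one comparison to about `1e-5` and
agrees with `multcomp`'s single-step values to better than `1e-3` (the
tolerance contract); a Monte-Carlo evaluation would meet the same
contract but was rejected in favour of bit-reproducibility without seed
management. The two-factor variant uses the cell-means error term
(degrees of freedom `N` minus the number of observed cells) and compares
every treated cell against the pooled control cell, reducing exactly to
the one-way case when one factor is constant. Tukey all-pairs
comparisons use the studentized range (`ptukey`), Tukey–Kramer for
unequal sizes. Stars follow the screening-figure tiers: `****` at
p ≤ 0.0001, `**` at 0.01, `*` at 0.05, with alpha 0.05 and 95%
intervals throughout. Adjusted p-values are never below their
unadjusted counterparts, and control rows carry p = 1 by convention.

## The synthetic-data generator

No imaging data are deposited with the source study, so validation runs
on a generator whose defaults encode the published mature-culture
conditions: presynaptic density 0.03 puncta/µm², postsynaptic 0.014,
and a colocalized fraction of 11/14 of postsynaptic puncta (colocalized
density about 0.011/µm²). Each scene draws Poisson counts at density
times area, places presynaptic puncta with a hard-core minimum
separation, marks each postsynaptic punctum colocalized independently
with the configured probability, and places colocalized puncta uniformly
in a 2 px disk around their partner (sub-resolution apposition) and free
puncta at least `min_sep_px` (default 6 px, at least twice the maximum
punctum radius) from any opposite-channel punctum. Fields contain the
nuisance structure the detection chain exists to remove: neurite-like
smoothed random-walk ridges carrying dim, diffuse shaft label (about 1.3
noise SD, several px wide), large Gaussian soma blobs, a linear
illumination gradient, and Poisson shot noise (gain 2 ADU/e⁻) plus
Gaussian read noise (10 ADU), quantized to 16 bits last. Punctum radii
are drawn from 1.6–2.4 px with ±20% brightness scatter around an
amplitude of `snr` (default 6) times the background noise SD.

Geometry is a deliberate desk-scale choice: the default field is
224 × 224 px at 0.35 µm/px (about 6.1 × 10³ µm², an expected ~184
presynaptic puncta), roughly an eighth of a full-frame acquisition;
whole-plate simulations in the tests and the acceptance script use a
160 px tile so that hundreds of complete plates can be simulated. These
sizes, the background amplitudes and the noise levels are calibration
choices — the source reports puncta densities but neither SNR nor
background statistics — and are fixed once here. What passing tests
show is therefore that the pipeline recovers ground truth under this
noise model, not that it reproduces any instrument's point-spread
function, photobleaching kinetics, focus drift, or debris; those are
explicitly not modelled.

Treatment is Bernoulli removal per punctum between timepoints, with a
colocalized presynaptic punctum removed jointly with its postsynaptic
partner (decouplable); the follow-up scene is then rigidly translated by
an integer stage jitter and re-imaged with fresh noise. Illumination
does not move with the stage. The bundled glutamate preset encodes the
published tiers: 85% colocalized loss at ≥ 25 µM, 60% at 2.5 µM, 20%
at 250 and 25 nM, and ≤ 5% at 2.5 nM, with presynaptic loss at 0.8
times the postsynaptic fraction (postsynaptic puncta are reported to be
hit harder).

## Known limitations and degenerate inputs

* The vendor "Flatten Background" and "No Neighbors" kernels are
  proprietary; this package implements their stated contracts (opening
  subtraction; scaled-blur haze removal), and equivalence with vendor
  output cannot be asserted.
* The colocalization-fraction estimate from detections is biased low by
  roughly the product of the channel recalls (a pair is counted only if
  both partners are detected); at the default SNR this bias is a few
  percent and sits well inside the per-field binomial error band used
  in the tests.
* Constant images are degenerate inputs for thresholding and alignment
  and raise errors rather than returning arbitrary values; empty masks
  yield empty puncta sets; a baseline mean of zero makes
  percent-of-baseline undefined and is reported as missing with a QC
  entry rather than silently dropped.
* Sub-pixel registration, rotation, nonrigid warping, intensity-based
  punctum quantification and dose-response curve fitting are out of
  scope.

## Problem sizes used in the bundled checks

Threshold and labeling oracles run on 50 random 64 × 64 images / 40 × 40
masks; registration recovery on 100 default-size field pairs with shifts
up to ±20 px; detection fidelity on 8 default fields; colocalization
recovery on 50 fields per target fraction; loss-detection power on 100
simulated six-well plates (five 160 px sites per well, two timepoints,
both channels); null calibration of the three multiple-comparison
procedures on 2000 replicates each. These sizes were chosen to give
stable estimates at desk scale and are stated here so they can be scaled
up when more compute is available.
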