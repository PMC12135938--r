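---
title: "Quantifying presynaptic puncta distributions in neuropil subdomains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying presynaptic puncta distributions in neuropil subdomains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synaptlas)
```

## The problem

In the Drosophila larval ventral nerve cord, the presynaptic terminals of
early-born interneurons of a lineage concentrate in a few compact neuropil
territories (here labelled i1–i3), while later-born siblings of the same
lineage innervate a broader, distinct "late-born" territory. Comparing
genotypes — in particular a genotype in which the early temporal
transcription factor Hunchback is expressed for longer than normal (HbOE),
reprogramming late-born neurons toward early-born identities — requires a
quantitative answer to: *what fraction of a hemisegment's presynaptic
puncta lies in each territory?*

`synaptlas` implements the two complementary procedures used to answer
that question, together with the spot detection, behavioural metrics and
group statistics that surround them, and a synthetic-data generator that
makes every stage testable against known ground truth.

## Coordinate conventions

All coordinates are right-handed micrometres: axis 1 is medial–lateral
(x), axis 2 dorsal–ventral (y), axis 3 anterior–posterior (z), with the
origin at the anterior-dorsal-medial corner of the hemisegment box. The
hemisegment midline is the medial face; right-hemisegment data are always
mirrored across it before pooling, so all analyses happen in a left frame.
Voxel `(i, j, k)` of a volume has its centre at
`origin + (c(i, j, k) - 0.5) * voxel_size`. The default voxel size is
0.1 × 0.1 × 0.22 µm; the axial value is the acquisition's z-resolution,
the lateral value a conventional confocal sampling choice.

## The centroid-frame ("manual") procedure

1. Each hemisegment's **centroid** is the midpoint of its measured
   length, height and depth (`hemisegment_centroid()`); segmental depth
   borders are accepted as given metadata.
2. For each labelled reference hemisegment, the **region centre** is the
   mean medial-lateral/dorsal-ventral position of its labelled puncta,
   expressed as an offset from the centroid
   (`region_center_per_hemisegment()`). The anterior–posterior axis is
   ignored because presynapses of these neurons run the full depth of the
   segment.
3. A **region definition** is the box centred on the mean of those
   per-hemisegment offsets with half-width twice their sample standard
   deviation (n−1 denominator) per axis, spanning the full depth
   (`build_region_definition()`). When the references are degenerate
   (SD = 0) the half-width is clamped to a floor of 0.1 µm (one lateral
   voxel) so the region stays usable.
4. Puncta are counted per region with a **closed-box** membership test; a
   punctum on a shared face goes to the first-listed region, and any box
   overlap triggers a warning (`assign_and_percent()`). Percentages are
   normalised by each hemisegment's own total count, which cancels
   between-animal variation in labelling efficiency. A hemisegment with
   zero puncta yields `NA` percentages — missing, never zero.
5. `capture_rate()` validates a region against held-out labelled
   hemisegments; a hemisegment counts as captured when a strict majority
   (> 50 %) of its labelled puncta fall inside the box. The majority rule
   is our choice — the source procedure does not define "captured".

## The template ("computational") procedure

1. **Template construction** (`build_template()`): segmented neuropil
   masks are averaged iteratively — register every mask to the current
   template, average the aligned binaries, re-binarise at 0.5 — starting
   from the first mask, until the mean Dice improves by less than 1e-3.
2. **Registration** (`register_to_template()`) is a nine-parameter affine
   (translation, rotation, per-axis scale; no shear) scored by Dice
   overlap. The optimiser works on a smooth surrogate: a volume-weighted
   soft Dice in which each moving foreground voxel contributes the
   trilinearly interpolated value of a lightly blurred template, weighted
   by `|det A|` so that shrinking into the template interior is penalised
   exactly as over-coverage is. Initialisation matches foreground
   centroids and per-axis second moments; a tiny quadratic penalty
   (1e-5) on the deformation breaks ties along the symmetry flats of
   near-symmetric masks. A registration whose final binary Dice is below
   0.5 raises an alignment-failure error, mirroring the source pipeline's
   practice of discarding images that failed to align. We restrict the
   transform to affine maps; the original toolchain may have used warped
   alignment, which we deliberately do not reproduce.
3. **Density maps** (`density_map()`): puncta are binned into the
   template grid and blurred with an isotropic 1 µm Gaussian, then scaled
   to a true density (µm⁻³) so the map integrates to
   `scale_factor × n_spots`. The sparse Hb-filtered channel is scaled by
   10 per hemisegment and the wild-type channel by 1, equalising
   intensities between channels whose puncta counts differ roughly
   ten-fold.
4. **Inclusion thresholding** (`threshold_inclusive()`): the combined
   early-born (Hb⁺) region is the suprathreshold voxel set at the
   *largest* threshold that still includes 95 % of the puncta. The
   largest-threshold convention minimises the region volume and makes the
   region unique; candidate thresholds are exactly the puncta's own voxel
   densities, so the search is finite and exact, and ties across
   equal-density voxels are included.
5. **Late-born region** (`define_late_region()`): the difference map
   `D = wt − hb` is thresholded at the positive value whose
   suprathreshold volume best matches the Hb⁺ region volume, found by
   exact search over the sorted positive values of `D` (no continuous
   bisection, no tolerance). Because the threshold is positive, the late
   region can only occupy territory where the wild-type density strictly
   dominates, making it disjoint from the Hb⁺ region by construction. If
   the positive support of `D` cannot reach half the target volume the
   two densities are too similar and an explicit volume-unreachable error
   is raised.
6. **Partition and quantification**: the Hb⁺ region is cut into i1–i3 by
   two medial–lateral planes (`partition_subregions()`); the boundary
   positions are required configuration with no claim of fidelity, since
   the source procedure placed them manually. `quantify_template()` then
   counts each hemisegment's puncta per region mask with the same
   normalisation contract as the centroid procedure, and errors when more
   than half of a hemisegment's puncta fall outside the template grid
   (almost always an unregistered input).

## Spot detection

`detect_spots()` is an anisotropic Laplacian-of-Gaussian blob detector
parameterised exactly by the diameters used in the source analysis
(0.41/1.46 µm laterally/axially for wild-type and HbOE channels,
0.31/1.71 µm for the Hb-filtered channel). Per-axis sigma is
`diameter / (2√3)`, the scale at which the LoG response of a ball of that
diameter peaks. Local maxima of the scale-normalised response are refined
to sub-voxel positions by 3-point parabolic interpolation per axis,
ranked by response with lexicographic voxel-index tie-breaks, and pruned
so no two detections are closer than half a diameter in the anisotropic
metric. Detections within half a diameter of the volume border are kept
but flagged, preserving the totals used for percentage normalisation.

The minimum-intensity gate (default 10 AU, from the stated 7–12 AU range)
is evaluated on the Gaussian-smoothed volume at the detection voxel — the
matched-filter estimate of spot intensity in the input volume's own
units — rather than on a single raw voxel. At realistic noise levels a
raw-voxel threshold cannot simultaneously keep true puncta and reject
noise maxima: read noise with a standard deviation of a fifth of the peak
straddles any workable raw threshold, while the smoothed estimate
separates the two populations by an order of magnitude. Whether the
original tool subtracted background before thresholding is not stated; we
do not.

## The synthetic-data generator

`genotype_model()` describes a hemisegment's puncta as a four-component
mixture: three compact anisotropic Gaussian clusters (SD 0.5 µm
laterally, 5 µm anterior-posteriorly — compact in cross-section,
elongated along the segment) plus a broad diffuse late-born component
(Gaussian, SD 5 × 5 × 6 µm at the centroid, truncated to the neuropil).
The neuropil itself is an axis-aligned superellipsoid (exponent 2.5)
inscribed in the hemisegment box. Cluster centres sit at distinct
medial–lateral positions (offsets (−6, −3), (6, 5), (0, 4) µm from the
centroid for i1, i2, i3), i2 being the furthest territory from the
centroid; across hemisegments each centre jitters with SD 0.6 µm,
truncated so it stays inside the neuropil. That jitter is what gives the
reference-derived ±2 SD boxes their width. The absolute µm positions of
the real territories are not published; these defaults are chosen for
plausibility — compact clusters well separated within a ~20 µm
hemisegment — and make no claim of anatomical fidelity.

Genotypes differ only in mixture weights and expected totals: wild-type
≈ 340 puncta per hemisegment, HbOE ≈ 356, and the Hb-filtered reference
labelling ≈ 34 (a tenth of wild type, which is why the template procedure
scales that channel by 10). `render_volume()` is the forward model for
the detector: each punctum deposits an anisotropic Gaussian of integrated
intensity equal to its intensity (PSF SD 0.12/0.12/0.42 µm) plus constant
background and additive Gaussian read noise. All randomness flows from a
single top-level seed through named substreams (`substream_seed()`), so a
cohort can be extended without perturbing earlier hemisegments.

### Calibration of mixture weights

A ±2 SD box captures slightly less than all of its cluster's puncta and
picks up a few diffuse late-born puncta, so generating weights and
expected *measured* percentages differ by a linear map. The reported
wild-type structure (i1 4.05 %, i2 3.90 %, i3 7.74 % of the hemisegment
total) and the HbOE structure (8.45/10.16/5.13 %) are therefore treated
as targets for the *measured* scale: `calibrate_region_weights()`
estimates the capture/contamination matrix by Monte Carlo (a 20-
hemisegment Hb-filtered reference defines the boxes; a 400-hemisegment
cohort with known ground truth estimates the matrix) and solves the
linear system for the weights whose expected measurement hits the
targets. The same calibration is *not* applied to the template-procedure
outputs: one generative weight vector cannot satisfy both the
centroid-frame and the template-space linear systems at once, so the
template percentages the package reports are whatever the operators
produce on the manually-calibrated cohorts — systematically wider than
the box-based ones, because 1 µm blurring dilates the thresholded
regions.

### What the generator does and does not emulate

It reproduces the statistical structure the analysis relies on: mixture
weights, per-hemisegment totals, cluster compactness and jitter,
left/right mirroring, rendered noise volumes and FIMTrack-style spine
tracks. It does not emulate staining chemistry, optics beyond a Gaussian
PSF, neuron morphology, segmentation errors of the neuropil outline, or
spatial correlations between puncta of one neuron. Passing tests
therefore demonstrate the correctness and calibration of the *operators*,
not the anatomical fidelity of the defaults.

## Behaviour and morphometrics

Tracks carry head/midpoint/tail coordinates at 25 frames/s for 2 minutes
(recordings are made at higher rate and saved at 25 fps). Speed is the
midpoint's frame-to-frame displacement times fps; gaps up to 3 frames are
linearly interpolated, longer gaps are an error. The speed AUC is the
Riemann sum `sum(series) / fps` — each sample covers one frame interval,
so a constant speed `v` held for `T` seconds integrates to exactly
`v × T`; with per-frame samples the difference from the trapezoid is one
part in `fps × T`. The body-bend metric is the absolute deviation of the
head–midpoint–tail interior angle from 180°, with coincident-point frames
flagged invalid and excluded; the per-larva summary is the mean over
valid frames (the source reports a single per-larva value without naming
the reduction — the mean is our choice). The track generator's defaults
are calibrated so the expected group summaries equal the reported control
group (speed 1.325 units/s giving AUC ≈ 159 over 2 minutes; 35° bends at
a 50 % duty cycle giving ≈ 17.5°); `simulate_track_hboe()` carries the
slower, more bent HbOE group (0.891 units/s, 56.6°).

Soma-to-neuropil distance — a proxy for birth order, since early-born
somata sit deep near the neuropil and late-born ones superficially — is
the Euclidean distance from the soma centre to the nearest neuropil
foreground voxel centre (0 inside the mask), computed directly against
the foreground voxel set. It is exact up to voxel quantisation, 0 on the
mask and 1-Lipschitz in the soma coordinate. The measured quantity is
described in places as "neurite length"; we implement the distance
interpretation. Division-window inference is the arithmetic of the
lineage: each neuroblast division in a window makes one ganglion mother
cell that divides into two siblings, so `n` neurons imply `ceiling(n/2)`
divisions (5 neurons → 3 divisions; 2 → 1).

## Group statistics

Two-group comparisons use Welch's unequal-variance t test with two-tailed
p-values (`welch_t()`, wrapping `stats::t.test`); the accompanying
description of the test as simultaneously normal and non-parametric is
resolved as the standard parametric Welch test, which is what the named
analysis software computes under that option. The degenerate case of two
constant samples is resolved explicitly (t = 0, p = 1 when means agree).
Multi-group comparisons use fixed-effects one-way ANOVA with Tukey HSD
adjusted pairwise p-values (`anova_oneway()`); no post-hoc is named in
the source, and Tukey is the conventional default. Stars follow
**** < 0.0001, *** < 0.001, ** < 0.01, * < 0.05. `ingest_supplementary()`
reads wide one-column-per-group sheets (CSV or XLSX) defensively:
non-numeric headers are required, unrecognised layouts raise a
schema-mismatch error rather than coercing, and dropped cells are
counted. Hemisegments are treated as independent units throughout; no
per-animal mixed-effects modelling is attempted.

## Numerical choices and degenerate inputs

* Gaussian filtering is separable with kernels truncated at 4σ and
  normalised to unit sum; borders are zero-padded.
* Local maxima require a voxel to be ≥ all 26 neighbours and > at least
  one, so constant plateaus yield no detections; grid-edge voxels never
  qualify.
* The registration scale parameters are clamped to `exp(±2)` so a
  wandering optimiser cannot reach a singular map.
* Sampling inside the neuropil uses vectorised rejection with a cap of
  1000 rounds; exceeding the cap (a component essentially outside the
  geometry) is an error, not a silent truncation.
* Thresholds in both region-defining operators are searched over finite
  sorted value sets, so results are exactly reproducible and
  tie-handling is explicit.

## Problem sizes used by the test-suite and acceptance script

The packaged checks run the full operator chain at the study's sample
sizes (30 hemisegments per genotype for the centroid procedure, 22 for
the template procedure, 17-hemisegment Hb-filtered references, 61/62
larvae, 200-punctum detection volumes, 10,000 simulated null tests) but
on coarser template grids (0.5–0.8 µm voxels) and with 200 small
replicate cohorts for the sign-recovery sweep; these grid and replicate
sizes are the package's own verification choices and keep the entire
suite self-contained and quick.

## Known limitations

* Registration is affine-only and mask-driven; image-intensity or
  deformable alignment of real stains is out of scope.
* The i1/i2/i3 medial–lateral boundary positions and all absolute
  cluster coordinates are configuration, not published anatomy.
* Whether the boxed manual regions were truly axis-aligned boxes or free
  surfaces is ambiguous in the source; boxes are implemented.
* The late-born component is a single smooth distribution; real late-born
  territory is structured, so late-percentage magnitudes from the
  template procedure should be read as operator output, not biology.
* AUC units follow the track's coordinate units, which the source leaves
  unstated.
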