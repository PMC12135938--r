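# synaptlas

Quantification of presynaptic puncta distributions within neuropil
subdomains of the Drosophila larval ventral nerve cord.

In a neuroblast lineage, neurons born under the early temporal
transcription factor Hunchback (Hb) target their presynapses to a few
compact neuropil territories (i1–i3), while later-born siblings innervate
a broader "late-born" territory. Prolonging Hb expression (HbOE)
reprograms late-born neurons toward early-born identities, and the
quantitative signature of that reprogramming is a shift of presynaptic
mass into the early territories. `synaptlas` implements the two
procedures that measure this shift, plus everything needed to test them
end-to-end:

* **Centroid-frame ("manual") quantification** — per-hemisegment
  subregion boxes built from reference puncta as
  *mean offset from the hemisegment centroid ± 2 SD* per axis, spanning
  the hemisegment depth; per-region counts normalised by each
  hemisegment's total:
  `pct_r = 100 · n_r / n_total`.
* **Template ("computational") quantification** — iterative neuropil
  template construction with Dice-scored affine mask registration,
  left/right mirroring, 1 µm Gaussian kernel-density maps of puncta
  (Hb-filtered channel scaled ×10 to equalise intensity), thresholding at
  the largest value that includes 95 % of the puncta, and a late-born
  territory defined by volume-matched subtraction: the set
  `{wt_density − hb_density ≥ t*}` with `t*` chosen so its volume equals
  the Hb⁺ region volume.
* **Spot detection** — anisotropic Laplacian-of-Gaussian detector with
  per-axis sigma `diameter/(2√3)` (diameters 0.41/1.46 µm, or 0.31/1.71 µm
  for the Hb-filtered channel), sub-voxel refinement, and half-diameter
  anisotropic exclusion.
* **Behaviour & morphometrics** — crawl-speed series and speed AUC,
  body-bend deviation from 180°, soma-to-neuropil distance, and
  division-window inference (`ceiling(n/2)` divisions for `n` neurons).
* **Statistics** — Welch's two-tailed t test, one-way ANOVA with Tukey
  post hoc, group summaries (mean ± SD), and a defensive reader for
  supplementary-style wide tables (CSV/XLSX).
* **Synthetic cohorts** — a seeded generator (mixture of three compact
  clusters plus a diffuse late component inside a superellipsoid
  neuropil) with weight calibration so that the *measured* wild-type and
  HbOE percentages match the study conditions; rendered noisy volumes and
  FIMTrack-style larva tracks included.

## Worked example

Simulate a calibrated two-genotype cohort at the study's sample size and
quantify it with the centroid-frame procedure:

```r
library(synaptlas)

g   <- make_geometry(20, 20, 20)   # one abdominal hemisegment, um
cal_wt <- calibrate_region_weights(c(i1 = 4.05, i2 = 3.90, i3 = 7.74),
                                   g, wt_model(), seed = 99)
cal_oe <- calibrate_region_weights(c(i1 = 8.45, i2 = 10.16, i3 = 5.13),
                                   g, hboe_model(), seed = 99)

cohort <- simulate_cohort(list(WT = cal_wt$model, HbOE = cal_oe$model),
                          n_hemisegments = 30, geometry = g, seed = 1)
counts <- assign_and_percent(pool_left_frame(cohort), cal_wt$regions)
aggregate(counts[, c("i1_pct", "i2_pct", "i3_pct", "total_n")],
          by = list(genotype = counts$genotype), FUN = mean)
#>   genotype i1_pct i2_pct i3_pct total_n
#> 1     HbOE  8.707 10.461  4.968   353.6
#> 2       WT  4.277  3.455  7.984   335.7

welch_t(counts$i2_pct[counts$genotype == "WT"],
        counts$i2_pct[counts$genotype == "HbOE"])
#> Welch two-sample t test (two-tailed)
#>   t/F = -11.7, df = 39.03, p = 2.457e-14 (****)
```

Each row of `counts` is one hemisegment; the `*_pct` columns are the
percentage of that hemisegment's puncta falling in each early-born box
(~340 puncta per wild-type hemisegment). The HbOE cohort shows the
expected shift: more mass in i1/i2, less in i3 and outside. The Welch
test compares the i2 percentage across genotypes exactly as the per-panel
contrasts are computed.

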