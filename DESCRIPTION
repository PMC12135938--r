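Package: synaptlas
Title: Quantification of Presynaptic Puncta Distributions in Neuropil Subdomains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for quantifying the spatial distribution of
    presynaptic puncta within neuropil subdomains of the Drosophila larval
    ventral nerve cord. Implements two complementary quantification
    procedures: a centroid-frame ("manual registration") procedure that builds
    subregion boxes from reference puncta positions (mean offset from the
    hemisegment centroid plus/minus two standard deviations), and a
    template-registration ("computational") procedure that aligns segmented
    neuropil masks to a shared template, builds Gaussian kernel-density maps
    of puncta, thresholds them to include a set fraction of puncta, and
    defines a late-born territory by volume-matched density subtraction.
    Includes anisotropic 3D Laplacian-of-Gaussian spot detection, a synthetic
    cohort generator with known ground truth, larval locomotion metrics
    (speed area-under-curve and body-bend angle), morphometric helpers, and
    the group statistics used to compare genotypes (Welch's t test, one-way
    ANOVA with Tukey post hoc).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    tiff
Suggests:
    readxl,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
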