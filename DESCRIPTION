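Package: warnsig
Title: Quantification of Warning-Signal Phenotypes and Mimicry Convergence
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies aposematic colour-pattern phenotypes of mimetic poison
    frogs from standardized, landmarked dorsal photographs: per-region colour
    (hue and saturation, brightness discarded), landmark-aligned head-pattern
    rasters, and transect transition counts ("adjacent method" reticulation
    scores). Per-characteristic distance matrices are min-max normalized and
    fused into a global phenotypic distance, from which the package derives
    within-population variability (Var), centroid-based mimetic distance (Im)
    and mimicry similarity (ms), the Var-ms correlation, a multidimensional
    scaling morphospace with density peaks and outlier fractions, and
    characteristic-level variability statistics (Kruskal-Wallis with pairwise
    Wilcoxon and Bonferroni correction). A synthetic-frog generator renders
    images with known ground truth so the whole pipeline is testable without
    field photographs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils,
    yaml,
    jsonlite,
    png,
    digest,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
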