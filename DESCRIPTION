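Package: spheroprofile
Title: Radial Intensity Profiling and Metabolic Imaging Analysis of Tumor Spheroids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies the internal organization of multicellular tumor
    spheroids from fluorescence microscopy images. Provides automated
    quality control of spheroid fields of view, radial line-intensity
    profiling with min-max normalization, partitioning of profiles into
    necrotic-core, quiescent and proliferative-edge microregions with
    two-way ANOVA and Tukey comparisons, per-pixel biexponential fitting
    of NADH fluorescence-lifetime (TCSPC) decays, and optical redox ratio
    mapping. A synthetic phantom generator with known ground truth makes
    the whole pipeline testable without real imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    tiff,
    minpack.lm,
    emmeans,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
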