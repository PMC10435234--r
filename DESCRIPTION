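Package: cavemorph
Title: Brain-Wide Volumetric and Shape Modularity Analysis for Segmented Atlases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Atlas-based neuroanatomical morphometry for comparative studies of
    brain evolution, developed around the surface and cave morphs of the Mexican
    tetra (Astyanax mexicanus) and their F1/F2 hybrids. Reads integer label
    volumes (NIfTI) and region ontologies, measures relative region volumes
    (percent of total brain), compares populations with one-way ANOVA and
    Holm-Sidak corrected contrasts, validates segmentations by vectorized
    Pearson cross-correlation, detects volume-covariation modules by
    hierarchical clustering of correlation distances, and implements 3-D
    geometric morphometrics from scratch: generalized Procrustes analysis with
    sliding semilandmarks, thin-plate-spline warping with template surface
    patching, shape PCA, two-block partial least squares with permutation
    tests, and Procrustes regression with residual randomization. A synthetic
    cohort generator with known ground truth (module-structured volume
    covariance, dorsal/ventral tradeoff, additive-dominant inheritance,
    compositional closure) supports end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    MASS,
    stats,
    tools,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
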