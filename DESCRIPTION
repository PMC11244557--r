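Package: dimorph
Title: Sex-by-Genotype Interaction Mapping for Brain Connectivity and
    Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis machinery for 2x2 sex-by-genotype factorial studies of
    mouse brain phenotypes. Implements resting-state fMRI connectivity mapping
    (global and local weighted degree centrality, seed-based Fisher-z maps)
    with time-series conditioning (volume trimming, nuisance regression,
    mask-renormalized Gaussian smoothing, ideal band-pass filtering), voxelwise
    factorial linear models with permutation-based cluster-extent familywise
    error correction, and a bulk RNA-seq differential-expression pipeline
    (count filtering, TMM normalization, log-CPM, voom-style precision
    weights, residual-SVD surrogate variables, weighted interaction models,
    M+F-/M-F+ classification) feeding hypergeometric odds-ratio gene-set and
    chromosome enrichment. Includes synthetic-data generators with planted
    effects so every stage is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    edgeR,
    limma,
    fgsea,
    car,
    yaml,
    jsonlite,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
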