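Package: pjresbin
Title: Correlation-Based Binning of pJRES 1H NMR Spectra
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Dimensionality reduction for 1D projections of J-resolved (pJRES)
    1H NMR spectra of biofluids. Implements a correlation-guided binning
    algorithm that detects metabolite peaks as local maxima of a sliding-window
    average-correlation spectrum and expands them into clusters, together with
    two comparators (statistical recoupling of variables and equidistant
    binning), a data-driven procedure that selects the correlation threshold by
    contrasting a noise-dominated against a metabolite-dominated spectral
    region, an evaluation battery (cross-correlation of binned features with
    external metabolite concentrations, paired signed-rank comparison of
    methods, PCA variance diagnostics), and a synthetic pJRES spectra generator
    with ground-truth peak supports for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    SummarizedExperiment,
    data.table,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Metabolomics, Preprocessing, Clustering, DimensionReduction
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'cli.R'
    'correlation.R'
    'evaluate.R'
    'io.R'
    'jba.R'
    'pjresbin-package.R'
    'srv.R'
    'standardBin.R'
    'synthetic.R'
    'threshold.R'
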