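Package: leafprint
Title: Metabolite Fingerprinting of Plant Leaf Tissue by Flow-Infusion
    Mass Spectrometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for flow-infusion electrospray
    ionisation mass spectrometry (FIE-MS) metabolite fingerprints of plant
    leaf material. Provides spectral binning of centroided mzML spectra into
    fixed-width m/z features with occupancy, pooled-QC and total-ion-current
    based filtering and normalisation; accurate-mass molecular formula
    annotation under configurable electrospray adduct rules with consensus
    chemical-taxonomy classification; random-forest classification and
    regression with margin statistics, permutation-based significance,
    proximity ordination and importance-based feature selection; k-means
    clustering of diurnal abundance trends; and structural
    over-representation plus diffusion (personalized PageRank) pathway
    enrichment. A synthetic-data module generates fingerprint datasets with
    fully known ground truth for validation and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    randomForest,
    igraph,
    jsonlite
Suggests:
    mzR,
    mclust,
    yaml,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
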