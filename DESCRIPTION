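Package: comigratr
Title: Phosphorylation-Linked Protein Complex Profiling from Affinity
    Purification, Native Fractionation and Targeted Mass Spectrometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for dissecting how phosphorylation organizes a
    bait protein's interactome into distinct complexes. Quantifies
    affinity-purification mass spectrometry (AP-MS) experiments from top-n
    peptide intensities with bait normalization, left-censored imputation,
    Welch t-tests and Benjamini-Hochberg correction; clusters treatment
    time-course responses by fuzzy c-means; deconvolves blue-native PAGE
    (BN-PAGE) migration profiles over 64 gel fractions into co-migrating
    modules by Gaussian peak detection, peak splitting and
    correlation-distance hierarchical clustering with silhouette-guided model
    selection; attaches bait phosphosite signatures and interpolated native
    molecular weights to each module; evaluates modules against a
    protein-protein interaction reference and by hypergeometric compartment
    enrichment; classifies phosphosite-interactor associations against
    phospho-null mutant fold changes; and scores and quantifies parallel
    reaction monitoring (PRM) peak groups with retention-time and spectral
    dot-product gates. A synthetic-data module generates ground-truth-labeled
    inputs for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    e1071,
    fgsea,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
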