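Package: ptgspace
Title: Predictive Toxicogenomics Space Modelling and Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a predictive toxicogenomics space (PTGS) from
    chemical-perturbation transcriptomics. Differential expression profiles
    are summarised as signed gene-set activation counts by preranked gene
    set enrichment analysis, decomposed into latent components with a
    collapsed-Gibbs latent Dirichlet allocation sampler, and fused with
    GI50-anchored potency data to select the component subset most
    predictive of dose-dependent cytotoxicity. The selected space supports
    component- and gene-based scoring of new expression experiments,
    ordinal liver-pathology endpoint analysis, and drug-induced liver
    injury (DILI) safety-margin classification against therapeutic Cmax
    exposure. Includes synthetic-data generators with planted ground truth
    for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    limma,
    glmnet,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
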