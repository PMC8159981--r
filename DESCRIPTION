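Package: picogas
Title: Neural Gas Analysis of Marine Picoplankton and Bacterial Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis workflow for depth-stratified marine microbial surveys:
    taxonomic and prevalence filtering of 16S amplicon sequence variant (ASV)
    tables, genus-level agglomeration, per-feature standardization, Neural-gas
    vector quantization with selection of the number of best-matching units by
    the coefficient of variation of the SSIntra quantization error, cluster
    characterization (per-unit summaries, taxon composition profiles, anomaly
    direction concordance), alpha-diversity statistics (Shannon, Pielou,
    hypergeometric rarefaction), stoichiometric nutrient-limitation
    classification, and a synthetic-data generator that emulates a multi-station
    depth-stratified sampling design with planted community structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    vegan
LinkingTo: Rcpp
Suggests:
    biomformat,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
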