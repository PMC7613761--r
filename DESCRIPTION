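Package: napscan
Title: Quantitative Proteomic Survey and Prediction of Archaeal
    Nucleoid-Associated Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying archaeal chromatin through quantitative
    proteomics. Reads label-free protein quantification tables, hmmer domain
    hit tables, operon maps, DNA-binding predictor scores, species metadata
    and species trees; converts intensities to fractional proteome abundances
    and computes aggregate investment in nucleoid-associated proteins (NAPs);
    surveys known NAP families across genomes; predicts candidate NAPs with a
    four-filter pipeline built around the generalized extreme studentized
    deviate (Rosner) outlier test; scores nucleoid-versus-top-fraction
    enrichment with an empirical-Bayes moderated t-test; and relates NAP
    investment to optimal growth temperature with Spearman screens, ordinary
    least squares prediction intervals and phylogenetic generalized least
    squares under Brownian motion. A synthetic-study generator with known
    ground truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    limma,
    nlme,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
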