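Package: nesim
Title: Simulation-Based Benchmarking of Effective Population Size Estimators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An individual-based, age-structured forward simulator for large,
    migration-connected populations with full pedigree recording, coalescent
    recapitation of founder lineages and neutral mutation overlay, together
    with estimators of effective population size (Ne): theoretical and
    realized demographic Ne from vital rates and recorded pedigrees
    (hybrid Felsenstein-Hill approach), contemporary Ne from linkage
    disequilibrium (Burrows composite r-squared with sampling-bias
    correction, jackknife confidence intervals and a physical-linkage
    correction), and long-term Ne from the site-frequency spectrum
    (Watterson's theta). Includes a factorial benchmark orchestrator over
    migration rates, sample sizes and locus counts, and readers/writers for
    genepop, VCF, PLINK PED/MAP and dadi-format SFS files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
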