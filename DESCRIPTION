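Package: momicsmr
Title: Multi-Omics Summary-Data Mendelian Randomization and Colocalization
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Integrates molecular quantitative trait loci (methylation,
    expression, protein) with disease genome-wide association summary
    statistics to nominate causal genes. Implements top-cis-SNP summary-data
    Mendelian randomization with the HEIDI heterogeneity (pleiotropy) test,
    Wakefield approximate-Bayes-factor colocalization over five hypotheses,
    multi-omics evidence tier classification, tissue-level validation
    bookkeeping, phenome-wide Wald-ratio screening, and hypergeometric
    gene-set over-representation. Ships a summary-level simulator of
    LD-correlated cis-regions under controlled causal scenarios so the whole
    pipeline is testable without cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
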