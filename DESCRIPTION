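Package: ksenrich
Title: Expression-Based Drug Repositioning with Signed Kolmogorov-Smirnov Enrichment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores a ranked case/control disease gene list (an "instance")
    against a database of unordered compound-gene interaction signatures using
    a signed Kolmogorov-Smirnov enrichment statistic, assigns significance by
    a length-stratified bootstrap null, and reports Benjamini-Hochberg
    FDR-corrected candidate compounds for repositioning. Includes readers and
    writers for ranked lists and GMT gene-set files, a converter for raw
    Comparative Toxicogenomics Database (CTD) chemical-gene interaction dumps,
    evaluation statistics (hypergeometric enrichment of known therapies,
    percentile ranks), a synthetic-fixture generator with planted enrichment,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
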