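Package: rxconverge
Title: Pharmacovigilance Signal Detection and Drug-Target Genetic Convergence
Version: 0.1.0
Authors@R:
    person("rxconverge", "maintainers", email = "maintainers@rxconverge.org",
           role = c("aut", "cre"))
Description: Tools for identifying medications disproportionately linked to a
    side-effect syndrome in spontaneous-reporting data (proportional reporting
    ratio and Yates chi-square signal detection), testing their target genes
    for class-level overrepresentation and directional mechanism of action by
    permutation, testing target-gene sets for enrichment in gene-level genetic
    risk, and intersecting the evidence streams to nominate convergent target
    genes. Includes a seeded synthetic-data generator with planted ground
    truth so the full pipeline can be exercised and validated end to end, a
    simplified medical-lexicon string normalizer, and exact set-overlap
    statistics (hypergeometric and Fisher tests with fold enrichment).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
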