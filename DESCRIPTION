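Package: diphic
Title: Allele-Specific Hi-C Analysis of Diploid Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for allele-specific Hi-C analysis in F1 hybrid systems:
    haplotype segregation of SNP-annotated contact pairs, binned diploid
    contact-map construction with iterative correction, empirical-Bayes
    Poisson-Gamma EM assignment of allele-uncertain contacts, bipartite-index
    detection and significance testing of inactive-X superdomains, Poisson
    metric-scaling 3D structure inference, radial periphery enrichment of
    genes and chromatin features, and virtual-4C allelic contact-ratio
    analysis. Includes a seeded synthetic diploid Hi-C simulator so the full
    pipeline is testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    jsonlite
Config/testthat/edition: 3
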