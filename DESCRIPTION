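Package: mdmtriage
Title: Triage and Verification of Unclassifiable 16S rRNA Amplicon Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for detecting and characterising "microbial
    dark matter" sequences (MDMS) in 16S rRNA amplicon surveys: identification
    of OTUs that cannot be assigned to any known lineage, abundance-based
    candidate selection, inference of a taxonomic novelty rank from best-hit
    percent identity, reference-based bimera screening, primer quality control
    with in-silico PCR verification, cross-validation against metagenome
    contigs and bins, and phylogenetic placement against a masked reference
    alignment. Includes a seeded synthetic-community generator so the whole
    pipeline runs end-to-end without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    ape,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
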