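Package: salipan
Title: Comparative Pan-Genomics of Lactobacillus salivarius Strain Groups
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for contrasting two groups of bacterial
    strains (e.g. Lactobacillus salivarius isolates collected before and
    after the antibiotic-growth-promoter ban) by pan-genome analysis:
    pseudogene filtering, identity-threshold single-linkage ortholog
    clustering with majority-vote consensus sequences, presence/absence and
    copy-number pan-genome matrices, fragment-based average nucleotide
    identity, screening of ortholog consensi against labelled reference gene
    panels (antibiotic resistance, exopolysaccharide, extracellular-protein
    families) under a joint identity/E-value rule, subsystem enrichment by
    Fisher's exact test, presence/absence hierarchical clustering and MLST
    neighbor-joining trees with bootstrap support, and qPCR absolute
    quantification by genome-copy conversion. A synthetic strain-genome
    generator with a full ground-truth table makes every stage testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    ape,
    data.table,
    stats,
    utils
Suggests:
    mclust,
    jsonlite,
    withr,
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
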