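Package: xkmir
Title: Cross-Kingdom microRNA Target Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An offline, testable pipeline for predicting cross-kingdom
    regulation of host (human) mRNAs by dietary plant microRNAs. Stages:
    quality filtering of mature miRNAs by deep-sequencing read count and
    length; discovery of candidate target sites as exact antisense matches
    of miRNA nucleotides 2-13 in transcript sequences; evaluation of
    miRNA:mRNA hybridization by a constrained intermolecular
    nearest-neighbor minimum-free-energy dynamic program (perfect
    Watson-Crick seed pairing, no G:U wobbles in the seed, configurable
    energy threshold); transcript-region annotation and collapsing of
    isoforms to unique protein-coding genes; hypergeometric
    over-representation analysis with Benjamini-Hochberg false discovery
    rate control; seed-mimicry detection against host miRNAs and
    cross-species mature-sequence conservation; plus a fully seeded
    synthetic-data generator that plants binding sites with known ground
    truth so every stage is testable without database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    BiocGenerics,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
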