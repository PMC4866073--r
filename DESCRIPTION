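Package: barcodegap
Title: DNA Barcode Evaluation Within Plant Genera
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates candidate plastid DNA barcodes (matK, rpoC1, rpoB,
    trnH-psbA) within genera of closely related species. From per-locus
    alignments and a specimen table it computes sequence-variation summaries,
    codes indels and structural events as single mutation steps, collapses
    sequences into haplotypes for every locus combination and scores
    species-level assignment success, diagnoses the barcoding gap from
    Kimura 2-parameter distance distributions, builds bootstrapped
    neighbour-joining trees with species-monophyly reports, draws
    median-joining haplotype networks, and estimates rarefaction sequence
    richness and sampling-size correlations. A synthetic-data generator
    reproduces the evolutionary scenarios (incomplete lineage sorting,
    chloroplast capture, sequencing dropout) that shape such datasets, so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    graphics,
    igraph,
    jsonlite,
    phangorn,
    stats,
    tools,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    vegan,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
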