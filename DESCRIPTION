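Package: vamp
Title: Virus-Encoded Auxiliary Metabolic Gene Discovery and Curation from
    Metagenome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A post-annotation inference chain for discovering and curating
    virus-encoded methane-metabolism auxiliary metabolic genes (AMGs) in
    assembled metagenomes. Combines ensemble virus calling from per-contig
    predictor scores, contaminant screening, clustering of viral contigs
    into vOTUs by average nucleotide identity and aligned fraction,
    coverage-per-gigabase abundance ecology (Bray-Curtis, PCoA, PERMANOVA),
    genomic-context curation of AMG candidates with pathway-module
    exclusivity classification, virus-host linkage from CRISPR spacer,
    tRNA, sequence-similarity and composition evidence with lineage-level
    virus/host abundance ratios, and gene-level pN/pS selection screening.
    Ships a synthetic-community generator that plants ground truth through
    every stage so the whole chain is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    vegan,
    seqinr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
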