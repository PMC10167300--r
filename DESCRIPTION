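Package: hlacomposite
Title: HLA Genotype Concordance, Copy-Number Filtering and Composite
    Genotyping for Pseudobulk RNA-seq
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for benchmarking and improving HLA genotype predictions
    obtained from pseudobulk single-cell or bulk RNA-seq. Implements
    field-resolved success/accuracy/agreement metrics between predicted and
    molecular genotypes, positional Shannon-entropy profiling of HLA
    multiple sequence alignments, a k-nearest-neighbour HLA-DRB3/4/5
    copy-number classifier on paralog/DRB1 read ratios with Hand & Till
    multiclass AUC and top-n genotype filtering, a decision-tree composite
    genotyper that picks the best upstream caller per locus and field, and
    a random-effects (DerSimonian-Laird) meta-analytic summary of per-cell
    allele-specific expression. A synthetic-data generator emulates all
    required inputs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    FNN,
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Transcriptomics, SingleCell, Classification, Genetics
RoxygenNote: 7.3.3
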