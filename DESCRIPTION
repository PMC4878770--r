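Package: pedrecomb
Title: Crossover and Non-Crossover Detection in Three-Generation Pedigree
    Sequencing Data
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects meiotic crossover and non-crossover gene-conversion
    events from whole-genome genotype data of a three-generation pedigree
    (four grandparents, two F1 parents, five F2 offspring), as used in avian
    pedigree-sequencing studies. Provides site-level quality filtering,
    grandparent-of-origin phasing, haploblock construction and error pruning,
    crossover interval calling with resolution metrics, a stringent
    non-crossover filter cascade with weak/strong conversion classification,
    and downstream statistics: sex-specific genetic maps, crossover
    interference (coefficient of coincidence), hot-spot permutation tests,
    genomic feature association, and the GC-biased gene conversion
    transmission-distortion test. A synthetic-pedigree simulator with known
    crossover/non-crossover ground truth (gamma-renewal interference model,
    Z/PAR inheritance, tunable genotype-error channels) makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings,
    VariantAnnotation,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    optparse,
    knitr,
    rmarkdown
biocViews: Genetics, SNP, VariantDetection, Sequencing
Config/testthat/edition: 3
RoxygenNote: 7.3.3
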