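Package: phageTakeover
Title: Transcriptome Takeover, Growth Kinetics, RNA Features and
    Metabolomics of a Lytic Phage Infection
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for characterising a lytic bacteriophage
    infection of its bacterial host from classical and omics readouts:
    one-step growth-curve and adsorption kinetics (logistic and
    exponential fits yielding eclipse, latency, cycle duration, burst
    size and the adsorption rate constant); dual-genome RNA-seq with
    per-genome median-of-ratios normalisation, negative-binomial Wald
    differential expression and temporal classification of phage genes;
    calling of intergenic small RNAs, cis-antisense RNAs and riboswitch
    candidates from stranded coverage, plus exact k-mer target scanning;
    and time-course metabolomics with Welch tests and rank-subset Fisher
    pathway enrichment. Seeded simulators generate every input the
    pipeline consumes together with ground-truth records for recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    BiocGenerics,
    stats,
    utils,
    MASS,
    minpack.lm,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
biocViews: Transcriptomics, DifferentialExpression, Metabolomics,
    Normalization, Sequencing, Coverage
RoxygenNote: 7.3.3
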