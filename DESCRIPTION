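Package: scSomaAging
Title: Somatic Mutation Signatures and Transcriptome Aging in Single Brain Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated pipeline for studying how somatic single-nucleotide
    variants (sSNVs) and gene expression change with age in single cells of the
    human prefrontal cortex. Provides trinucleotide-context mutation spectra,
    de novo signature extraction by Kullback-Leibler non-negative matrix
    factorization with rank selection and exposure refitting, mutation-burden
    age regression, matched-spectrum random controls for genic/intergenic and
    expression-quantile enrichment, transcriptional strand bias, gene-length
    resolved sSNV rates, single-nucleus differential expression with
    percent-expressed filters, housekeeping/neuron-specific gene
    classification, a cross-cell-type shared-downregulation permutation test,
    and a seeded synthetic-data generator that emulates the statistical
    structure of aging cortex scWGS/snRNA-seq corpora so that every stage is
    testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    SummarizedExperiment,
    SingleCellExperiment,
    rtracklayer,
    VariantAnnotation,
    Matrix,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
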