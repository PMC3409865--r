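Package: sRNAcascade
Title: Hierarchical Classification and Differential Expression of Small
    RNA Sequencing Libraries
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for two-library small RNA sequencing comparisons in
    species without an assembled genome: 3' adapter trimming with a
    position-anchored scanner, unique-read collapsing and thresholded
    size-distribution tables, an ordered reference-library classification
    cascade with read removal (chloroplast, known and homologous miRNAs,
    ncRNA families, repeats, antisense gene and transgene profiling),
    total-count normalization with log2 fold-change accounting of
    group-specific and shared reads, novel miRNA discovery by precursor
    window extraction and hairpin folding under a minimum-free-energy
    filter, and degradome (PARE) cleavage-site calling.  Includes a
    ground-truth synthetic data generator emulating a transgenic versus
    control barley experiment, and the published summary tables of that
    experiment for arithmetic verification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    Rcpp,
    stringi,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'cascade.R'
    'degradome.R'
    'diffexp.R'
    'io.R'
    'matcher.R'
    'novel.R'
    'pipeline.R'
    'preprocess.R'
    'published.R'
    'synthetic.R'
    'utils.R'
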