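Package: plasmaBias
Title: Coverage Bias Correction and Aneuploidy Detection for Plasma
    Cell-Free DNA Sequencing
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for investigating and correcting coverage bias in
    low-pass sequencing of plasma cell-free DNA. Implements
    mappability-weighted read-count correction, the binned LOESS GC
    correction, the single-position GC bias model with total-variation
    (TV) score selection of the GC window, breakpoint 3-mer
    fragmentation profiling and motif-stratified correction, and a
    chromosome-proportion Z-score test for fetal trisomy together with
    an evaluation harness over reduced sequencing depths. A synthetic
    plasma-DNA simulator with known GC bias, cleavage-motif weights,
    nucleosomal fragment-length mixture, fetal fraction and ploidy
    provides ground truth for parameter-recovery and detection tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    Rsamtools,
    rtracklayer,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Sequencing, Coverage, CopyNumberVariation, Preprocessing,
    QualityControl
RoxygenNote: 7.3.3
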