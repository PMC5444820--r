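Package: ligprobe
Title: Simulation and Analysis of Ligation-Probe Targeted Expression Profiling
Version: 0.2.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A generative read simulator and complete processing chain for
    targeted whole-transcriptome assays that count ligated detector-oligo
    pairs. Detector-oligo pools are modelled as pairs of 25-nt arms whose
    ligation product is a 50-nt sequenceable template; the simulator emulates
    log-uniform transcript abundances, per-probe signal attenuation,
    mis-ligation chimeras, assay background, partial reads and sequencing
    error, and emits FASTQ with per-read ground truth. The pipeline covers
    dual-index demultiplexing, mismatch-tolerant probe alignment, read
    accounting, normalization, attenuation back-calculation, QC metrics,
    negative-binomial differential expression with Benjamini-Hochberg
    adjustment, limit-of-detection and minor-population sensitivity
    analytics, and rank-based extraction of cell-type-independent compound
    signatures from ranked expression profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
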