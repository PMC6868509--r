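Package: rloopas
Title: Strand-Aware Analysis of R-Loop-Driven Antisense Transcription
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for testing whether R-loops act as
    promoters of antisense transcription. Provides a ground-truth synthetic
    data generator for stranded 5'-tag tracks (chromatin RNA, R-loop IP,
    capped 5' ends), a strand-aware local-Poisson peak caller with
    fold/q-value retention, genomic-category classification of peaks
    (TSS/TES/genebody/antisense/intergenic), stranded RPKM/RPM
    quantification, RNase-H1 sensitivity scoring by fold change, peak to
    transcript association, metagene TSS/TES profiling, capped 5'-end
    cluster analysis, and bisulfite single-stranded DNA footprint mapping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
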