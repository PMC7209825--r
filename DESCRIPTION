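Package: ribostat
Title: Bacterial Ribo-Seq Processing, Periodicity Validation, and
    Differential Translation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Processing toolkit for bacterial ribosome profiling
    (Ribo-Seq) experiments: adapter and sliding-window quality trimming
    of single-end FASTQ reads, decompilation of text SAM alignments into
    sorted BED6 intervals via CIGAR arithmetic, extraction of CDS
    features keyed by locus_tag from NCBI-style GFF3 annotation,
    metagene ribosome-density profiles around start codons with
    selectable 5'/3' read-end assignment and a three-nucleotide
    periodicity statistic, A-site mapping by a fixed 3'-end offset,
    depth-normalized genome-wide footprint profiles, strand-specific
    per-CDS read counting, median-of-ratios count normalization,
    reproducibility diagnostics (sample distances, PCA, clustering),
    and pairwise differential-translation contrast tables.  A seeded
    simulator generates ribosome-protected-fragment reads, alignments
    and count matrices with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
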