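Package: g2iscan
Title: Detection and Genomic Context Analysis of Bacterial Group II Introns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects, assembles and classifies bacterial and archaeal group II
    introns (G2Is) from genome sequences together with tabular homology and
    covariance-model search evidence. Joins reverse-transcriptase (RT) domain
    hits with RNA domain V/VI hits under a distance rule to call IEP-containing
    and ORF-less introns, extracts and classifies intron-encoded proteins
    (canonical, interrupted, short ORF), clusters peptides at an identity
    threshold, locates intron 5' ends with per-type log-odds profiles, measures
    distances to rho-independent transcription terminators, scores
    replication-strand insertion bias relative to ori/ter, and computes GC skew
    and the GC skew index (GCSI). Includes a synthetic-genome generator that
    plants introns, decoys and terminators with machine-readable truth tables so
    the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
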