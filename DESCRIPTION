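Package: svkmer
Title: Mapping-Free Structural Variant Genotyping from k-mer Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genotypes structural variants (deletions, insertions, inversions)
    directly from raw sequencing reads without mapping. For each variant the
    package selects k-mers whose genomic copy number is altered by the event
    (breakpoint-junction k-mers and k-mers internal to the affected sequence),
    filters them against the reference genome and against training samples with
    known genotypes, counts them in FASTQ or BAM read streams with a
    neighbor-verified rolling scan, and calls genotypes {0/0, 0/1, 1/1} by
    maximum likelihood under a normal model of k-mer counts parameterized by
    sample-wide depth statistics. A seeded diploid-genome read simulator is
    included for end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    Rsamtools,
    GenomicRanges,
    IRanges,
    vcfR,
    yaml,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
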