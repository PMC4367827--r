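Package: bactrokit
Title: Raw-Read Repeat Discovery, Satellite Statistics and Sibling-Species
    Divergence for Tephritid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable implementations of the raw-read analyses used to
    characterise the Queensland fruit fly (Bactrocera tryoni) draft genome and
    its sibling species: exact k-mer counting with greedy k-mer-extension
    repeat discovery, align-and-extend consensus construction, satellite DNA
    tandem-arrangement statistics and variant-tolerant abundance estimation,
    two genome-size estimators (k-mer histogram and single-copy transcript
    coverage), fixed-difference calling partitioned by genomic region with
    joint-codon synonymous/non-synonymous and compensated-stop classification,
    ribosomal RNA per-site variant profiling, zero-coverage deletion detection
    with flank filters, a repeat-association permutation test, and a transposon
    insert-span comparison. Includes a synthetic-data generator emulating the
    study conditions (small annotated genomes with alphoid-style satellite
    arrays, fragmented transposons and gene models; sibling genomes with
    per-region substitution rates, planted deletions and insert-size jitter;
    uniform-coverage 100 bp paired reads), plus a lightweight seed-and-extend
    read mapper so the whole pipeline runs on desk-scale data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
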