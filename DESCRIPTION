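Package: parthenoscan
Title: Standardized Genome Features of Parthenogenetic Animals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A standardized pipeline for quantifying genome features that have
    been proposed as consequences of parthenogenetic reproduction:
    intragenomic heterozygosity estimated directly from sequencing reads via a
    negative-binomial mixture model fitted to the k-mer spectrum (including
    decomposition of the allele structure of polyploids from heterozygous
    k-mer families), transposable-element load from low-coverage read
    subsamples annotated against a repeat library, palindromic gene
    arrangements detected as reverse-complementary collinear blocks on a
    single scaffold, and horizontal-gene-transfer candidates of non-metazoan
    origin with a scaffold-linkage contamination control. A synthetic-genome
    generator produces multi-haplotype genomes with prescribed divergence
    topologies (AB, AAB, AAAB, AABB, ABC), implanted repeats, palindromes and
    foreign genes, together with truth tables, so that every stage can be
    validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
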