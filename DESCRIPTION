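Package: haplograph
Title: Haplotype Graphs and Pan-Genome Analytics for Autotetraploid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds haplotype graphs from window-clustered haplotype sequences of
    highly heterozygous autotetraploid genomes, genotypes node copy numbers in a
    query genome from short-read marker k-mer depths with a Gaussian-mixture
    expectation-maximization model, stitches copy-supported nodes into phased
    pseudo-contigs and scores them against a truth set. Also provides window-based
    population statistics (nucleotide diversity, Watterson theta, haplotype-block
    counting, haplotype sharing, linkage-disequilibrium decay), pan-genome
    saturation fitting, gene-family pan/core resampling analyses, depth-based
    contig ploidy triage, and a synthetic pan-genome simulator so that the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    Rcpp,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
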