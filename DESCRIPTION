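Package: rebait
Title: Targeted Assembly of Genomic Regions by Iterative Read Baiting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selectively assembles target genomic regions (mitochondrial
    genomes, rDNA repeat units, barcoding loci) from whole-genome shotgun
    read sets without assembling the whole genome. Reads are recruited by
    exact 31-mer matching against a bait set seeded from one or more
    reference sequences, assembled de novo with a deterministic greedy
    overlap assembler, and the bait is replaced by the growing assembly
    until a per-target completion criterion is met (exhaustive, total
    size, longest contig, N50, or full-length homology match with
    oriented region extraction). Multiple targets run as independent
    threads within a single pass over the reads. Helpers detect identical
    end overlaps to circularize contigs of circular molecules and tandem
    repeat units, and a seeded simulator generates genomes and paired-end
    reads for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
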