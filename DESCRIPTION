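Package: motifstore
Title: Composite-Motif DNA Data Storage with Motif-Search Decoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end composite-motif DNA data-storage system. Binary
    payloads are encoded as addressed composite motifs (unordered k-subsets of
    a prefabricated payload-motif library) via exact combinadic ranking, giving
    floor(log2 C(m,k)) bits per synthesis cycle. Simulators model enzymatic
    bridged oligonucleotide assembly (expansion of logical sequences into
    single-molecule oligo pools) and amplification-free direct nanopore
    sequencing of short oligos, including merged multi-oligo reads, heavy
    3'-end truncation, strand flips and junk reads. The Motif-Search decoder
    recovers the stored data from noisy reads by spacer k-mer-vote
    segmentation, randomized-embedding position refinement, affine-gap local
    alignment of inter-spacer windows against the motif library, greedy
    overlap resolution, and top-k frequency consensus per address.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
SystemRequirements: C++11
RoxygenNote: 7.3.3
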