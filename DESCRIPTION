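Package: tdnarch
Title: Reconstruction of T-DNA Insertion Architecture from Long Reads and
    Optical Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to locate and reconstruct Agrobacterium T-DNA and vector
    backbone insertions in plant genomes from long reads or assembled
    contigs, and to size them independently from nick-label optical maps.
    Reads and contigs are segmented into genomic, T-strand and backbone
    blocks with an exact k-mer seed-and-extend annotator; per-locus
    insertion architectures (concatemer segments, orientation flips,
    border truncations, insertion-site deletions) are summarized, and
    large-scale rearrangements (inversions, translocations, arm swaps)
    are classified from split contig alignments. A dynamic-programming
    label-map aligner with an explicit sizing-error model estimates
    insertion sizes from CMAP/XMAP optical data. Epigenomic profiling of
    inserted vector sequence covers small-RNA size-class tables and
    binomial methylation calling in CG/CHG/CHH contexts with
    Benjamini-Hochberg FDR control. A fully seeded synthetic-data
    generator (genomes, concatemer insertions, rearrangements, noisy long
    reads, labelled molecules, small-RNA reads, bisulfite counts) with a
    machine-readable truth ledger supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    IRanges,
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
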