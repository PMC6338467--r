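# tdnarch

Reconstruction of Agrobacterium T-DNA insertion architecture from long
reads and optical maps, with epigenomic profiling of the inserted
vector.

## Who this is for

Plant genomicists and transgene-line curators who need to know *what
actually integrated* at a T-DNA locus. Insertions in widely used
mutant collections (SALK, SAIL, WISC) are rarely single clean copies:
they are concatemers of T-strand and vector backbone — scrambled,
orientation-mixed, border-truncated — accompanied by insertion-site
deletions and sometimes chromosome-scale rearrangements, and the
inserted DNA is often silenced by RNA-directed DNA methylation.
`tdnarch` takes long reads or assembled contigs plus the
transformation-vector sequence and reconstructs each locus; takes
nick-label optical maps (CMAP/XMAP) and sizes insertions independently
of assembly; and profiles siRNA size classes and CG/CHG/CHH
methylation on the vector.

## What it computes

* **Segmentation** — an internal exact k-mer seed-and-extend aligner
  tiles each read/contig into `genomic | t_strand | backbone | linker`
  blocks, with breakpoints where vector coordinates jump or
  orientation flips.
* **Architecture** — per locus: genomic anchors, deletion
  (`right_anchor − left_anchor`), ordered segments, total insert
  length (conserved: Σ segments + Σ linkers), border identity (LB/RB)
  and truncation measured from the border's outer edge inward.
* **SV calls** — loci clustered across reads; inversions,
  intra-/inter-chromosomal translocations, arm swaps and unplaced
  fragments classified from split contig alignments; per-sample
  In/Re counts with reciprocal-evidence deduplication.
* **Optical sizing** — in-silico Nt.BspQI digest (`GCTCTTC`, both
  strands), a dynamic-programming label-map aligner with an explicit
  robust sizing cost, and insertion/deletion sizes from inter-label
  distance discrepancies; CMAP 0.1 / XMAP 0.2 I/O.
* **Epigenome** — per-element siRNA size-class tables (15–20, 21, 22,
  23, 24 nt; exact full-length matches only) and per-cytosine
  methylation calls (one-sided binomial against the non-conversion
  rate, Benjamini–Hochberg FDR at 1%).
* **Simulation** — seeded generators for genomes, concatemer
  insertions (border truncations drawn from 73–113 bp), inversions /
  excisions / translocations / arm swaps, noisy long reads, labelled
  molecules (FP/FN/sizing noise, 100 kb length filter), element-
  targeted small RNAs, and bisulfite counts — all tied together by a
  truth ledger that round-trips byte-for-byte.

## Worked example

Simulate a locus, then recover its architecture from a spanning read:

```r
library(tdnarch)

genome <- simulate_genome(c(chr1 = 60000), seed = 7)
vec    <- prok2_like_vector(seed = 8)            # 4.4 kb T-strand + 4.6 kb backbone
conc   <- simulate_concatemer(vec, copies = 2, flip_prob = 1,
                              breakpoint_prob = 0, seed = 9)
imp    <- implant_events(genome,
                         list(insertion_event("chr1", 30000, conc, vec,
                                              deletion = 1200)))

idx  <- build_anchor_index(genome = genome, vector = vec)
op   <- imp$ledger$ops[1, ]
read <- substr(imp$genome[["chr1"]], op$der_start - 3000 + 1, op$der_end + 3000)
arch <- summarize_architecture(
  segment_sequence(anchor_blocks(read, idx), nchar(read), vec,
                   query_id = "read_1"), vec)
arch
#> <insertion_architecture> chr1:30,000-31,200
#>   deletion: 1,200 bp, insert: 8,613 bp (2 segment(s) + 0 bp linker), 1 breakpoint(s)
#>   borders: left RB (96 bp missing), right LB (91 bp missing)
#>     source vstart vend orientation length
#> 1 t_strand      0 4304           -   4304
#> 2 t_strand     91 4400           -   4309
```

The read covers two reverse-oriented T-strand copies (one internal
breakpoint where vector coordinates jump), the 1,200 bp deletion the
insertion caused, and border truncations of 96 and 91 bp — inside the
73–113 bp range the simulator drew from:

```r
measure_border_truncation(arch)
#>   junction border missing
#> 1     left     RB      96
#> 2    right     LB      91
```

Coordinate arithmetic follows printed-coordinate conventions, e.g. a
deletion printed as chr2:18,864,678–18,870,175:

```r
span_length(18864678, 18870175, "bp")
#> [1] 5497
```

A whole run — simulate, annotate, cluster, size, profile — is one
call: `run_pipeline(list(sample = "toy", seed = 42, simulate = list(...),
optmap = list(), epigenome = list(simulate = TRUE)))`, or from a shell,
`Rscript scripts/run_pipeline.R --config config.yaml --out outdir`.

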