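---
title: "Reconstructing T-DNA insertion architecture: methods and design"
author: "tdnarch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing T-DNA insertion architecture: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdnarch)
```

## The problem

Agrobacterium-mediated transformation rarely delivers a single clean
T-DNA copy. Insertions at a locus are typically conglomerates —
concatemers mixing T-strand and vector-backbone copies in both
orientations, with internal breakpoints, border truncations, and
deletions of the flanking genomic sequence — and can reach tens to
hundreds of kilobases, far beyond the T-strand itself. Larger
rearrangements (inversions, intra- and inter-chromosomal
translocations, reciprocal exchanges of chromosome arms) can accompany
integration, and the inserted sequence is frequently silenced through
RNA-directed DNA methylation (RdDM), visible as 24 nt siRNAs plus dense
cytosine methylation in all three plant contexts (CG, CHG, CHH with H
∈ {A, C, T}).

`tdnarch` reconstructs these events from long reads or assembled
contigs, sizes insertions independently from nick-label optical maps,
and profiles the epigenomic state of the inserted vector. A
synthetic-data generator with a machine-readable truth ledger provides
ground truth for every stage, so the whole pipeline is testable end to
end.

## Coordinates

All internal coordinates are 0-based half-open; interval length is
always `end - start`. Printed 1-based coordinates convert by
`start - 1`, and pairs of printed positions subtract directly: a
deletion printed as chr2:18,864,678–18,870,175 spans
`span_length(18864678, 18870175)` = 5,497 bp.

## Segmentation and architecture

Reads/contigs are annotated by an internal exact-k-mer seed-and-extend
aligner (`anchor_blocks()`): k-mers (default k = 14, matching the exact
word length commonly used for stringent short-read mapping) are hashed
over the genome and vector, matches collinear in query and target
within a diagonal band (default 25 bp, the indel tolerance) are chained
and merged, and block edges are extended by a gapped X-drop scan
(+1 match / −2 mismatch, drop 16, single-base indel hops) so that
junction placement survives isolated read errors. Identity is
estimated from k-mer survival — with per-base accuracy $a$, a fraction
$\approx a^k$ of k-mers anchor exactly, so $\hat a = f^{1/k}$ where $f$
is the anchored fraction. This is 1.0 for exact matches and ≈ 0.94 at
5% read error; the default threshold 0.8 tolerates nanopore-like error
while rejecting random similarity. A pluggable external aligner could
replace this backend, but the internal one keeps the pipeline
dependency-free and its behaviour fully specified.

`segment_sequence()` resolves overlapping blocks (identity, then
length, then vector-coordinate contiguity with the neighbouring block,
then lowest target coordinate — fully deterministic, which matters for
vectors with internal duplications such as a doubled terminator),
relabels vector blocks as T-strand or backbone by majority overlap
with the T-strand interval (blocks straddling the border are cut at
it), absorbs gaps up to `gap_tol` (25 bp) and labels larger gaps
`linker`, and records a breakpoint wherever adjacent vector-derived
blocks jump by more than `contig_tol` (25 bp) in vector coordinates or
flip orientation.

`summarize_architecture()` turns a spanning annotation into the locus
record: genomic anchors (junction = outermost genomic block edge
adjacent to vector sequence), deletion length (negative values would be
target-site duplications, supported though rarely observed), ordered
segments, and border assignment. Border truncation is measured from
the border's outer edge inward — the convention under which a
simulated truncation of 90 bp is reported as 90 — because observed
truncations (typically 73–113 bp) exceed the ~25 bp border repeat
itself, so the distance is necessarily anchored at the outer edge.

**Identifiability caveat.** With error-free reads, junction placement
is exact only up to the micro-homology between the insert end and the
flanking genome: if the first $h$ inserted bases coincide with the
continuing genomic sequence, every split within those $h$ bases
describes the same read, and no aligner can distinguish them. Under a
uniform base model the overshoot is geometric (mean 1/3 bp per
junction); the validation suite therefore asserts exactness up to this
ambiguity (±12 bp covers it with probability ≈ 1 − 4⁻¹²) rather than
literal equality, and ±20 bp at 5% read error. The same ambiguity is a
genuine feature of real junctions, where microhomology-mediated repair
is common.

## Rearrangement classification

`classify_rearrangement()` walks the ordered genomic blocks of each
contig: a reversed-orientation block contiguous with both flanks is an
inversion; a displaced block whose flanks are mutually contiguous is an
intra-chromosomal translocation (its `inverted` flag records
orientation); joins between chromosomes are arm swaps when the contig's
outermost blocks reach both chromosome ends (within 10 kb), otherwise
inter-chromosomal translocations; and a single-block contig matching a
fragment skipped at another contig's join is an unplaced fragment. Note
that an intra-chromosomal translocation has two equivalent minimal
descriptions (moving segment A between B and C is the same derived
genome as moving B between A and C); the classifier reports one of
them. Counting (`count_events()`) deduplicates reciprocal evidence for
the same event by keying on the unordered set of breakpoints — one
consistent convention, since published summary tables rarely state
theirs.

## Optical map sizing

Molecules are labelled at every occurrence of the Nt.BspQI site
(GCTCTTC) on either strand (single-enzyme chemistry); the label is
placed at the motif start, since the true nick offset is a constant
that cancels in all distance arithmetic. `align_label_maps()` is an
explicit, simplified dynamic program — deliberately not a
reimplementation of a commercial aligner's likelihood. Its cost is

* per adjacent matched pair, the squared sizing discrepancy
  $\left(\frac{|\Delta q - \Delta r|}{s\,\max(\Delta q, \Delta r, 1)}\right)^2$
  capped at an outlier penalty;
* `miss_q` per unmatched query label anywhere (the whole molecule
  should align);
* `miss_r` per unmatched reference label inside the aligned span
  (labels outside it are free — a molecule covers a window of the
  chromosome).

Defaults: `sizing_scale` s = 0.05 (a 5% interval discrepancy costs 1),
`outlier` = 30, `miss_q` = `miss_r` = 10, skip depth 5 (complexity
O(n·m·36)). The symmetric denominator max(Δq, Δr) and the outlier cap
are what let alignments *bridge* genuine insertions: an uncapped or
reference-scaled cost grows quadratically with insert size and would
force the optimum to truncate at every real event, making sizing
impossible. With the cap, bridging a 250 kb insert costs at most
`outlier` plus the skipped-label penalties, which is cheaper than
abandoning a long flank. A lenient scale (e.g. 0.2) is also unsafe in
the other direction: when inter-label spacings are similar, shifted
matchings become nearly free. The defaults assume ~2% sizing noise,
matching the simulator's.

`call_insertion_size()` emits, for each adjacent matched pair whose
query/reference interval discrepancy exceeds `min_size` (default
1.5 kb, roughly the sizing noise at typical inter-label distances),
an insertion (positive) or deletion (negative) at the midpoint
reference coordinate, merging runs of adjacent discordant intervals.
On noiseless input the estimate is exact; at 2% sizing noise the mean
over a dozen molecules is within 2% across 10–250 kb inserts. Sizing
validation uses insert sequences free of the nicking site (see
`mask_sites()`): inserts carrying many internal labels would need a
correspondingly larger skip depth, and a vector that lacks the
recognition site is the scenario in which label-gap sizing is
best-posed. CMAP 0.1 / XMAP 0.2 dialects are written with positions to
0.1 bp; the XMAP `Alignment` column stores `(refSite,qrySite)` pairs.

## Epigenome profiling

`classify_context()` implements the plant context classes on either
strand; positions without two downstream bases of strand context are
reported `none` rather than guessed. `call_methylated_sites()` tests
each covered cytosine against the bisulfite non-conversion rate with a
one-sided (greater) binomial test — one-sided because non-conversion
can only inflate the methylated count — followed by Benjamini–Hochberg
correction, calling sites methylated at q ≤ 0.01. The non-conversion
rate is an input (default 0.0035, i.e. the `< 0.35%` bound one would
estimate from an unmethylated chloroplast control); whether published
per-site callers used exactly a binomial test is usually unstated, so
binomial + BH is this package's explicit choice.

`sirna_size_table()` counts a read only if it matches the vector
exactly, full length, no mismatches or gaps, on either strand —
multimappers count once at the lowest coordinate and are flagged.
Reads are assigned to the element containing the majority of the
matched span (a stated convention; boundary-straddling reads are not
split), pooled as 15–20 nt and separate 21/22/23/24 nt classes, raw
counts by default with an optional per-kb mode (figure-style raw
counts are the default because cross-element comparisons in the
source domain are typically unnormalized).

## The synthetic-data generator

The generator is first-class, tested code; its defaults state the
study conditions the analysis assumes:

* **Vector**: 4.4 kb T-strand + 4.6 kb backbone (a pROK2-like layout
  with NOSp, nptII, duplicated NOSt, CaMV 35S elements); 7.1 kb and
  9.1 kb T-strands are a parameter away.
* **Concatemers**: geometric copy number (the copy-number distribution
  is not observable from published summaries; geometric is the
  simplest memoryless choice, configurable), per-copy internal
  breakpoints and orientation flips, terminal copies always T-strand
  (insertions begin and end in border sequence), border truncations
  drawn uniformly from 73–113 bp, optional 55 bp G-rich linkers
  (≥ 26 G) between segments — treated as arbitrary filler, since
  whether such linkers arise from integration machinery or assembly
  is open.
* **Events**: insertions with site deletions, inversions, excisions,
  intra-chromosomal translocations (optionally inverted), arm swaps;
  a microhomology-style excision is expressible as excision. The
  truth ledger records source and derived coordinates plus every
  implanted sequence, and round-trips byte-for-byte.
* **Reads**: substitution + indel noise only — sufficient to stress
  the segmentation contract; homopolymer-specific error is not
  modelled.
* **Molecules**: label false negatives (probability per label), false
  positives (per 100 kb), multiplicative inter-label sizing noise, and
  a minimum-length filter (100 kb reproduces the standard molecule
  filter; fluorescence signal-to-noise itself is not modelled, only
  its downstream length cut).
* **Bisulfite**: methylated counts are
  Binomial(depth, level + (1 − level)·p₀) per strand-resolved
  cytosine.

All generators are bit-reproducible under a fixed seed; the pipeline
derives per-stage seeds from one master seed via fixed offsets.

What passing on synthetic data does *not* show: real nanopore error is
structured (homopolymers), real insertions can exceed read length
(reported open-ended here, as in practice), optical molecules have
fragility and stretch biases beyond i.i.d. sizing noise, and real
bisulfite data has coverage heterogeneity. The synthetic suite
validates the *algorithms and their contracts*, not instrument models.

## Problem sizes used in validation

The test suite runs at desk scale, chosen so the full suite completes
in minutes while keeping every estimate's sampling error far below its
tolerance: genomes of 20–600 kb, 30–100 seeded replicates for junction
recovery, 500 instances for the alignment-vs-enumeration equivalence
(maps to 8 labels), 12 molecules per insert size for optical sizing,
and ~10,000 cytosines × 50 seeds for the null-FDR check.

## Known limitations

* Junction coordinates are identifiable only up to junction
  micro-homology (above).
* Insertions larger than the read/contig span are summarized
  open-ended, with no attempt to assemble across them.
* The optical DP's bounded skip depth limits how many unexpected
  labels one step can absorb; heavily labelled large inserts require a
  larger `max_skip`.
* Phasing of heterozygous insertions is limited to the vector-free
  spanning-read fraction (`zygosity_hint`); no genotype model is fit.
* The rearrangement classifier targets isolated, well-supported
  events; deeply nested rearrangements are flagged rather than
  decomposed.
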