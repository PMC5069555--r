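---
title: "Calling non-templated 3' oligo(U) tails in CLIP-seq reads: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling non-templated 3' oligo(U) tails in CLIP-seq reads: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uridylome)
```

## The problem

Terminal uridylyltransferases mark RNAs for decay by appending short
non-templated oligo(U) stretches to their 3' ends; the cytoplasmic
exoribonuclease DIS3L2 recognizes and degrades these uridylated
substrates. CLIP-seq with a catalytically dead DIS3L2 bait captures the
uridylated RNA population ("the uridylome") in vivo: protein-bound RNA is
fragmented with RNase T1 (which cleaves 3' of guanosines), gel-selected,
reverse-transcribed and sequenced. The computational problem this package
addresses is to recover, from such reads, (i) which reads carry a
non-templated 3' tail and of what composition, (ii) which RNA each read
came from, positioned within its gene model, and (iii) the positional
summaries that characterize the substrate classes — all of it verifiable
on synthetic data with known ground truth.

## Two-pass mapping and the tail-calling model

A read with a long U tail will not map end-to-end, so mapping proceeds in
two passes. Pass 1 aligns the raw read; reads that fail are trimmed of
3'-terminal T stretches of at least `trim_min_run = 4` nt (runs of more
than three Ts) and realigned in pass 2. Every read ends up in exactly one
of four classes — `pass1`, `pass2`, `unmapped`, `all_tail` — and the four
counts always sum to the input count, which every run asserts.

The built-in aligner is a 5'-anchored seed-and-extend search intended for
desk-scale references (up to a few hundred kb): the first `min_span = 18`
nt of the read are matched exactly against both strands of every contig,
and each hit is extended base by base. The aligned span `k` must satisfy
three conditions:

* running mismatch count within the budget `floor(k / 25)` (one mismatch
  per 25 aligned nt by default);
* the span ends on a matching base;
* the last `tail_guard = 12` nt of the span are mismatch-free.

Among admissible spans the aligner maximizes `span − 2·mismatches`
(shorter span wins ties). The guard window deserves explanation: without
it, the mismatch budget lets the aligner "absorb" the first tail base as
a mismatch whenever two or more subsequent tail bases coincide with the
genome, silently shortening the called tail. With the guard, a tail base
can only be absorbed if followed by 12 consecutive coincidental matches
(probability about `0.25^12`), which makes the aligned span end exactly at
the last genuinely templated base for error-free reads, while still
tolerating isolated internal mismatches more than 12 nt from the 3' end.
This realizes the rule that tails must match the genome exactly to count
as templated. A placement is *unique* when its score exceeds the
second-best placement by at least `unique_margin = 2`; non-unique reads
are kept in the alignment table but excluded from tail calling.

Pass 1 runs by default in *soft* mode (an unaligned 3' remainder of up to
40% of the read is allowed, so short A/C/G tails do not unmap a read);
*strict* mode (end-to-end) reproduces the published procedure in which
uridylated reads fail pass 1 entirely and are rescued by trimming.

### The maximal-templated convention

Given a unique alignment, the raw 3' remainder (the unaligned suffix plus
any Ts trimmed before pass 2) is extended base by base along the genome
past the alignment end, strand-aware. The maximal genome-matching prefix
is the *templated overlap*; the residual is the *untemplated tail*. A
genomically encoded T run directly downstream of an RNA 3' end is
therefore never counted as tail — encoded and added uridines cannot be
distinguished at such junctions, and this convention deliberately
undercounts rather than overcounts. Every output header records it. The
composition classes are:

* `U+` — terminal untemplated T run of at least `min_u = 4` nt ("at least
  4 Us"), regardless of upstream tail bases (`ATTTT` is `U+`);
* `U`, `A`, `C`, `G` — homopolymer tails below the U+ threshold, labelled
  by their base (reported in RNA sense, so T-runs shorter than `min_u`
  are class `U`);
* `mixed` — heterogeneous tails (`TTTTA` is mixed: the terminal base is
  not part of a qualifying U run);
* `none` — empty tail.

The exposed `min_u` default of 4 follows the "at least 4 Us" definition;
the alternative reading "longer than four" (i.e. 5) is one configuration
flag away.

## Annotation

Reads are assigned to genes by a fixed priority — tRNA > miRNA > snRNA >
5S rRNA > miscRNA > snoRNA > mRNA > lincRNA — so that, for example, an
intronic snoRNA outranks its host mRNA and a pre-tRNA trailer read is
never swallowed by an overlapping mRNA annotation. tRNA genes are queried
with ±60 nt extensions (pre-tRNA leaders/trailers) while retaining mature
bounds. Assignment is same-strand only; ties within a category go to the
larger overlap, then the lexicographically smaller gene id. Anchors of
calls whose read interval overlaps nothing are given a second chance
within a configurable 200-nt window downstream of annotated 3' ends,
where 3'-extended degradation intermediates accumulate.

Each annotated call gets a signed offset of its anchor (last templated
base) from the mature 3' end: 0 is the mature end (`Mat`), negative is
trimmed (`Trim`), positive is 3'-extended (`ext`) — the trichotomy used
for snRNA 3'-end states, tallied per gene together with the U+ count.
mRNA anchors are sub-classified into 5'UTR/CDS/3'UTR/intron from the gene
model (an exon1-intron1 junction read classifies as intronic, consistent
with unspliced precursors). tRNA anchors get cloverleaf subregions from a
linear partition of the mature length — acceptor stem 0–18%, D-arm
18–44%, anticodon arm 44–66%, T-loop 66–100%, trailers outside — a
documented stand-in for structure-derived arm boundaries, which the
underlying study does not specify; callers can supply their own
partition.

## Hybrid (chimeric) reads

Intramolecular ligation during CLIP joins two RNase T1 fragments of one
molecule; the resulting read maps as two arms of one locus, and the 5'
arm of a genuine ligation ends in G. Detection is an exhaustive split
search: every split point with both halves at least `min_arm = 12` nt is
tried, the 5' half aligned end-to-end, the 3' half 5'-anchored with a
free remainder (its tail), and candidates kept when both halves map
uniquely. The winning candidate maximizes total aligned length subject to
both arms on one strand of one annotated locus with a gap in
`[min_gap = 4, max_gap = 10000]` nt; ties break by fewest mismatches,
smallest gap, then — decisive in practice — by preferring a split whose
5' arm ends in G, then the longer 5' arm. The G rule remains a *flag* on
the emitted call (`rnase_t1_consistent`), never a filter.

One genuine limitation surfaced by the simulator: when the genome base
just past the 5' arm coincides with the 3' arm's first base, neighbouring
splits reconstruct the *identical* read, and no algorithm can tell them
apart. In random sequence at GC 0.5 roughly one in eight simulated
hybrids is ambiguous in this way. Such calls are flagged
(`ambiguous_junction`) and dropped from the hybrid table by default, the
same way inter-locus best splits are: a conservative caller reports only
identifiable junctions. On the retained calls, junction recovery on
simulated data is essentially exact; the cost is a corresponding loss of
sensitivity, which the truth tables quantify.

Reads that map contiguously are never candidates (they are screened out),
and a read whose two halves map adjacently (gap below `min_gap`) is not a
hybrid; together these make false chimera calls on contiguous reads
structurally impossible rather than merely rare: an arm always matches at
its true position, so any extra coincidental placement renders it
non-unique and discards the candidate.

## Profiles

* **Tail histograms** per composition class (optionally per category) on
  untemplated lengths, with medians and quartiles.
* **U+ fraction per category**, with explicit denominators.
* **Scaled coverage**: each gene's mature length scaled to 100% into 100
  bins, bin 100 being the mature 3' end on either strand; per-read bin
  coverage accumulated over U+ calls and each row normalized to maximum
  1. Row order: category (priority order), then gene id.
* **TSS metagene**: each U+ call contributes one count at the offset of
  its 3' anchor from the nearest TSS, signed in the TSS strand's
  orientation (upstream negative, so the documented antisense peak 200 nt
  "upstream" appears at −200); same-strand calls feed the sense profile.
  Peaks are maxima after a centred moving average (`smooth = 5` nt) over
  a ±500 nt window. An external bedGraph (e.g. RNAP II occupancy) can be
  averaged over the same offsets for a side-by-side overlay; no cross-
  track statistics are computed.

## The simulator and what a green test establishes

`simulate_clip_run()` emulates exactly the structure the analysis
assumes: random gene loci of all eight categories on one contig (mRNAs
with TSS, exons, one intron and UTRs; optional minus-strand genes,
duplicated loci for multi-mapper tests, snoRNAs nested in mRNA introns
for priority tests); partial RNase T1 digestion (each G cut with
probability 0.5 — the digestion extent behind the published two-enzyme-
concentration protocol is unstated, so it is a configurable default, not
a fitted value); per-category tail models (oligo(U) lengths 4–20 nt as a
truncated shifted Poisson with median 7, matching the reported 6–8 nt
range; A/C/G runs of 1–3 nt, uniform); reads of 20–110 nt (the gel-
selection range, shorter allowed after trimming); a fixed fraction of
intramolecular chimeras whose 5' arm ends at a G; constant FASTQ
qualities (the pipeline never uses them); DNA alphabet throughout, since
reads are sequenced cDNA. Every read carries a truth row (locus, fragment
coordinates, exact appended tail, chimera arms), and a fixed seed gives
byte-identical FASTQ and truth tables.

What the simulator does *not* emulate — sequencing errors, PCR
duplicates, adapter read-through, crosslink-induced mutations, expression
heterogeneity, paralog families beyond verbatim duplicated loci — bounds
what a green test establishes: correctness of the algorithms under the
stated generative model, not robustness to platform artefacts. Reads
whose genomic fragment is shorter than the 18-nt minimum aligned span
(about a fifth of a 20–110 nt library digested this way) are structurally
unmappable, and recovery guarantees are therefore stated over reads the
aligner is permitted to map.

## Numerical and design choices

* Coordinates are 0-based half-open internally; 1-based only in GFF3 and
  reports (chimera junctions are reported 1-based in transcript
  coordinates of their locus, matching figure conventions like the
  28/61 hairpin junction).
* Tail calling on the minus strand happens in transcript orientation
  (reverse-complemented genome downstream of the alignment's 3' end).
* The composition enum gains a plain `U` class for sub-threshold T
  homopolymers; the published histograms bin U runs of all lengths, so a
  4-threshold-only enum would silently relabel 1–3 nt U tails.
* The config file is declarative JSON (`validate_config()` fills
  documented defaults, rejects unknown keys and out-of-range values in
  one aggregated report, and is idempotent); every threshold is echoed
  into the run manifest, and output TSV headers repeat the active
  configuration.
* The run manifest records input and output MD5 checksums, per-stage
  counts and the seed; identical config + seed reproduce byte-identical
  outputs.
* External alignments (SAM/BAM) import through `import_alignments()`:
  3'-most soft clips (in original read orientation) become remainders,
  secondary/supplementary records are dropped, and uniqueness is MAPQ ≥
  20. The native and imported paths produce identical tail calls where
  the alignments agree, which the round-trip test enforces.

## Known limitations

* The seed of the built-in aligner is the exact first `min_span` nt of
  the read; a sequencing error in that prefix hides a placement the
  exhaustive search would find. For error-free synthetic data the two are
  provably equivalent; for error-containing real data, import external
  alignments instead.
* A chimera whose 3' arm plus tail fits inside the soft-mode remainder
  allowance maps contiguously in pass 1 and is not routed to chimera
  detection; strict pass-1 mode avoids this at the cost of more pass-2
  traffic.
* Multi-copy gene families are handled only by the uniqueness margin
  (multi-mappers are excluded, not rescued); repeat-aware remapping,
  e.g. against a dedicated rDNA contig, is supported only insofar as the
  user supplies that contig in the reference.
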