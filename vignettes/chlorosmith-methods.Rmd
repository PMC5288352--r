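---
title: "Targeted plastome assembly and variant-landscape analysis with chlorosmith"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted plastome assembly and variant-landscape analysis with chlorosmith}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chlorosmith)
```

## The problem

Whole-genome shotgun libraries from green plant tissue contain the
chloroplast genome at a very high copy number relative to the nuclear
genome — often two orders of magnitude. chlorosmith exploits this
over-representation to assemble the plastome *de novo* from the bulk
reads, without mapping to a reference, and then to characterize the
mutational landscape (SNVs and InDels) of a set of such assemblies
against a reference plastome.

A plastome is a circular molecule with a conserved quadripartite
architecture: a large and a small single-copy region (LSC, SSC)
separated by two identical inverted repeats (IRa, IRb). Two properties
of this architecture drive the design throughout the package:

* single-copy plastome sequence appears in the k-mer spectrum of the
  bulk reads as a coverage peak at some multiplicity N, and the IRs —
  present twice per circle — as a *linked* second peak at 2N;
* any assembler collapses the two identical IR copies into one
  high-coverage contig, so the quadripartite circle has to be restored
  explicitly afterwards.

## The five-stage assembly pipeline

**Stage 1 — spectrum and linked peaks.** Reads are quality-filtered
(pairs are kept when both mates have mean Phred above 20; the
threshold interprets a per-read "Q-value" cutoff as a mean, the least
aggressive of the common readings). Canonical k-mers (k = 31 by
default; k is exposed everywhere) are counted and the multiplicity
histogram is smoothed with a width-5 moving average. Local maxima are
located with plateau handling, and each candidate peak is refined to a
count-weighted centroid whose window re-centers on the running
estimate; this matters because fragment-based sampling overdisperses
multiplicities, making the raw local maximum wobble by several units —
enough to push the peak-pair ratio outside tolerance. The pair of
refined peaks whose ratio lies within 2 ± 0.15 and which carries the
most k-mer mass becomes the peak model. The valley separating the
error/nuclear spike from the chloroplast band is the first local
minimum after the initial spike.

**Stage 2 — baiting and initial assembly.** Bait k-mers are those with
multiplicity in `[max(valley + 1, 0.5 N), 3 N]`, a band that spans both
the N and 2N peaks while excluding nuclear (about N/100) and error
(mostly singleton) k-mers. A read pair is baited when either mate
contains a bait k-mer, preserving insert information. The baited reads
are assembled with a canonical-k-mer de Bruijn graph at each word size
of a spread (31, 41, 51, 63), and the candidates are scored: fewest
scaffolds, then total length within 0.8–1.2 x the expected genome size
when one is supplied, then N50.

The graph cleaning proceeds in three layers. First an abundance cutoff
at the spectrum valley of the assembled read set itself (the
least-populated multiplicity below the instance-weighted median, ties
towards 1) removes the bulk of error k-mers; because ties resolve
towards multiplicity 1, a clean low-coverage read set — where the
histogram has no error spike — keeps everything. Then dead-end unitigs
shorter than 2k with coverage under a tenth of the weighted median are
clipped as tips, together with "hairs": dead-end paths at under a
twentieth of the median regardless of length, which arise from reads
carrying several clustered errors. Finally parallel unitigs between
the same flanking nodes that differ by at most 3 edits are popped as
bubbles, keeping the higher-coverage arm. Rounds of clipping and
popping alternate until stable.

**Stage 3 — iterative re-selection.** Reads from the full QC-passed
set (not only the baited subset) sharing at least one exact k-mer with
the current assembly are re-selected and reassembled, until the total
length changes by less than 0.1% or five iterations pass. This
recovers segments whose k-mers fell outside the bait band (for
example, diverged or locally under-represented sequence). No stage
may return an assembly scoring worse than its input.

**Stage 4 — scaffold-end rescue.** For each scaffold end, pairs with a
mate matching the terminal 500 bp are locally assembled and the end is
extended when a local contig overlaps it by at least k bases with at
most 1 mismatch per 100 bp. Two safeguards keep this honest on
complete assemblies: an extension whose k-mers already occur elsewhere
in the assembly is rejected (it is a repeat boundary, not missing
sequence), and scaffolds whose coverages differ by more than 1.5-fold
are never merged (a collapsed IR at about twice single-copy coverage
must stay separate for structural resolution).

**Stage 5 — gap filling.** For each N-run, pairs anchoring within two
insert lengths of the flanks are locally assembled, and a contig
bridging both flanks with exact k-base anchors replaces the N-run;
gaps without such a bridge are kept and reported.

## Quadripartite resolution and canonical form

After gap filling, the typical assembly consists of three scaffolds:
the LSC arc, the SSC arc, and the collapsed IR at about twice their
coverage. `restoreQuadripartite()` identifies the IR by coverage and
re-threads the circle LSC + IR + SSC + rc(IR) through the exact
(k-1)-base junction overlaps.

The SSC orientation cannot be decided from the unitig graph alone:
both isomers satisfy every junction overlap, which mirrors the
biological situation (plastid preparations contain both SSC
orientations). `genomesEquivalent()` therefore treats the SSC flip as
identity by default, with a flag to disable.

`findInvertedRepeat()` locates the IR pair as the longest pair of
disjoint spans that are exact reverse complements, seeded at canonical
k-mers occurring exactly twice on opposite strands and extended
maximally. Because a linear cut through an IR copy truncates the
detectable repeat, detection runs twice: once on the given rotation,
then again after rotating the cut into the middle of the longer
inter-IR arc — the second pass recovers the exact spans regardless of
the input rotation. `canonicalizeGenome()` rotates to LSC-first order
(LSC, IRa, SSC, IRb, with IRa the copy following the LSC) and picks
the lexicographically smaller of the two strand readings, making the
canonical form unique over all rotations and reflections. For
simulated genomes the two bases flanking each IR copy are chosen so
the planted repeat is maximal; without this, exact-match detection
would legitimately report spans one or two bases larger than planted.

Genome comparisons use MUMmer-style anchor chains: maximal exact
matches seeded at k-mers unique in both sequences, chained by dynamic
programming to the heaviest subset with increasing query and target
order. Anchors may overlap by a few bases where maximal extension runs
through the repeat context around an InDel; overlaps below the seed
size are allowed during chaining and trimmed afterwards, which keeps
anchors exact.

## Variant calling and the density analysis

Variants are called assembly-against-reference: the anchor chain
verifies collinearity (at least 90% of the reference covered by
plus-strand anchors, otherwise the caller aborts), inter-anchor
segments are globally aligned with affine gap penalties (match +1,
mismatch -2, gap open -4, gap extend -1, via
`Biostrings::pairwiseAlignment`), and alignment columns become
variants with the VCF anchor-base convention. All InDels are
left-normalized through repeat context; normalization is idempotent
and cross-checked against `bcftools norm` in the test suite. A<->G and
C<->T SNVs are transitions, everything else a transversion.

Multi-sample merging groups normalized variants by position within two
class families (SNV versus InDel), records the union of alternate
alleles and per-sample presence, and flags a position triallelic when
two or more distinct alternates are observed — matching multisample
calling semantics. The density report counts variants per scope —
whole genome; LSC, SSC and pooled IR; exon, intron and intergenic
from a gene annotation — and reports `count * 1000 / span` per kb. Two
conventions are explicit because the choice changes the numbers: the
IR denominator is the *combined* length of both copies, and a variant
belongs to the scope containing its normalized 1-based position (the
anchor base for InDels). Display rounding is one decimal at or above
0.1 and two below; machine columns keep full precision. Window tracks
tile non-overlapping windows (500 bp default) from position 1, the
last partial window keeping its true span, and hotspot listing
reports windows above the 95th percentile of counts — a convention,
as no published threshold exists for hotspot maps.

## The simulator and what passing tests mean

`simulateGenome()` builds a random circle with the quadripartite
architecture (defaults 83,282 / 17,776 / 2 x 26,212 bp, GC 0.36 —
the dimensions of the *Brassica rapa* reference plastome).
`mutateGenome()` plants region-specific SNVs and InDels; IR mutations
are placed on IRa and mirrored into IRb so the repeat identity is
preserved, and both copies are logged. Default per-accession rates
(SNV 0.003 / 0.004 / 0.0005 per bp, InDel 0.0008 / 0.0008 / 0.0001
for LSC / SSC / IR) follow the empirical ordering SSC > LSC >> IR of
plastome variability; InDel lengths are geometric (p = 0.5) truncated
at 38 bp, reflecting the observed dominance of single-base events
within a 1–38 bp range. Mutations closer than 31 bp to an accepted one
are rejected (and counted), keeping truth/call matching unambiguous.
`simulateReads()` draws 400-bp-insert pairs (sd 40) on the circle —
some fragments span the origin — plus an i.i.d. nuclear background
(1 Mb at 1x by default against 100x chloroplast; the 100:1 ratio is a
design choice, as real ratios are only known to be "very high").
Errors are uniform substitutions at 1%; qualities are constant Q35
with a linear-decay option. Every pair carries an origin label.

The standard study conditions used by the end-to-end tests are the
scaled genome LSC 8,000 / SSC 2,000 / IR 3,000 bp at 100x chloroplast,
1x nuclear, 1% error — small enough that one pipeline run takes well
under a minute, large enough that the IR is two orders of magnitude
longer than k. Peak-recovery checks compare the detected N against the
expected *k-mer* coverage, `C * (L - k + 1)/L * (1 - e)^k` (about 51.3
for C = 100x, L = 100 bp, k = 31, e = 1%): base coverage and k-mer
multiplicity differ by the window and error-survival factors, and
ignoring them would misstate the oracle by about 30%.

The simulator deliberately omits several features of real libraries:
nuclear repeat structure (so baiting specificity against repetitive
nuclear DNA is not exercised), coverage bias along the genome, indexed
adapter remnants, PCR duplicates, and quality-dependent error
patterns. Passing the end-to-end tests therefore demonstrates the
correctness of the algorithms under the stated model, not performance
on any particular sequencing run. Mitochondrial plastid-derived
segments (NUMTs/NUPTs), which can blur the coverage bands in real
data, are likewise not modelled.

## Numerical and design choices

* k = 31 default for spectrum and baiting; the assembler spread is
  31/41/51/63 (all odd, at most 63 by the 2-bit integer encoding,
  and at most the read length).
* Linked-peak ratio tolerance 0.15; minimum peak multiplicity 5;
  smoothing width 5.
* Determinism is a contract: node identities in the de Bruijn graph
  follow sorted k-mer order, all traversals are in that order, and
  identical seeds give byte-identical FASTQ, FASTA and manifest
  checksums.
* Degenerate inputs fail with typed conditions
  (`chlorosmith_invalid_parameter`, `chlorosmith_no_linked_peaks`,
  `chlorosmith_no_ir_found`, `chlorosmith_not_collinear`, ...), so
  callers can distinguish error paths programmatically.
* The variant caller requires collinear genomes by construction; it
  does not call across rearrangements (none are expected within a
  plastome clade; the anchor chain reports an inversion rather than
  calling through it).
* The per-gene variant tabulations of large published cohorts are out
  of scope, as are mapping-based genotype likelihoods; externally
  produced VCFs can be ingested instead of the built-in caller.

## Worked-example arithmetic

The published plastome dimensions and variant counts give a compact
worked example exercised by the test suite and the acceptance script:
the quadripartite sum 83,282 + 17,776 + 2 x 26,212 = 153,482 bp; the
feature partition 87,356 + 12,574 + 53,552 = 153,482 bp; and, through
the density module, 2,646 SNVs over 153,482 bp = 17.2 SNVs per kb,
1,376 intergenic SNVs over 53,552 bp = 25.7 per kb (52.0% of SNV
positions), 464 InDels = 3.0 per kb overall with 0.1 / 4.9 / 7.3 per
kb across exon / intron / intergenic (84.5% intergenic), and
2,646 + 464 = 3,110 variant positions in total.

```{r example, eval = FALSE}
cfg <- makeRunConfig(seed = 1, outDir = "run1")
res <- runPipeline(cfg)
res$equivalence$equivalent   # assembly equals the simulated truth
show(res$peaks)              # fitted N / 2N peak model
variantCalls(res$table)      # calls against the simulated reference
```
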