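---
title: "Resolving interchromosomal insertions from paired-end WGS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving interchromosomal insertions from paired-end WGS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(insjunction)
```

## The event model

The package models a *direct interchromosomal insertion*: a donor segment
of one chromosome, duplicated and inserted between two adjacent bases of an
acceptor chromosome, leaving the donor locus itself intact (so carriers are
trisomic for the donor segment). Junctions formed by replicative repair
(MMBIR/FoSTeS) are not clean seams; the model therefore carries, per event:

- `acceptor_break` — the insertion sits between this base and the next;
- a donor segment with orientation;
- *proximal microhomology*: `k` bases present once at the junction that
  match both the acceptor end and the donor start, making the exact
  breakpoint assignment ambiguous. We report the maximal `k` with
  `suffix_k(acceptor) == prefix_k(donor)`; note this predicate is **not
  nested in `k`** (the aligned base pairs change with `k`), so every `k` is
  tested;
- an optional *micro-insert*: a short fragment from a third locus whose
  first bases may overlap (share sequence with) the donor end — a
  template-switch signature;
- an optional short *fold-back inversion* of the first acceptor bases
  distal to the insertion point;
- optional junction-adjacent SNV and short deletion on the acceptor side.

Because the microhomology bases exist once at the seam, the derivative
haplotype length is

```
acceptor + donor + (micro_insert − overlap) − deletion − microhomology.
```

The *reported* coordinates follow the field's designation convention: the
acceptor break includes the shared bases, and so does the donor start, i.e.
both printed coordinates count the microhomology as their own. The reported
*inserted length* follows the donor-segment designation plus the net
micro-insert minus junction deletions; the haplotype-length bookkeeping
above differs from it by the microhomology term, which is a property of the
physical junction rather than of the designated donor interval.

## What the generator emulates, and what it does not

`build_reference()` makes uniform-random contigs whose `offset` fields put
mini-contigs on genome-scale coordinates. The preset `"cmtx3"` (200 kb
acceptor, 200 kb donor, 5 kb third contig) plants the full published-style
architecture, including a 180 bp palindrome (88 bp arms, TATC loop)
spanning the insertion point, because hairpin-prone palindromes are the
recurrent-breakage context of interest.

`build_mutant_haplotype()` *harmonizes* the reference so planted homologies
are real: the donor start is rewritten to equal the acceptor end
(microhomology) and the micro-insert source start to equal the donor end
(overlap). It additionally writes *guard bases* immediately flanking every
planted boundary so each planted length is **exactly maximal**. Without
guards, a random genome extends a planted homology with probability ~1/4
per boundary, and exact parameter recovery would fail by construction on a
quarter of simulations — that is a property of random sequence, not of any
algorithm. The guards are part of the generator's contract: "the planted
length is the maximal one".

Reads are error-free by default (an optional uniform substitution rate
exists but is off), fragments are normal with mean 350 bp and sd 35 bp —
chosen so that twice the library mean equals the canonical 700 bp
discordance threshold — and truth records accompany every read. Passing
tests on these simulations therefore demonstrates correctness of the
*logic* (detection, clustering, segmentation, arithmetic), not robustness
to sequencing error, repeats, GC bias, or mapping ambiguity in real
genomes; the internal exact-seed mapper likewise assumes error-free reads.

## Detection parameters

| parameter | default | meaning |
|---|---|---|
| `insert_threshold` | 700 bp | discordant if implied insert strictly exceeds this (2x library mean) |
| `window_size` | 200 bp | discordant clustering window; step is half a window |
| `min_support` | 3 pairs | minimum discordant support per window |
| `max_low_mapq_frac` | 0.5 | windows with more low-MAPQ records are excluded |
| `min_mapq` | 20 | "high quality" read threshold (both mates) |
| `min_clip` | 20 bp | smallest soft clip considered split-read evidence |
| `min_match` | 10 bp | smallest attributable junction fragment |

"High quality read pairs" has no universal definition; we use both mates
primary, non-duplicate, MAPQ >= 20, all configurable. A clipped
subsequence that maps uniquely to another contig (or > 1 kb away) carries a
clip locus; a clip that maps *nowhere* — typical when the clip itself
crosses a complex junction and is chimeric — is still evidence ("did not
map locally"), with an unknown clip locus. On error-free wild-type
simulations both evidence classes are exactly empty, which the test suite
asserts.

## Junction resolution: anchored, not purely greedy

Per breakpoint, supporting reads are stacked on the column scale given by
their anchored alignments and majority-voted into a consensus (ties on more
than 10% of columns flag the consensus low-confidence). The consensus is
segmented against the reference by a greedy longest-exact-match walk
(either strand, ties broken by contig order, then leftmost locus, then plus
strand), with two deliberate deviations from a textbook greedy scan:

1. **The acceptor side is taken from the anchors, not from search.** The
   split reads' aligned portions pin the acceptor coordinate of the
   junction exactly. This matters because breakpoints in palindromes have a
   minus-strand *ghost*: the acceptor tail also matches the reference
   reverse strand via the inverted repeat, and the ghost can outscore the
   true match (it even absorbs a junction deletion, because the image
   coordinates slide smoothly through it). Anchor-driven resolution is
   immune to this; we observed the ghost beating the true segment on the
   packaged preset before making this choice.
2. **The segmentation seed adapts to reference size.** The smallest
   junction feature of interest is 10 bp, but a 10-mer has ~0.76 expected
   chance occurrences across 2x405 kb of reference; seeds are therefore
   lengthened until the expected number of chance hits across the reference
   is below 1/200 (14 for the preset). Features shorter than the seed are
   recovered by the dedicated string analyses below, so nothing 10 bp-scale
   is lost.

The junction interval between the donor segment's maximal extension and the
acceptor anchor is then analyzed directly: the *fold-back test* finds the
maximal gap suffix equal to the reverse complement of the acceptor bases
immediately before the anchor (inversions of any length, including below
the seed); the remaining gap goes to micro-insert attribution, which
searches the gap extended leftward into the donor end (largest extension
with an exact hit wins, giving both fragment length and donor overlap;
no hit at all is reported as unknown origin, keeping the length). Junction
variants are called by Needleman-Wunsch alignment
(`Biostrings::pairwiseAlignment`, match 2 / mismatch -3 / gap open 5 /
extend 2) of the 50 bp acceptor-side window against the reference —
exact-match segmentation alone would fragment around variants.

Microhomology is reported under the left-assignment designation described
above; where the paper-style designation is ambiguous the ambiguity flag on
segments records equally long alternatives.

## Depth and copy gain

Depth counts aligned reference-consuming bases (CIGAR M/=/X), not read
starts, over 1 kb windows by default (configurable; summaries are over
windows, so the reported SD is per-window SD). The copy-gain call compares
the insert-region mean to the mean of flank means; the expected fold under
one extra copy on an autosomal background is 1.5, and the default call
threshold 1.35 sits between no-gain (1.0) and that expectation, leaving
slack for sampling noise. No GC or mappability correction is attempted.

## Genotyping assay

Primer sites are solved from the three target product sizes (wild-type
340 bp spanning the insertion point; junction-crossing 595 bp and 235 bp)
rather than from fixed genomic coordinates — on a synthetic genome the
published primer sequences have no homologs, but the assay *logic* is fully
determined by the sizes. Placement is verified by in-silico PCR
(solve-then-verify); amplicons are labelled by product size exactly as a
gel lane is read, and genotype calls are a pure function of sex and the
span set (single wild-type product: non-carrier; both junction products in
a male: affected hemizygous; all three in a female: carrier). Primer
binding is exact-match with products capped at 2 kb; mismatch-tolerant
binding and thermodynamics are out of scope. The insert must exceed the
product cap for the wild-type pair to drop out on the mutant haplotype —
true by five orders of magnitude in the modelled event, and respected by
the test fixtures.

## Comparative Ct

Technical replicates are averaged first; each extraction yields
`dCt = Ct(target) − Ct(housekeeping)`; the calibrator's mean dCt is
subtracted and `fold = 2^(−ddCt)` with amplification efficiency fixed at 2.
The calibrator's own fold is exactly 1 by construction. Spread and the
t-test against the calibrator are computed on extraction-level folds (the
aggregation order and the choice of testing folds rather than dCt values
are package conventions; a Welch test is available by flag). A gene whose
wells are all undetermined is "not detected" — never fold 0 or infinity;
extractions mixing undetermined and numeric wells are dropped with a
warning.

## Problem sizes and numerical conventions

All coordinates are 1-based inclusive; 0-based half-open appears only at
BED-style export. Seeds are mandatory everywhere randomness exists, and a
run's randomness flows through one generator. The packaged preset runs at
40x over the ~278 kb derivative haplotype (~55k read pairs, well under a
minute end to end); the randomized-recovery property suite uses 6 kb / 3 kb
/ 0.8 kb mini-genomes at 40x, 100 replicates, which keeps the whole test
suite in the minutes range while preserving every junction feature at full
scale (feature sizes are absolute, not proportional to contig length).

## Known limitations

Exact-match clip remapping and primer binding assume error-free data; real
WGS requires mismatch-tolerant alignment throughout. Junctions embedded in
long repeats, donor segments shorter than the read length, and events whose
two junctions fall within one fragment length of each other are outside the
tested envelope. The discordant-cluster peak is a read-end mode, a proxy
with window-scale (not base-scale) resolution — base resolution comes only
from split reads.
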