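# insjunction

Detection and base-resolution characterization of large interchromosomal
insertions from paired-end whole-genome sequencing, with in-silico multiplex
PCR genotyping, X-linked segregation analysis and comparative-Ct expression
analysis.

## The problem

A class of Mendelian disease is caused not by coding point mutations but by
large structural variants: tens of kilobases of one chromosome duplicated
and inserted into another. The canonical example implemented here is an
X-linked peripheral neuropathy caused by a ~78 kb segment of chromosome
8q24.3 inserted into an intergenic region of Xq27.1. Such events leave three
sequencing signatures that this package detects and integrates:

- **split reads** — reads crossing a breakpoint align partly at the
  insertion site, with the soft-clipped remainder deriving from the donor
  chromosome ("one half of the read maps, the second half does not map
  locally");
- **discordant read pairs** — mates mapping to different chromosomes, or at
  an implied insert size beyond twice the library mean (default threshold
  700 bp), clustered in 200 bp windows to a local-maximum rearrangement
  position;
- **depth of coverage (DOC)** — the donor region is present in three copies
  instead of two, an expected 1.5-fold depth gain
  (`fold = insert mean / flank mean`).

Junctions repaired by microhomology-mediated break-induced replication
(MMBIR/FoSTeS) are complex, and the junction resolver recovers that
micro-architecture at base resolution: the microhomology shared by acceptor
and donor at the seam (maximal k with
`suffix_k(acceptor) == prefix_k(donor)`), short template-switch
micro-inserts from third chromosomes (including their overlap with the donor
end), short fold-back inversions of acceptor sequence, junction-adjacent
SNVs and deletions, and the palindrome/hairpin context of the breakpoint
(maximal inverted repeat containing it). Calls are emitted as VCF 4.2
breakends plus a derivative-chromosome notation string such as
`der(X)dir ins(X;8)(q27.1;q24.3)`.

Because no patient genomes are available, the package ships a first-class
synthetic-data generator: mini-contigs with coordinate offsets (so a 200 kb
contig carries hg19-scale positions), a derivative-haplotype builder that
plants any junction specification, an error-free paired-end read simulator
with truth records, a truth-projection aligner (plus a light exact-seed
mapper for raw FASTQ), X-linked cohort and pedigree generators, and
comparative-Ct (delta-delta-Ct) plate simulators. The packaged preset
`"cmtx3"` plants the published geometry: acceptor break at
chrX-style 139,502,948, donor start 145,768,312, insert length 77,856 bp,
2 bp microhomology (`AA`), a 19 bp chromosome-12 micro-insert whose first
10 bp overlap the donor end, a 12 bp inversion, a junction SNV (T>G at
139,502,968), a 1 bp deletion (139,502,976), and a 180 bp breakpoint
palindrome with a TATC hairpin loop.

## Worked example

```r
library(insjunction)

refs <- build_reference("cmtx3", seed = 1)
mut  <- build_mutant_haplotype(refs, cmtx3_spec())
refs <- mut$reference                       # homology-harmonized reference
sim  <- simulate_reads(list(mut), coverage = 40, seed = 2)
rec  <- project_alignments(sim, refs)
call <- resolve_insertion(rec, refs)
call
#> <insertion_call: 77,864 bp of chr8_mini:145,768,312-145,846,167 inserted
#>  at chrX_mini:139,502,948-139,502,949>
#>   microhomology 2 bp (AA); micro-insert 19 bp (overlap 10); inversion 12 bp
call$variants[, c("type", "ref", "alt", "coord")]
#>   type ref alt     coord
#> 1  snv   T   G 139502968
#> 2  del   T     139502976
```

The printed call says: a 77,856 bp donor segment (plus the 9 net micro-insert
bases, minus the 1 bp deletion) sits between acceptor positions 139,502,948
and 139,502,949; the junction carries the planted MMBIR signature. The
genotyping assay is then solved from the published product sizes and read
like a gel:

```r
assay <- place_assay(call, refs,
                     size_spec = c(wild_type = 340, proximal_junction = 595,
                                   distal_junction = 235))
insilico_pcr(list(assay$wild, assay$mutant), assay$primers)$length
#> [1] 340 595 235       # a carrier female's three products
```

A command-line front end for simulate/detect/resolve/qpcr lives at
`inst/scripts/insjunction`.

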