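Package: insjunction
Title: Detection and Base-Resolution Characterization of Interchromosomal
    Insertions from Paired-End Whole-Genome Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested re-implementation of a whole-genome-sequencing pipeline
    for large interchromosomal insertions: discordant read-pair and split-read
    structural-variant detection with windowed local-maximum clustering,
    depth-of-coverage copy-gain quantification, base-resolution breakpoint
    junction resolution (microhomology, micro-inserts, inversions, junction
    variants, palindrome/hairpin context), in-silico multiplex PCR genotyping
    with X-linked segregation analysis, and comparative-Ct (delta-delta-Ct)
    expression analysis. Ships a synthetic-data generator that plants a
    configurable insertion geometry - including a preset reproducing the
    junction micro-architecture of the CMTX3 78 kb chr8-into-chrX insertion -
    with paired-end reads, truth alignments, pedigrees and Ct tables, so the
    whole pipeline is exercised end-to-end without access to patient genomes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
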