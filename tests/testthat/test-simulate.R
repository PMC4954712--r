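test_that("read simulation validates parameters and emits 101 bp mates", {
  refs <- mini_reference(7, acc_len = 3000L)
  expect_error(simulate_reads(list(refs$accA), coverage = 0, seed = 1),
               "coverage")
  expect_error(simulate_reads(list(refs$accA), coverage = 10, read_len = 101,
                              insert_mean = 150, seed = 1), "insert_mean")
  sim <- simulate_reads(list(refs$accA), coverage = 5, seed = 1)
  expect_true(all(nchar(sim$r1) == 101))
  expect_true(all(nchar(sim$r2) == 101))
  ## forward-reverse orientation: mate 2 is the reverse complement of the
  ## fragment end
  i <- 1
  frag_end <- sim$pairs$start[i] + sim$pairs$frag_len[i] - 1
  expect_equal(sim$r2[i],
               revcomp(substr(refs$accA$sequence, frag_end - 100, frag_end)))
})

test_that("realized depth stays within 10% of target on a 100 kb contig", {
  refs <- build_reference(list(contigs = list(
    list(name = "big", length = 100000, offset = 0))), seed = 11)
  sim <- simulate_reads(list(refs$big), coverage = 30, seed = 7)
  cov <- oracle_depth(sim, "big", 1, refs$big$length)
  expect_gte(mean(cov), 27)
  expect_lte(mean(cov), 33)
})

test_that("FASTQ output is byte-identical for a fixed seed and parseable", {
  refs <- mini_reference(9, acc_len = 2000L)
  d <- withr::local_tempdir()
  s1 <- simulate_reads(list(refs$accA), coverage = 3, seed = 5)
  s2 <- simulate_reads(list(refs$accA), coverage = 3, seed = 5)
  f1 <- write_fastq(s1, file.path(d, "a"))
  f2 <- write_fastq(s2, file.path(d, "b"))
  expect_identical(readLines(f1[1]), readLines(f2[1]))
  expect_identical(readLines(f1[2]), readLines(f2[2]))
  fq <- read_fastq(f1[1])
  expect_equal(nrow(fq), nrow(s1$pairs))
  expect_equal(fq$seq, s1$r1)
  ## standard reader parses it too
  bs <- Biostrings::readDNAStringSet(f1[1], format = "fastq")
  expect_equal(length(bs), nrow(s1$pairs))
})

test_that("projected alignments match exhaustive substring search", {
  refs <- mini_reference(13, acc_len = 4000L, don_len = 2500L)
  spec <- random_mini_spec(refs, 77)
  mut <- build_mutant_haplotype(refs, spec)
  sim <- simulate_reads(list(mut), coverage = 6, seed = 3)
  rec <- project_alignments(sim, mut$reference)
  expect_s3_class(rec, "aln_frame")
  ## every full-match record's sequence occurs verbatim at its coordinate
  full <- rec[rec$cigar == "101M" & !aln_is_supplementary(rec), ]
  full <- full[sample.int(nrow(full), min(nrow(full), 50)), ]
  for (i in seq_len(nrow(full))) {
    ctg <- mut$reference[[full$contig[i]]]
    sq <- if (aln_is_reverse(full[i, ])) full$seq[i] else full$seq[i]
    expect_equal(substr(ctg$sequence, full$pos[i], full$pos[i] + 100), sq)
  }
  ## clipped primaries: every aligned M block matches the reference verbatim
  ## at its stated coordinate (D operations split the blocks)
  clipped <- rec[grepl("S", rec$cigar) & !aln_is_supplementary(rec), ]
  for (i in seq_len(min(nrow(clipped), 30))) {
    r <- clipped[i, ]
    p <- insjunction:::cigar_parse(r$cigar)[[1]]
    qpos <- 1L; rpos <- r$pos
    ctg <- mut$reference[[r$contig]]
    snv_local <- if (is.null(spec$junction_snv)) -1 else
      spec$junction_snv$pos - mut$reference$accA$offset
    for (j in seq_along(p$op)) {
      if (p$op[j] == "M") {
        blk <- strsplit(substr(r$seq, qpos, qpos + p$len[j] - 1L), "")[[1]]
        ref <- strsplit(substr(ctg$sequence, rpos, rpos + p$len[j] - 1L),
                        "")[[1]]
        mm <- which(blk != ref)
        ## an M block may mismatch only at the planted junction SNV
        expect_true(all((rpos + mm - 1L) == snv_local))
        qpos <- qpos + p$len[j]; rpos <- rpos + p$len[j]
      } else if (p$op[j] == "S") qpos <- qpos + p$len[j]
      else if (p$op[j] == "D") rpos <- rpos + p$len[j]
    }
  }
})

test_that("a junction-spanning read yields soft-clipped primary plus supplementary", {
  ## deterministic two-contig junction: 40 acceptor + 61 donor bases
  refs <- build_reference(list(contigs = list(
    list(name = "acc", length = 2000, offset = 0),
    list(name = "don", length = 2000, offset = 0))), seed = 21)
  spec <- junction_spec("acc", 1000, "don", genomic_interval("don", 501, 1400))
  mut <- build_mutant_haplotype(refs, spec)
  refs2 <- mut$reference
  ## a read covering haplotype positions 961..1061: 40 on acceptor, 61 donor
  sim <- structure(list(
    pairs = data.frame(qname = "jx", hap = "h", start = 961,
                       frag_len = 300),
    r1 = substr(mut$haplotype$sequence, 961, 1061),
    r2 = revcomp(substr(mut$haplotype$sequence, 1160, 1260)),
    read_len = 101L,
    haplotypes = list(h = list(contig = mut$haplotype, truth = mut$truth))),
    class = "sim_reads")
  rec <- project_alignments(sim, refs2)
  r1 <- rec[rec$mate == 1, ]
  prim <- r1[!aln_is_supplementary(r1), ]
  supp <- r1[aln_is_supplementary(r1), ]
  expect_equal(prim$contig, "don")            # 61 bases is the longer piece
  expect_equal(prim$cigar, "40S61M")
  expect_equal(supp$contig, "acc")
  expect_equal(supp$cigar, "40M61S")
  expect_equal(supp$pos, 961)
  expect_equal(prim$pos, 501)
  ## mate fields of a straddling pair name different contigs
  expect_equal(unique(r1$mate_contig), "don")
})

test_that("SAM round-trips through our writer/reader and a standard parser", {
  refs <- mini_reference(31, acc_len = 2000L)
  sim <- simulate_reads(list(refs$accA, refs$donB), coverage = 2, seed = 9)
  rec <- project_alignments(sim, refs)
  d <- withr::local_tempdir()
  sam <- file.path(d, "x.sam")
  write_alignments(rec, sam, refs)
  back <- read_alignments(sam, filter_policy(0, FALSE, FALSE, TRUE))
  expect_equal(nrow(back), nrow(rec))
  expect_equal(back$qname, rec$qname)
  expect_equal(back$pos, rec$pos)
  expect_equal(back$cigar, rec$cigar)
  expect_equal(back$seq, rec$seq)
  expect_equal(back$flag, rec$flag)
  ## independent format oracle: samtools-compatible conversion to BAM
  bam <- suppressWarnings(Rsamtools::asBam(sam, file.path(d, "x"),
                                           overwrite = TRUE))
  back2 <- read_alignments(bam, filter_policy(0, FALSE, FALSE, TRUE))
  expect_equal(nrow(back2), nrow(rec))
  expect_setequal(back2$qname, rec$qname)
})
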