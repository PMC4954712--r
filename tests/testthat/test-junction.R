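test_that("consensus assembly reproduces identical overlapping reads", {
  sq <- paste(sample(c("A", "C", "G", "T"), 101, TRUE), collapse = "")
  recs <- alignment_frame(data.frame(
    qname = c("a", "b", "c"), flag = 0L, contig = "acc", pos = 500,
    mapq = 60L, cigar = "60M41S", seq = sq, stringsAsFactors = FALSE))
  splits <- data.frame(qname = c("a", "b", "c"), contig = "acc",
                       breakpoint_pos = 559, side = "proximal")
  cons <- assemble_junction(splits, recs)
  expect_equal(cons$consensus, sq)
  expect_equal(cons$col1_ref, 500)
  expect_false(cons$low_confidence)
  expect_error(assemble_junction(splits[1, , drop = FALSE], recs),
               "supporting reads")
})

test_that("microhomology equals the exhaustive maximal-overlap scan", {
  ## the canonical worked case: acceptor ...GCAA | donor AAGT...
  refs <- contig_set(
    contig("acc", paste0(strrep("C", 20), "GCAA", strrep("T", 20)), 0),
    contig("don", paste0(strrep("G", 20), "AAGT", strrep("C", 20)), 0))
  left <- data.frame(contig = "acc", ref_start = 1, ref_end = 24,
                     strand = "+")
  right <- data.frame(contig = "don", ref_start = 21, ref_end = 44,
                      strand = "+")
  uh <- call_microhomology(left, right, refs)
  expect_equal(uh$length, 2)
  expect_equal(uh$sequence, "AA")
  ## no shared boundary bases
  right0 <- data.frame(contig = "don", ref_start = 23, ref_end = 40,
                       strand = "+")
  expect_equal(call_microhomology(left, right0, refs)$length, 0)

  ## randomized boundary pairs against the brute-force scan
  set.seed(9)
  for (i in 1:40) {
    a <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
    d <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
    k <- sample(0:5, 1)
    if (k > 0) substr(d, 1, k) <- substr(a, 30 - k + 1, 30)
    refs2 <- contig_set(contig("acc", a, 0), contig("don", d, 0))
    l2 <- data.frame(contig = "acc", ref_start = 1, ref_end = 30, strand = "+")
    r2 <- data.frame(contig = "don", ref_start = 1, ref_end = 30, strand = "+")
    expect_equal(call_microhomology(l2, r2, refs2)$length,
                 oracle_overlap(a, d))
  }
})

test_that("microhomology length is symmetric under role swap", {
  set.seed(11)
  for (i in 1:10) {
    a <- paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")
    refs <- contig_set(contig("x", a, 0),
                       contig("y", revcomp(a), 0))
    ## swapping acceptor/donor roles across the same physical junction:
    ## x(+) end-to-start y(+) vs y(-) ... x(-) report the same overlap
    l <- data.frame(contig = "x", ref_start = 1, ref_end = 40, strand = "+")
    r <- data.frame(contig = "y", ref_start = 1, ref_end = 40, strand = "+")
    lr <- call_microhomology(l, r, refs)$length
    l2 <- data.frame(contig = "y", ref_start = 1, ref_end = 40, strand = "-")
    r2 <- data.frame(contig = "x", ref_start = 1, ref_end = 40, strand = "-")
    rl <- call_microhomology(l2, r2, refs)$length
    expect_equal(lr, rl)
  }
})

test_that("micro-insert attribution recovers source, length and overlap", {
  refs <- mini_reference(201)
  mut <- build_mutant_haplotype(refs, cmtx3_like_spec(refs))
  spec <- mut$truth$spec
  thr <- mut$reference$thrC
  don <- mut$reference$donB
  mi_s <- spec$micro_insert$source$start - thr$offset
  gap <- contig_sub(thr, mi_s + 10, mi_s + 18)            # unshared 9 bp
  de <- spec$donor_segment$end - don$offset
  ctx <- contig_sub(don, de - 29, de)
  got <- detect_micro_insert(gap, mut$reference, min_hit = 10,
                             left_context = ctx)
  expect_equal(got$source_contig, "thrC")
  expect_equal(got$length, 19)
  expect_equal(got$overlap_with_donor, 10)

  ## a random 19-mer absent from the references is unknown origin
  set.seed(3)
  repeat {
    alien <- paste(sample(c("A", "C", "G", "T"), 19, TRUE), collapse = "")
    if (!nrow(insjunction:::search_exact(alien, refs))) break
  }
  un <- detect_micro_insert(alien, refs, min_hit = 10)
  expect_true(is.na(un$source_contig))
  expect_equal(un$length, 19)

  ## a fragment present on both strands of one contig is ambiguous
  pal <- "ACGTGCATTAAT"
  palrc <- revcomp(pal)
  refs3 <- contig_set(contig("p", paste0(strrep("C", 30), pal, strrep("G", 30),
                                         palrc, strrep("T", 30)), 0))
  amb <- detect_micro_insert(pal, refs3, min_hit = 10)
  expect_true(amb$ambiguous)
  expect_equal(nrow(amb$loci), 2)
})

test_that("fold-back inversion detection is exact for planted lengths", {
  set.seed(13)
  for (inv in c(0, 1, 5, 12, 30)) {
    acc <- contig("acc", paste(sample(c("A", "C", "G", "T"), 400, TRUE),
                               collapse = ""), 0)
    a1 <- 201
    invseq <- if (inv > 0) revcomp(contig_sub(acc, a1 - inv, a1 - 1)) else ""
    filler <- paste(sample(c("A", "C", "G", "T"), 8, TRUE), collapse = "")
    gap <- paste0(filler, invseq)
    got <- detect_inversion(gap, acc, a1)
    if (inv == 0) {
      ## chance fold-backs of length >= 1 are possible but must be < 3
      expect_lte(got$length, 2)
    } else if (substr(filler, 8, 8) != comp_base_one(contig_sub(acc, a1 - inv - 1,
                                                                a1 - inv - 1))) {
      expect_equal(got$length, inv)
      expect_equal(got$ref_start, a1 - inv)
    }
  }
  expect_equal(detect_inversion("", contig("a", "ACGT", 0), 3)$length, 0)
})

test_that("junction variant calling equals the planted edits", {
  refs <- mini_reference(301)
  acc <- refs$accA
  win <- contig_sub(acc, 1000, 1049)
  ## consensus equal to reference -> empty
  expect_equal(nrow(call_junction_variants(win, 1, acc, 1000)), 0)
  ## randomized single-edit fixtures against edit reconstruction
  set.seed(31)
  for (i in 1:20) {
    type <- sample(c("snv", "del"), 1)
    pos <- sample(10:40, 1)
    ch <- strsplit(win, "")[[1]]
    if (type == "snv") {
      old <- ch[pos]
      ch[pos] <- setdiff(c("A", "C", "G", "T"), old)[1]
      mutwin <- paste(ch, collapse = "")
      v <- call_junction_variants(mutwin, 1, acc, 1000, window = 50)
      v <- v[v$type == "snv", ]
      expect_equal(nrow(v), 1)
      expect_equal(v$ref_pos, 1000 + pos - 1)
      expect_equal(v$ref, old)
      expect_equal(v$alt, ch[pos])
    } else {
      if (ch[pos] == ch[pos + 1]) next    # skip ambiguous homopolymer gaps
      mutwin <- paste(ch[-pos], collapse = "")
      v <- call_junction_variants(mutwin, 1, acc, 1000, window = 49)
      v <- v[v$type == "del", ]
      expect_equal(nrow(v), 1)
      expect_equal(v$len, 1)
      expect_lte(abs(v$ref_pos - (1000 + pos - 1)), 1)
    }
  }
})

test_that("palindrome annotation matches the O(n^2) oracle", {
  ## constructed 180 bp palindrome with central TATC, breakpoint at center
  set.seed(17)
  arm <- paste(sample(c("A", "C", "G", "T"), 88, TRUE), collapse = "")
  pal <- paste0(arm, "TATC", revcomp(arm))
  seqstr <- paste0(strrep("C", 60), pal, strrep("A", 60))
  bp <- 60 + 88 + 2                       # inside the loop
  ann <- annotate_palindrome(seqstr, bp)
  expect_equal(ann$arm_length, 88)
  expect_equal(ann$loop, "TATC")
  expect_equal(ann$end - ann$start + 1, 180)
  expect_equal(ann$breakpoint_distance, bp - ann$center)
  expect_lte(abs(ann$breakpoint_distance), 2)

  ## random sequence: no qualifying palindrome
  rnd <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  expect_null(annotate_palindrome(rnd, 150))

  ## randomized planted arms against the quadratic oracle
  for (i in 1:8) {
    a <- sample(20:60, 1)
    armX <- paste(sample(c("A", "C", "G", "T"), a, TRUE), collapse = "")
    loop <- paste(sample(c("A", "C", "G", "T"), sample(0:6, 1), TRUE),
                  collapse = "")
    s <- paste0(paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = ""),
                armX, loop, revcomp(armX),
                paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = ""))
    bp2 <- 40 + a + 1
    got <- annotate_palindrome(s, bp2, min_arm = 20)
    want <- oracle_palindrome(s, bp2, min_arm = 20)
    expect_equal(if (is.null(got)) 0L else got$arm_length, want)
  }
})
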