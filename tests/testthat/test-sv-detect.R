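test_that("discordant pair detection applies both criteria strictly", {
  sq <- strrep("A", 50)
  mk <- function(qn, c1, p1, c2, p2) {
    alignment_frame(data.frame(
      qname = qn, mate = 1:2, flag = c(65L, 129L), contig = c(c1, c2),
      pos = c(p1, p2), mapq = 60L, cigar = "50M", seq = sq,
      mate_contig = c(c2, c1), mate_pos = c(p2, p1), isize = 0L))
  }
  inter <- mk("q1", "X_mini", 100, "8_mini", 900)
  dp <- find_discordant_pairs(inter)
  expect_equal(dp$reason, "inter_chromosomal")
  ## span exactly 700 is NOT discordant (strictly greater than)
  exact <- mk("q2", "c1", 100, "c1", 750)        # span = 750+49-100+1 = 700
  expect_equal(nrow(find_discordant_pairs(exact)), 0)
  over <- mk("q3", "c1", 100, "c1", 751)         # span 701
  expect_equal(find_discordant_pairs(over)$reason, "long_insert")
  expect_equal(find_discordant_pairs(over)$insert_size, 701)
})

test_that("discordant detection equals the brute-force predicate on random pairs", {
  for (s in 1:5) {
    rec <- random_pair_records(s, n = 200L)
    got <- find_discordant_pairs(rec, filter_policy(), 700)
    m1 <- rec[rec$mate == 1L, ]; m2 <- rec[rec$mate == 2L, ]
    span <- pmax(m1$pos, m2$pos) + 49 - pmin(m1$pos, m2$pos) + 1
    want <- m1$qname[m1$contig != m2$contig | span > 700]
    expect_setequal(got$qname, want)
    expect_true(!anyDuplicated(got$qname))
  }
})

test_that("discordant clustering finds the local-maximum position", {
  set.seed(5)
  pairs <- data.frame(
    qname = sprintf("q%02d", 1:10),
    contig_a = "acc", pos_a = c(1000, 1005, 1010, 1010, 1018, 1020,
                                1025, 1030, 1035, 1040),
    contig_b = "don", pos_b = sample(5000:9000, 10),
    reason = "inter_chromosomal", insert_size = NA_real_)
  cl <- cluster_discordant(pairs, window_size = 200, min_support = 3)
  acc_cl <- cl[cl$contig == "acc", ]
  expect_equal(nrow(acc_cl), 1)
  expect_gte(acc_cl$peak_pos, 1000)
  expect_lte(acc_cl$peak_pos, 1040)
  expect_equal(acc_cl$support, 10)
  ## per-base oracle: peak is the most frequent end position (mode 1010)
  expect_equal(acc_cl$peak_pos, 1010)

  expect_equal(nrow(cluster_discordant(pairs[1:2, ], min_support = 3)), 0)
  ## exclusion regions drop intersecting clusters
  excl <- data.frame(contig = "acc", start = 900, end = 1100)
  cl2 <- cluster_discordant(pairs, window_size = 200, min_support = 3,
                            exclusion = excl)
  expect_equal(nrow(cl2[cl2$contig == "acc", ]), 0)
})

test_that("poor-alignment windows are fraction-thresholded and mergeable", {
  mk <- function(pos, mapq) alignment_frame(data.frame(
    qname = sprintf("r%03d", seq_along(pos)), flag = 0L, contig = "c1",
    pos = pos, mapq = mapq, cigar = "50M", seq = strrep("A", 50)))
  good <- mk(seq(1, 2000, by = 20), 60L)
  expect_equal(nrow(poor_alignment_regions(good)), 0)
  ## one window with 6/10 low-mapq records at threshold 0.5
  rec <- mk(c(seq(10, 190, by = 20), seq(300, 390, by = 10)),
            c(rep(0L, 6), rep(60L, 4), rep(60L, 10)))
  bad <- poor_alignment_regions(rec, window_size = 200,
                                max_low_mapq_frac = 0.5)
  expect_equal(nrow(bad), 1)
  expect_equal(c(bad$start, bad$end), c(1, 200))
  ## threshold 1.0 can never be strictly exceeded
  allbad <- mk(seq(10, 190, by = 20), 0L)
  expect_equal(nrow(poor_alignment_regions(allbad, max_low_mapq_frac = 1)), 0)
})

test_that("split reads anchor the planted junction and classify mate anchors", {
  run <- run_mini_pipeline(101, coverage = 30)
  recs <- apply_policy(run$rec, filter_policy())
  sp <- find_split_reads(recs, run$refs)
  acc <- run$refs$accA
  b <- run$spec$acceptor_break - acc$offset
  prox <- sp[sp$contig == "accA" & sp$side == "proximal", ]
  expect_gt(nrow(prox), 1)
  tab <- table(prox$breakpoint_pos)
  expect_equal(as.numeric(names(tab))[which.max(tab)], b)
  ## proximal clips remap onto the donor contig
  expect_true(any(prox$clipped_contig == "donB", na.rm = TRUE))
  expect_setequal(intersect(unique(prox$mate_contig), c("accA", "donB")),
                  unique(prox$mate_contig))
  ## full-match records yield no evidence
  full <- recs[recs$cigar == "101M", ][1:50, ]
  expect_equal(nrow(find_split_reads(full, run$refs)), 0)
})

test_that("evidence summary tallies splits per class and matches direct counts", {
  expect_equal(nrow(summarize_evidence(
    data.frame(contig = character(0), side = character(0),
               breakpoint_pos = numeric(0), mate_contig = character(0)),
    data.frame(contig = character(0), start = numeric(0), end = numeric(0),
               partner_contig = character(0), support = integer(0),
               peak_pos = numeric(0)))), 0)
  splits <- data.frame(
    contig = "acc", side = "proximal", breakpoint_pos = 1000,
    mate_contig = c(rep("acc", 7), rep("don", 3)))
  cl <- data.frame(contig = character(0), start = numeric(0),
                   end = numeric(0), partner_contig = character(0),
                   support = integer(0), peak_pos = numeric(0))
  summ <- summarize_evidence(splits, cl)
  expect_equal(summ$count[summ$class == "split_mate_acc"], 7)
  expect_equal(summ$count[summ$class == "split_mate_don"], 3)
})

test_that("wild-type simulations produce zero SV evidence", {
  refs <- mini_reference(55, acc_len = 20000L, don_len = 8000L)
  sim <- simulate_reads(list(refs$accA, refs$donB), coverage = 40, seed = 56)
  rec <- project_alignments(sim, refs)
  recs <- apply_policy(rec, filter_policy())
  expect_equal(nrow(find_split_reads(recs, refs)), 0)
  expect_equal(nrow(find_discordant_pairs(rec)), 0)
  expect_null(resolve_insertion(rec, refs))
})

test_that("detection output is invariant to record order", {
  run <- run_mini_pipeline(61, coverage = 25)
  recs <- apply_policy(run$rec, filter_policy())
  shuf <- recs[sample.int(nrow(recs)), ]
  s1 <- find_split_reads(recs, run$refs)
  s2 <- find_split_reads(shuf, run$refs)
  o <- function(x) x[order(x$qname, x$clip_side), ]
  expect_equal(o(s1)[, c("qname", "breakpoint_pos", "side")],
               o(s2)[, c("qname", "breakpoint_pos", "side")],
               ignore_attr = TRUE)
})

test_that("BED export converts to 0-based half-open coordinates", {
  cl <- data.frame(contig = "acc", start = 1001, end = 1200,
                   partner_contig = "don", support = 7L, peak_pos = 1100)
  d <- withr::local_tempdir()
  p <- write_bed(cl, file.path(d, "cl.bed"))
  f <- strsplit(readLines(p), "\t")[[1]]
  expect_equal(f[1:3], c("acc", "1000", "1200"))
  expect_equal(f[5], "7")
})
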