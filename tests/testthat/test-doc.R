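test_that("windowed depth handles empty input and single reads exactly", {
  iv <- genomic_interval("c1", 1, 5000)
  empty <- alignment_frame(data.frame(
    qname = character(0), flag = integer(0), contig = character(0),
    pos = numeric(0), mapq = integer(0), cigar = character(0),
    seq = character(0)))
  prof <- windowed_depth(empty, iv, 1000)
  expect_true(all(prof$windows$depth == 0))
  ## one 101 bp read fully inside a 1 kb window -> depth 0.101
  one <- alignment_frame(data.frame(
    qname = "r", flag = 0L, contig = "c1", pos = 200, mapq = 60L,
    cigar = "101M", seq = strrep("A", 101)))
  prof <- windowed_depth(one, iv, 1000)
  expect_equal(prof$windows$depth[1], 101 / 1000)
  expect_equal(sum(prof$windows$depth * 1000), 101)  # aligned-base mass
})

test_that("region summaries equal hand arithmetic and a per-base oracle", {
  prof <- structure(list(
    contig = "c1", window_size = 1000L,
    windows = data.frame(start = c(1, 1001, 2001),
                         end = c(1000, 2000, 3000),
                         depth = c(60, 62, 58)),
    mean_depth = 60), class = "depth_profile")
  rs <- region_summary(prof, list(all = genomic_interval("c1", 1, 3000)))
  expect_equal(rs$mean, 60)
  expect_equal(rs$sd, 2)
  expect_error(region_summary(prof, list(e = genomic_interval("c1", 3500, 4000))),
               "no profiled windows")

  ## per-base oracle on a small simulated instance
  refs <- mini_reference(71, acc_len = 20000L)
  sim <- simulate_reads(list(refs$accA), coverage = 12, seed = 71)
  rec <- project_alignments(sim, refs)
  iv <- genomic_interval("accA", 2001, 18000)
  prof2 <- windowed_depth(rec[rec$contig == "accA", ], iv, 500)
  cov <- oracle_depth(sim, "accA", 2001, 18000)
  for (w in sample.int(nrow(prof2$windows), 8)) {
    lo <- prof2$windows$start[w] - 2001 + 1
    hi <- prof2$windows$end[w] - 2001 + 1
    expect_equal(prof2$windows$depth[w], mean(cov[lo:hi]))
  }
  expect_equal(prof2$mean_depth, mean(cov))
})

test_that("depth is additive across merged record sets", {
  refs <- mini_reference(73, acc_len = 10000L)
  s1 <- simulate_reads(list(refs$accA), coverage = 5, seed = 1)
  s2 <- simulate_reads(list(refs$accA), coverage = 5, seed = 2)
  r1 <- project_alignments(s1, refs); r2 <- project_alignments(s2, refs)
  iv <- genomic_interval("accA", 1, 10000)
  p1 <- windowed_depth(r1, iv); p2 <- windowed_depth(r2, iv)
  pm <- windowed_depth(alignment_frame(rbind(r1, r2)), iv)
  expect_equal(pm$windows$depth, p1$windows$depth + p2$windows$depth)
})

test_that("fold-change calls follow copy arithmetic", {
  mkprof <- function(depths) structure(list(
    contig = "c1", window_size = 1000L,
    windows = data.frame(start = seq(1, by = 1000,
                                     length.out = length(depths)),
                         end = seq(1000, by = 1000,
                                   length.out = length(depths)),
                         depth = depths),
    mean_depth = mean(depths)), class = "depth_profile")
  ## fixed-input arithmetic: insert 64x over 40x flanks = 1.6-fold
  prof <- mkprof(c(rep(40, 3), rep(64, 4), rep(40, 3)))
  call <- fold_change_call(prof, genomic_interval("c1", 3001, 7000),
                           list(up = genomic_interval("c1", 1, 3000),
                                down = genomic_interval("c1", 7001, 10000)))
  expect_equal(call$fold_change, 1.6)
  expect_true(call$gained)
  ## identical means -> fold 1, not gained
  flat <- mkprof(rep(40, 10))
  call2 <- fold_change_call(flat, genomic_interval("c1", 3001, 7000),
                            list(up = genomic_interval("c1", 1, 3000),
                                 down = genomic_interval("c1", 7001, 10000)))
  expect_equal(call2$fold_change, 1)
  expect_false(call2$gained)
  zero <- mkprof(c(rep(0, 3), rep(10, 4), rep(0, 3)))
  expect_error(fold_change_call(zero, genomic_interval("c1", 3001, 7000),
                                list(up = genomic_interval("c1", 1, 3000),
                                     down = genomic_interval("c1", 7001, 10000))),
               "zero flank")
})

test_that("wild-type fold change stays near 1", {
  refs <- mini_reference(79, don_len = 20000L)
  sim <- simulate_reads(list(refs$donB, refs$donB), coverage = 15, seed = 79)
  rec <- project_alignments(sim, refs)
  prof <- windowed_depth(rec[rec$contig == "donB", ],
                         genomic_interval("donB", 1001, 19000), 500)
  call <- fold_change_call(prof, genomic_interval("donB", 7001, 13000),
                           list(up = genomic_interval("donB", 1001, 7000),
                                down = genomic_interval("donB", 13001, 19000)))
  expect_gte(call$fold_change, 0.9)
  expect_lte(call$fold_change, 1.1)
  expect_false(call$gained)
})
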