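## Shared fixture builders: everything is generated in code at test time.

## small three-contig reference for junction experiments
mini_reference <- function(seed, acc_len = 6000L, don_len = 3000L,
                           thr_len = 800L) {
  build_reference(list(contigs = list(
    list(name = "accA", length = acc_len, offset = 10000),
    list(name = "donB", length = don_len, offset = 50000),
    list(name = "thrC", length = thr_len, offset = 90000))), seed = seed)
}

## random junction spec with paper-like feature ranges on the mini reference;
## variants are kept >= 12 bp beyond the inverted block so that the distal
## anchor is identifiable at segmentation scale
random_mini_spec <- function(refs, seed) {
  set.seed(seed)
  acc <- refs$accA; don <- refs$donB; thr <- refs$thrC
  b_loc <- sample(2000:3500, 1)
  dl <- sample(1200:1800, 1)
  ds_loc <- sample(200:(don$length - dl - 200), 1)
  uh <- sample(0:6, 1)
  mi_len <- sample(c(0L, 5L, sample(10:25, 1)), 1)
  ov <- if (mi_len >= 12) sample(0:min(10, mi_len - 2), 1) else 0L
  inv <- sample(c(0L, sample(1:15, 1)), 1)
  mi_s <- sample(100:(thr$length - 60), 1)
  with_snv <- runif(1) < 0.5
  with_del <- runif(1) < 0.5
  snv_off <- sample(12:40, 1); del_off <- snv_off + sample(4:10, 1)
  snv_ref <- substr(acc$sequence, b_loc + inv + snv_off,
                    b_loc + inv + snv_off)
  junction_spec(
    acceptor_contig = "accA", acceptor_break = acc$offset + b_loc,
    donor_contig = "donB",
    donor_segment = genomic_interval("donB", don$offset + ds_loc,
                                     don$offset + ds_loc + dl - 1),
    proximal_microhomology_len = uh,
    micro_insert = if (mi_len > 0)
      list(source = genomic_interval("thrC", thr$offset + mi_s,
                                     thr$offset + mi_s + mi_len - 1),
           length = mi_len, overlap_with_donor = ov) else NULL,
    acceptor_inversion_len = inv,
    junction_snv = if (with_snv)
      list(pos = acc$offset + b_loc + inv + snv_off, ref = snv_ref,
           alt = setdiff(c("A", "C", "G", "T"), snv_ref)[1]) else NULL,
    junction_deletion = if (with_del)
      list(pos = acc$offset + b_loc + inv + del_off, len = 1L) else NULL)
}

comp_base_one <- function(x) chartr("ACGT", "TGCA", x)

## fixed paper-architecture spec (uh 2, 19 bp insert with 10 bp overlap,
## 12 bp inversion, one SNV, one 1 bp deletion) on the mini reference
cmtx3_like_spec <- function(refs) {
  acc <- refs$accA; don <- refs$donB; thr <- refs$thrC
  b <- acc$offset + 3000
  junction_spec(
    acceptor_contig = "accA", acceptor_break = b,
    donor_contig = "donB",
    ## insert longer than the PCR max_product so the wild-type primer pair
    ## cannot bridge it on the mutant haplotype
    donor_segment = genomic_interval("donB", don$offset + 200,
                                     don$offset + 2600),
    proximal_microhomology_len = 2,
    micro_insert = list(source = genomic_interval("thrC", thr$offset + 300,
                                                  thr$offset + 318),
                        length = 19, overlap_with_donor = 10),
    acceptor_inversion_len = 12,
    junction_snv = list(pos = b + 20,
                        ref = substr(acc$sequence, 3020, 3020),
                        alt = setdiff(c("A", "C", "G", "T"),
                                      substr(acc$sequence, 3020, 3020))[1]),
    junction_deletion = list(pos = b + 28, len = 1))
}

## simulate + project + resolve one spec end to end
run_mini_pipeline <- function(seed, coverage = 40) {
  refs <- mini_reference(seed)
  spec <- random_mini_spec(refs, seed + 1000L)
  mut <- build_mutant_haplotype(refs, spec)
  sim <- simulate_reads(list(mut), coverage = coverage, seed = seed + 2000L)
  rec <- project_alignments(sim, mut$reference)
  call <- resolve_insertion(rec, mut$reference)
  list(spec = spec, call = call, refs = mut$reference, mut = mut, rec = rec)
}

## brute-force per-base coverage from truth placements of a simulation
oracle_depth <- function(sim, hap_id, lo, hi) {
  p <- sim$pairs[sim$pairs$hap == hap_id, ]
  rl <- sim$read_len
  cov <- numeric(hi - lo + 1)
  add <- function(s, e) {
    s <- max(s, lo); e <- min(e, hi)
    if (s <= e) cov[(s - lo + 1):(e - lo + 1)] <<- cov[(s - lo + 1):(e - lo + 1)] + 1
  }
  for (i in seq_len(nrow(p))) {
    add(p$start[i], p$start[i] + rl - 1)
    add(p$start[i] + p$frag_len[i] - rl, p$start[i] + p$frag_len[i] - 1)
  }
  cov
}

## brute-force maximal junction overlap: largest k with suffix_k(left) ==
## prefix_k(right)
oracle_overlap <- function(left, right) {
  kmax <- min(nchar(left), nchar(right))
  best <- 0L
  for (k in seq_len(kmax)) {
    if (substr(left, nchar(left) - k + 1, nchar(left)) ==
        substr(right, 1, k)) best <- k
  }
  best
}

## O(n^2) oracle: longest inverted repeat (loop <= max_loop) containing pos
oracle_palindrome <- function(seqstr, pos, max_loop = 8L, min_arm = 1L) {
  ch <- strsplit(seqstr, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  n <- length(ch)
  best <- 0L
  for (g in 0:max_loop) for (c0 in seq_len(n)) {
    a <- 0L
    while (c0 - a >= 1 && c0 + g + a + 1 <= n &&
           ch[c0 - a] == comp[[ch[c0 + g + a + 1]]]) a <- a + 1L
    if (a >= min_arm && pos >= c0 - a + 1 && pos <= c0 + g + a)
      best <- max(best, a)
  }
  best
}

## random alignment frame of paired full-match records over two contigs
random_pair_records <- function(seed, n = 40L, rl = 50L) {
  set.seed(seed)
  ctgs <- c("c1", "c2")
  rows <- list()
  for (i in seq_len(n)) {
    same <- runif(1) < 0.7
    c1 <- sample(ctgs, 1)
    c2 <- if (same) c1 else sample(setdiff(ctgs, c1), 1)
    p1 <- sample(1:5000, 1)
    p2 <- if (same) p1 + sample(c(50:800, 2000), 1) else sample(1:5000, 1)
    sq <- paste(sample(c("A", "C", "G", "T"), rl, TRUE), collapse = "")
    rows[[2 * i - 1]] <- data.frame(
      qname = sprintf("q%04d", i), mate = 1L, flag = 1L + 64L,
      contig = c1, pos = p1, mapq = 60L, cigar = paste0(rl, "M"), seq = sq,
      mate_contig = c2, mate_pos = p2, isize = 0L)
    rows[[2 * i]] <- data.frame(
      qname = sprintf("q%04d", i), mate = 2L, flag = 1L + 128L + 16L,
      contig = c2, pos = p2, mapq = 60L, cigar = paste0(rl, "M"), seq = sq,
      mate_contig = c1, mate_pos = p1, isize = 0L)
  }
  alignment_frame(do.call(rbind, rows))
}
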