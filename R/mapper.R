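#' Light exact-seed read mapper
#'
#' Desk-scale mapper so the pipeline can run from raw FASTQ without an
#' external aligner: a k-mer index over the (plus strand of the) reference is
#' probed with the first and last k bases of each read in both orientations
#' and every candidate locus is verified by exact extension. Unique
#' full-length matches get a full-match CIGAR at MAPQ 60; reads whose prefix
#' and suffix match different loci are emitted as a soft-clipped primary plus
#' a supplementary record (split alignment); reads with several equally good
#' placements get MAPQ 0. Mismatches are not tolerated, which is lossless on
#' error-free simulated data.
#'
#' @param r1,r2 character vectors of mate sequences, or paths to FASTQ files.
#'   `r2` may be NULL for single-end input.
#' @param reference a `contig_set` (total size must be modest; the index is
#'   held in memory).
#' @param k seed length, default 31 (must not exceed the read length).
#' @param min_piece smallest split piece reported (default 20 bp).
#' @param qnames optional read names (defaults to FASTQ names or `read_i`).
#' @return an alignment frame.
#' @export
map_reads <- function(r1, r2 = NULL, reference, k = 31L, min_piece = 20L,
                      qnames = NULL) {
  if (is.character(r1) && length(r1) == 1L && file.exists(r1)) {
    fq <- read_fastq(r1)
    qnames <- fq$qname; r1 <- fq$seq
  }
  if (!is.null(r2) && is.character(r2) && length(r2) == 1L && file.exists(r2))
    r2 <- read_fastq(r2)$seq
  if (any(nchar(c(r1, r2)) < k)) stop("k must not exceed the read length")
  if (is.null(qnames)) qnames <- sprintf("read_%06d", seq_along(r1))

  idx <- kmer_index(reference, k)
  recs1 <- map_mate(r1, qnames, 1L, idx, reference, k, min_piece)
  recs <- if (is.null(r2)) recs1
          else rbind(recs1, map_mate(r2, qnames, 2L, idx, reference, k, min_piece))
  ## mate fields from each mate's primary record
  prim <- recs[!aln_is_supplementary(recs) & !flag_has(recs$flag, 4L), ]
  m <- match(paste(recs$qname, 3L - recs$mate), paste(prim$qname, prim$mate))
  recs$mate_contig <- prim$contig[m]
  recs$mate_pos <- prim$pos[m]
  mate_rev <- !is.na(m) & flag_has(ifelse(is.na(m), 0L, prim$flag[m]), 16L)
  recs$flag <- recs$flag + 32L * mate_rev
  alignment_frame(recs[order(recs$contig, recs$pos), ])
}

## data.table k-mer index over the plus strand of every contig
kmer_index <- function(reference, k) {
  total <- sum(vapply(reference, `[[`, numeric(1), "length"))
  if (total > 10e6) stop("reference too large to k-mer index in memory")
  tabs <- lapply(reference, function(ctg) {
    n <- ctg$length - k + 1L
    if (n < 1L) return(NULL)
    data.table::data.table(kmer = substring(ctg$sequence, 1:n, k:ctg$length),
                           contig = ctg$name, pos = 1:n)
  })
  idx <- data.table::rbindlist(tabs)
  data.table::setkey(idx, kmer)
  idx
}

map_mate <- function(reads, qnames, mate, idx, reference, k, min_piece) {
  L <- nchar(reads)
  base_flag <- 1L + if (mate == 1L) 64L else 128L
  out <- vector("list", length(reads))
  for (i in seq_along(reads)) {
    out[[i]] <- map_one(reads[i], qnames[i], mate, base_flag, idx, reference,
                        k, min_piece)
  }
  do.call(rbind, out)
}

## candidate (contig, pos) loci for a k-mer
seed_hits <- function(idx, pattern_kmer) {
  ## the join variable must not share the column's name (data.table scoping)
  h <- idx[list(pattern_kmer), nomatch = NULL]
  if (!nrow(h)) NULL else h
}

## length of exact match between read[from..] and contig sequence at ref pos
extend_fwd <- function(ctg, p, s, from = 1L) {
  n <- min(nchar(s) - from + 1L, ctg$length - p + 1L)
  if (n <= 0L) return(0L)
  a <- strsplit(substr(s, from, from + n - 1L), "")[[1]]
  b <- strsplit(substr(ctg$sequence, p, p + n - 1L), "")[[1]]
  mm <- which(a != b)
  if (!length(mm)) n else mm[1] - 1L
}

map_one <- function(read, qname, mate, base_flag, idx, reference, k, min_piece) {
  L <- nchar(read)
  unmapped <- data.frame(qname = qname, mate = mate, flag = base_flag + 4L,
                         contig = "*", pos = 1, mapq = 0L, cigar = "*",
                         seq = read, stringsAsFactors = FALSE)
  best <- list()   # per orientation: full matches / prefix / suffix pieces
  for (orient in c("+", "-")) {
    s <- if (orient == "+") read else revcomp(read)
    pre <- seed_hits(idx, substr(s, 1L, k))
    fulls <- list(); prefixes <- list()
    if (!is.null(pre)) for (j in seq_len(nrow(pre))) {
      ctg <- reference[[pre$contig[j]]]
      m <- extend_fwd(ctg, pre$pos[j], s)
      rec <- list(contig = pre$contig[j], pos = pre$pos[j], len = m)
      if (m == L) fulls[[length(fulls) + 1L]] <- rec
      else prefixes[[length(prefixes) + 1L]] <- rec
    }
    suf <- seed_hits(idx, substr(s, L - k + 1L, L))
    suffixes <- list()
    if (!is.null(suf)) for (j in seq_len(nrow(suf))) {
      ctg <- reference[[suf$contig[j]]]
      ## extend backwards: match suffix of s ending at suf$pos + k - 1
      e <- suf$pos[j] + k - 1L
      rs <- revcomp(s); rctg <- contig(ctg$name, revcomp(ctg$sequence), 0)
      m <- extend_fwd(rctg, ctg$length - e + 1L, rs)
      if (m < L)
        suffixes[[length(suffixes) + 1L]] <-
          list(contig = suf$contig[j], pos = e - m + 1L, len = m)
    }
    best[[orient]] <- list(fulls = fulls, prefixes = prefixes,
                           suffixes = suffixes)
  }
  nfull <- length(best[["+"]]$fulls) + length(best[["-"]]$fulls)
  if (nfull >= 1L) {
    orient <- if (length(best[["+"]]$fulls)) "+" else "-"
    hit <- best[[orient]]$fulls[[1]]
    return(data.frame(
      qname = qname, mate = mate,
      flag = base_flag + 16L * (orient == "-"),
      contig = hit$contig, pos = hit$pos,
      mapq = if (nfull == 1L) 60L else 0L, cigar = paste0(L, "M"),
      seq = if (orient == "-") revcomp(read) else read,
      stringsAsFactors = FALSE))
  }
  ## chimeric: best prefix + best suffix covering the read
  pick <- function(ps) if (!length(ps)) NULL else
    ps[[which.max(vapply(ps, `[[`, numeric(1), "len"))]]
  cand <- list()
  for (orient in c("+", "-")) {
    pf <- pick(best[[orient]]$prefixes); sf <- pick(best[[orient]]$suffixes)
    if (!is.null(pf) && !is.null(sf) && pf$len >= min_piece &&
        sf$len >= min_piece && pf$len + sf$len >= L)
      cand[[orient]] <- list(pf = pf, sf = sf)
  }
  if (!length(cand)) return(unmapped)
  orient <- names(cand)[1]
  pf <- cand[[orient]]$pf; sf <- cand[[orient]]$sf
  s <- if (orient == "+") read else revcomp(read)
  rev_bit <- 16L * (orient == "-")
  mk <- function(piece, left, supp) {
    lc <- if (left) 0L else L - piece$len
    rc <- if (left) L - piece$len else 0L
    data.frame(
      qname = qname, mate = mate,
      flag = base_flag + rev_bit + 2048L * supp,
      contig = piece$contig, pos = piece$pos, mapq = 60L,
      cigar = paste0(if (lc) paste0(lc, "S") else "", piece$len, "M",
                     if (rc) paste0(rc, "S") else ""),
      seq = s, stringsAsFactors = FALSE)
  }
  primary_left <- pf$len >= sf$len
  rbind(mk(pf, TRUE, !primary_left), mk(sf, FALSE, primary_left))
}
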