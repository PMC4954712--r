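#' Simulate paired-end reads from haplotypes
#'
#' Draws fragments (normal insert-size model, forward-reverse orientation)
#' uniformly along each haplotype and reports both mates plus a per-read
#' truth record. Reads are error-free by default so that truth projection
#' stays exact; an optional uniform substitution rate is available.
#'
#' @param haplotypes list of haplotypes: each element either a `contig`
#'   (wild-type, identity truth) or the list returned by
#'   [build_mutant_haplotype()]. Each listed haplotype copy receives
#'   `coverage` fold depth, so passing two copies of a contig doubles its
#'   depth.
#' @param coverage target per-haplotype fold coverage (> 0).
#' @param read_len read length in bp (>= 20), default 101.
#' @param insert_mean,insert_sd fragment length distribution; the default
#'   mean of 350 makes twice the library mean equal the canonical 700 bp
#'   discordance threshold. `insert_mean` must be >= 2 * `read_len`.
#' @param seed mandatory integer seed.
#' @param error_rate per-base substitution probability, default 0.
#' @return object of class `sim_reads`: `$pairs` (data.frame qname, hap,
#'   start, frag_len), `$r1`, `$r2` (read sequences), `$read_len`,
#'   `$haplotypes` (named list of `list(contig=, truth=)`).
#' @export
simulate_reads <- function(haplotypes, coverage, read_len = 101L,
                           insert_mean = 350, insert_sd = 35, seed,
                           error_rate = 0) {
  if (coverage <= 0) stop("coverage must be > 0")
  if (read_len < 20) stop("read_len must be >= 20")
  if (insert_mean < 2 * read_len)
    stop("insert_mean must be at least 2 * read_len")
  haps <- normalize_haplotypes(haplotypes)

  out <- with_seed(seed, {
    res <- lapply(names(haps), function(id) {
      ctg <- haps[[id]]$contig
      len <- ctg$length
      n <- max(1L, as.integer(round(len * coverage / (2 * read_len))))
      frag <- as.integer(round(rnorm(n, insert_mean, insert_sd)))
      frag <- pmin(pmax(frag, 2L * read_len), len)
      start <- floor(runif(n) * (len - frag + 1)) + 1L
      r1 <- substring(ctg$sequence, start, start + read_len - 1L)
      r2 <- revcomp(substring(ctg$sequence, start + frag - read_len,
                              start + frag - 1L))
      list(pairs = data.frame(
             qname = sprintf("%s_p%07d", id, seq_len(n)),
             hap = id, start = start, frag_len = frag,
             stringsAsFactors = FALSE),
           r1 = r1, r2 = r2)
    })
    r1 <- unlist(lapply(res, `[[`, "r1")); r2 <- unlist(lapply(res, `[[`, "r2"))
    if (error_rate > 0) {
      r1 <- inject_errors(r1, error_rate)
      r2 <- inject_errors(r2, error_rate)
    }
    list(pairs = do.call(rbind, lapply(res, `[[`, "pairs")), r1 = r1, r2 = r2)
  })
  structure(list(pairs = out$pairs, r1 = out$r1, r2 = out$r2,
                 read_len = as.integer(read_len), haplotypes = haps),
            class = "sim_reads")
}

normalize_haplotypes <- function(haplotypes) {
  if (inherits(haplotypes, "contig") ||
      (is.list(haplotypes) && !is.null(haplotypes$haplotype)))
    haplotypes <- list(haplotypes)
  haps <- lapply(haplotypes, function(h) {
    if (inherits(h, "contig")) list(contig = h, truth = wildtype_truth(h))
    else if (is.list(h) && !is.null(h$haplotype))
      list(contig = h$haplotype, truth = h$truth)
    else if (is.list(h) && !is.null(h$contig)) h
    else stop("haplotypes must be contigs or build_mutant_haplotype() results")
  })
  ids <- names(haplotypes)
  auto <- vapply(haps, function(h) h$contig$name, character(1))
  if (is.null(ids)) ids <- auto else ids[!nzchar(ids)] <- auto[!nzchar(ids)]
  names(haps) <- make.unique(ids, sep = "_")
  haps
}

inject_errors <- function(reads, rate) {
  vapply(reads, function(r) {
    ch <- strsplit(r, "")[[1]]
    hit <- which(runif(length(ch)) < rate)
    if (length(hit)) ch[hit] <- vapply(ch[hit], function(b)
      sample(setdiff(DNA_BASES, b), 1L), character(1))
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Write simulated reads as a paired FASTQ
#'
#' @param sim a `sim_reads` object.
#' @param prefix output path prefix; writes `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq`.
#' @return invisibly, the two file paths.
#' @export
write_fastq <- function(sim, prefix) {
  q <- strrep("I", sim$read_len)
  f1 <- paste0(prefix, "_1.fastq"); f2 <- paste0(prefix, "_2.fastq")
  writeLines(as.vector(rbind(paste0("@", sim$pairs$qname, "/1"),
                             sim$r1, "+", q)), f1)
  writeLines(as.vector(rbind(paste0("@", sim$pairs$qname, "/2"),
                             sim$r2, "+", q)), f2)
  invisible(c(f1, f2))
}

#' Read a FASTQ file
#'
#' @param path FASTQ file.
#' @return data.frame with `qname` and `seq`.
#' @export
read_fastq <- function(path) {
  x <- readLines(path)
  if (length(x) %% 4L != 0L) stop("truncated FASTQ: ", path)
  qn <- sub("^@", "", x[seq(1, length(x), by = 4L)])
  qn <- sub("/[12]$", "", qn)
  data.frame(qname = qn, seq = x[seq(2, length(x), by = 4L)],
             stringsAsFactors = FALSE)
}

#' Write contigs as FASTA
#'
#' @param contigs a `contig_set` or list of contigs.
#' @param path output file.
#' @export
write_fasta <- function(contigs, path) {
  if (inherits(contigs, "contig")) contigs <- list(contigs)
  seqs <- Biostrings::DNAStringSet(vapply(contigs, `[[`, character(1), "sequence"))
  names(seqs) <- vapply(contigs, `[[`, character(1), "name")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read contigs from FASTA
#'
#' @param path FASTA file.
#' @param offsets optional named numeric vector of coordinate offsets.
#' @return a `contig_set`.
#' @export
read_fasta <- function(path, offsets = NULL) {
  seqs <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(seqs))
  contig_set(lapply(seq_along(seqs), function(i) {
    contig(nm[i], as.character(seqs[[i]]),
           if (!is.null(offsets) && nm[i] %in% names(offsets)) offsets[[nm[i]]] else 0)
  }))
}

#' Serialize simulation truth as JSON
#'
#' @param sim a `sim_reads` object.
#' @param path output JSON path.
#' @export
write_truth <- function(sim, path) {
  truth <- list(
    haplotypes = lapply(sim$haplotypes, function(h) {
      list(name = h$contig$name, length = h$contig$length,
           segments = h$truth$segments)
    }),
    pairs = sim$pairs)
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Project simulated reads to reference alignments
#'
#' Replaces an external aligner for error-free simulated data: each read is
#' placed at its true reference location through the haplotype segment map.
#' Reads wholly inside one reference segment get a full-match CIGAR;
#' junction-spanning reads are emitted as a primary record (longest mapped
#' piece, remainder soft-clipped) plus supplementary records for every other
#' piece of at least `min_anchor` bases. Pieces separated only by a reference
#' deletion are merged into one record with a `D` CIGAR operation. MAPQ is 60
#' for all uniquely projected records.
#'
#' @param sim a `sim_reads` object.
#' @param reference the `contig_set` the truth maps point into.
#' @param min_anchor smallest mapped piece emitted as its own record (bp).
#' @return an alignment data.frame (see [alignment_frame()]).
#' @export
project_alignments <- function(sim, reference, min_anchor = 20L) {
  haps <- sim$haplotypes
  rl <- sim$read_len
  for (h in haps) {
    segs <- h$truth$segments
    bad <- !segs$contig %in% names(reference)
    if (any(bad)) stop("truth references unknown contig: ",
                       paste(unique(segs$contig[bad]), collapse = ", "))
  }
  reads <- rbind(
    data.frame(qname = sim$pairs$qname, mate = 1L, hap = sim$pairs$hap,
               hstart = sim$pairs$start, strand = "+", seq = sim$r1,
               stringsAsFactors = FALSE),
    data.frame(qname = sim$pairs$qname, mate = 2L, hap = sim$pairs$hap,
               hstart = sim$pairs$start + sim$pairs$frag_len - rl,
               strand = "-", seq = sim$r2, stringsAsFactors = FALSE))
  reads$hend <- reads$hstart + rl - 1L

  rec_list <- vector("list", length(haps))
  for (hi in seq_along(haps)) {
    id <- names(haps)[hi]
    segs <- haps[[id]]$truth$segments
    rr <- reads[reads$hap == id, , drop = FALSE]
    i1 <- findInterval(rr$hstart, segs$hap_start)
    i2 <- findInterval(rr$hend, segs$hap_start)
    simple <- i1 == i2
    ## fast path: read wholly inside one mapped segment
    rs <- rr[simple, , drop = FALSE]
    si <- i1[simple]
    plus <- segs$strand[si] == "+"
    pos <- ifelse(plus,
                  segs$ref_start[si] + (rs$hstart - segs$hap_start[si]),
                  segs$ref_end[si] - (rs$hend - segs$hap_start[si]))
    rev_map <- xor(rs$strand == "-", !plus)
    recs <- data.frame(
      qname = rs$qname, mate = rs$mate,
      flag = 1L + 64L * (rs$mate == 1L) + 128L * (rs$mate == 2L) +
        16L * rev_map,
      contig = segs$contig[si], pos = pos, mapq = 60L,
      cigar = paste0(rl, "M"),
      seq = ifelse(rev_map, revcomp_v(rs$seq), rs$seq),
      supplementary = FALSE, stringsAsFactors = FALSE)
    ## slow path: junction-spanning reads
    rj <- rr[!simple, , drop = FALSE]
    jrecs <- if (nrow(rj)) do.call(rbind, lapply(seq_len(nrow(rj)), function(k)
      project_split_read(rj[k, ], segs, rl, min_anchor)))
    rec_list[[hi]] <- rbind(recs, jrecs)
  }
  rec <- do.call(rbind, rec_list)
  rec$flag <- rec$flag + 2048L * rec$supplementary

  ## mate fields from each mate's primary record
  prim <- rec[!rec$supplementary, ]
  key <- paste(rec$qname, 3L - rec$mate)
  m <- match(key, paste(prim$qname, prim$mate))
  rec$mate_contig <- prim$contig[m]
  rec$mate_pos <- prim$pos[m]
  mate_rev <- !is.na(m) & bitwAnd(ifelse(is.na(m), 0L, prim$flag[m]), 16L) > 0L
  rec$flag <- rec$flag + 32L * mate_rev
  ## template length for same-contig primary pairs
  self <- match(paste(rec$qname, rec$mate), paste(prim$qname, prim$mate))
  same <- !is.na(m) & !is.na(self) & rec$mate_contig == rec$contig &
    !rec$supplementary
  rec$isize <- 0L
  lo <- pmin(rec$pos, rec$mate_pos)
  hi2 <- pmax(rec$pos + rl - 1L, rec$mate_pos + rl - 1L)
  rec$isize[same] <- as.integer((hi2 - lo + 1L)[same] *
                                  ifelse(rec$pos[same] <= rec$mate_pos[same], 1L, -1L))
  alignment_frame(rec[order(rec$contig, rec$pos), ])
}

revcomp_v <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## one junction-spanning read -> primary + supplementary records
project_split_read <- function(r, segs, rl, min_anchor) {
  ov <- which(segs$hap_end >= r$hstart & segs$hap_start <= r$hend)
  pieces <- lapply(ov, function(si) {
    ps <- max(r$hstart, segs$hap_start[si]); pe <- min(r$hend, segs$hap_end[si])
    plus <- segs$strand[si] == "+"
    list(q1 = ps - r$hstart + 1L, q2 = pe - r$hstart + 1L,
         contig = segs$contig[si], strand = segs$strand[si],
         ref_start = if (plus) segs$ref_start[si] + (ps - segs$hap_start[si])
                     else segs$ref_end[si] - (pe - segs$hap_start[si]),
         ref_end = if (plus) segs$ref_start[si] + (pe - segs$hap_start[si])
                   else segs$ref_end[si] - (ps - segs$hap_start[si]))
  })
  ## merge adjacent same-contig same-plus-strand pieces split by a deletion
  merged <- list(pieces[[1]])
  for (p in pieces[-1]) {
    last <- merged[[length(merged)]]
    if (p$contig == last$contig && p$strand == "+" && last$strand == "+" &&
        p$q1 == last$q2 + 1L && p$ref_start > last$ref_end + 1L) {
      last$dels <- rbind(last$dels,
                         c(qpos = last$q2, gap = p$ref_start - last$ref_end - 1L))
      last$q2 <- p$q2; last$ref_end <- p$ref_end
      merged[[length(merged)]] <- last
    } else merged[[length(merged) + 1L]] <- p
  }
  keep <- vapply(merged, function(p) p$q2 - p$q1 + 1L >= min_anchor, logical(1))
  if (!any(keep)) keep[which.max(vapply(merged, function(p) p$q2 - p$q1, numeric(1)))] <- TRUE
  merged <- merged[keep]
  lens <- vapply(merged, function(p) as.integer(p$q2 - p$q1 + 1L), integer(1))
  primary <- which.max(lens)

  do.call(rbind, lapply(seq_along(merged), function(i) {
    p <- merged[[i]]
    rev_map <- xor(r$strand == "-", p$strand == "-")
    seq_out <- if (rev_map) revcomp_v(r$seq) else r$seq
    ## clips in reference orientation
    lc <- if (p$strand == "+") p$q1 - 1L else rl - p$q2
    rc <- if (p$strand == "+") rl - p$q2 else p$q1 - 1L
    mlen <- p$q2 - p$q1 + 1L
    cig <- if (is.null(p$dels)) paste0(mlen, "M") else {
      dq <- p$dels[, "qpos"] - p$q1 + 1L
      ops <- character(0); prev <- 0L
      for (j in seq_len(nrow(p$dels))) {
        ops <- c(ops, paste0(dq[j] - prev, "M"), paste0(p$dels[j, "gap"], "D"))
        prev <- dq[j]
      }
      paste0(paste(ops, collapse = ""), mlen - prev, "M")
    }
    cig <- paste0(if (lc > 0) paste0(lc, "S") else "", cig,
                  if (rc > 0) paste0(rc, "S") else "")
    data.frame(qname = r$qname, mate = r$mate,
               flag = 1L + 64L * (r$mate == 1L) + 128L * (r$mate == 2L) +
                 16L * rev_map,
               contig = p$contig, pos = p$ref_start, mapq = 60L, cigar = cig,
               seq = seq_out, supplementary = i != primary,
               stringsAsFactors = FALSE)
  }))
}
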