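#' Find discordant read pairs
#'
#' Flags high-quality read pairs whose mates map to different contigs
#' (`inter_chromosomal`) or whose implied insert exceeds the threshold
#' (`long_insert`, strictly greater). The default threshold of 700 bp equals
#' twice the default library mean insert size.
#'
#' @param records alignment frame (will be filtered through `policy`).
#' @param policy a [filter_policy()]; both mates must survive it.
#' @param insert_threshold discordance threshold in bp (default 700).
#' @return data.frame with one row per discordant pair: `qname`, `contig_a`,
#'   `pos_a`, `contig_b`, `pos_b`, `reason`, `insert_size`.
#' @export
find_discordant_pairs <- function(records, policy = filter_policy(),
                                  insert_threshold = 700) {
  recs <- apply_policy(records, policy)
  prim <- recs[!aln_is_supplementary(recs) & !aln_is_secondary(recs) &
                 !flag_has(recs$flag, 4L), , drop = FALSE]
  m1 <- prim[prim$mate == 1L, , drop = FALSE]
  m2 <- prim[prim$mate == 2L, , drop = FALSE]
  ## reconstruct pairs by qname
  common <- intersect(m1$qname, m2$qname)
  if (length(common) < nrow(m1) || length(common) < nrow(m2))
    warning("unpaired records in stream; pairs reconstructed by qname")
  m1 <- m1[match(common, m1$qname), , drop = FALSE]
  m2 <- m2[match(common, m2$qname), , drop = FALSE]
  if (!length(common))
    return(data.frame(qname = character(0), contig_a = character(0),
                      pos_a = numeric(0), contig_b = character(0),
                      pos_b = numeric(0), reason = character(0),
                      insert_size = numeric(0)))
  inter <- m1$contig != m2$contig
  span <- pmax(m1$pos + cigar_ref_length(m1$cigar) - 1,
               m2$pos + cigar_ref_length(m2$cigar) - 1) - pmin(m1$pos, m2$pos) + 1
  long <- !inter & span > insert_threshold
  sel <- inter | long
  data.frame(qname = common[sel],
             contig_a = m1$contig[sel], pos_a = m1$pos[sel],
             contig_b = m2$contig[sel], pos_b = m2$pos[sel],
             reason = ifelse(inter[sel], "inter_chromosomal", "long_insert"),
             insert_size = ifelse(inter[sel], NA_real_, span[sel]),
             stringsAsFactors = FALSE)
}

#' Windows of generally poor read alignment
#'
#' Fixed windows in which the fraction of low-quality records (MAPQ below 20
#' or unmapped/ambiguous) strictly exceeds `max_low_mapq_frac`; adjacent
#' flagged windows are merged.
#'
#' @param records alignment frame (unfiltered).
#' @param window_size window width in bp (default 200).
#' @param max_low_mapq_frac tolerated low-quality fraction (default 0.5).
#' @param low_mapq records below this MAPQ count as poor (default 20).
#' @return data.frame `contig`, `start`, `end` (contig-local, 1-based
#'   inclusive); zero rows when nothing is flagged.
#' @export
poor_alignment_regions <- function(records, window_size = 200L,
                                   max_low_mapq_frac = 0.5, low_mapq = 20L) {
  out <- list()
  for (ctg in unique(records$contig)) {
    r <- records[records$contig == ctg, , drop = FALSE]
    win <- (r$pos - 1) %/% window_size
    low <- r$mapq < low_mapq | flag_has(r$flag, 4L)
    frac <- tapply(low, win, mean)
    bad <- as.numeric(names(frac))[frac > max_low_mapq_frac]
    if (!length(bad)) next
    bad <- sort(bad)
    grp <- cumsum(c(1, diff(bad) > 1))
    for (g in unique(grp)) {
      w <- bad[grp == g]
      out[[length(out) + 1L]] <- data.frame(
        contig = ctg, start = min(w) * window_size + 1,
        end = (max(w) + 1) * window_size, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) data.frame(contig = character(0), start = numeric(0),
                               end = numeric(0))
  else do.call(rbind, out)
}

#' Cluster discordant pairs into candidate rearrangement windows
#'
#' Slides half-overlapping windows along each contig, keeps windows holding
#' at least `min_support` discordant ends sharing a partner contig, merges
#' overlapping windows, and reports the local-maximum rearrangement position
#' (the base with the highest discordant-end count, leftmost on ties).
#' Clusters intersecting an exclusion region are dropped.
#'
#' @param pairs output of [find_discordant_pairs()].
#' @param window_size window width in bp (default 200; step is half).
#' @param min_support minimum pair support per window (default 3).
#' @param exclusion optional data.frame `contig`,`start`,`end` of regions to
#'   drop (e.g. [poor_alignment_regions()]).
#' @return data.frame `contig`, `start`, `end`, `partner_contig`, `support`,
#'   `peak_pos`.
#' @export
cluster_discordant <- function(pairs, window_size = 200L, min_support = 3L,
                               exclusion = NULL) {
  if (!nrow(pairs))
    return(data.frame(contig = character(0), start = numeric(0),
                      end = numeric(0), partner_contig = character(0),
                      support = integer(0), peak_pos = numeric(0)))
  ends <- rbind(
    data.frame(contig = pairs$contig_a, pos = pairs$pos_a,
               partner = pairs$contig_b, qname = pairs$qname),
    data.frame(contig = pairs$contig_b, pos = pairs$pos_b,
               partner = pairs$contig_a, qname = pairs$qname))
  step <- max(1L, window_size %/% 2L)
  out <- list()
  for (key in unique(paste(ends$contig, ends$partner))) {
    e <- ends[paste(ends$contig, ends$partner) == key, , drop = FALSE]
    e <- e[order(e$pos), , drop = FALSE]
    w0 <- seq(from = (min(e$pos) %/% step) * step - window_size,
              to = max(e$pos), by = step)
    support <- vapply(w0, function(s)
      length(unique(e$qname[e$pos >= s & e$pos <= s + window_size - 1])),
      integer(1))
    hit <- which(support >= min_support)
    if (!length(hit)) next
    ## merge overlapping qualifying windows
    grp <- cumsum(c(1, diff(hit) > window_size %/% step))
    for (g in unique(grp)) {
      h <- hit[grp == g]
      s <- w0[min(h)]; en <- w0[max(h)] + window_size - 1
      inw <- e[e$pos >= s & e$pos <= en, , drop = FALSE]
      tab <- table(inw$pos)
      peak <- as.numeric(names(tab))[which.max(tab)]   # leftmost on ties
      out[[length(out) + 1L]] <- data.frame(
        contig = e$contig[1], start = max(1, s), end = en,
        partner_contig = e$partner[1],
        support = length(unique(inw$qname)), peak_pos = peak,
        stringsAsFactors = FALSE)
    }
  }
  cl <- if (length(out)) do.call(rbind, out)
        else return(data.frame(contig = character(0), start = numeric(0),
                               end = numeric(0), partner_contig = character(0),
                               support = integer(0), peak_pos = numeric(0)))
  if (!is.null(exclusion) && nrow(exclusion)) {
    drop <- vapply(seq_len(nrow(cl)), function(i) {
      any(exclusion$contig == cl$contig[i] &
            exclusion$start <= cl$end[i] & exclusion$end >= cl$start[i])
    }, logical(1))
    cl <- cl[!drop, , drop = FALSE]
  }
  rownames(cl) <- NULL
  cl
}

## all exact occurrences of a pattern (both strands) across a contig_set;
## returns data.frame(contig, pos, strand) with pos = 1-based start of the
## plus-strand footprint
search_exact <- function(pattern, reference, subjects = NULL) {
  if (is.null(subjects)) subjects <- reference_subjects(reference)
  hits <- list()
  pat <- Biostrings::DNAString(pattern)
  rpat <- Biostrings::reverseComplement(pat)
  for (nm in names(subjects)) {
    fw <- Biostrings::start(Biostrings::matchPattern(pat, subjects[[nm]]))
    rv <- Biostrings::start(Biostrings::matchPattern(rpat, subjects[[nm]]))
    if (length(fw))
      hits[[length(hits) + 1L]] <- data.frame(contig = nm, pos = fw,
                                              strand = "+")
    if (length(rv))
      hits[[length(hits) + 1L]] <- data.frame(contig = nm, pos = rv,
                                              strand = "-")
  }
  if (!length(hits)) data.frame(contig = character(0), pos = integer(0),
                                strand = character(0))
  else do.call(rbind, hits)
}

reference_subjects <- function(reference) {
  setNames(lapply(reference, function(ctg) Biostrings::DNAString(ctg$sequence)),
           names(reference))
}

#' Find split reads
#'
#' Extracts records with a soft-clipped tail of at least `min_clip` bases and
#' remaps the clipped subsequence by exact search (both strands) across the
#' reference. A read yields evidence when the clipped piece maps uniquely on
#' another contig or more than `min_distance` away from the anchor ("did not
#' map locally"). The breakpoint is the last aligned base adjacent to the
#' clip; the mate's contig classifies the evidence into the two paired-end
#' anchor classes.
#'
#' @param records alignment frame (apply a [filter_policy()] first if wanted).
#' @param reference `contig_set` for remapping.
#' @param min_clip minimum clipped length (default 20 bp).
#' @param min_distance minimum distance for a same-contig split (default
#'   1000 bp).
#' @return data.frame with columns `qname`, `contig`, `breakpoint_pos`,
#'   `breakpoint_coord` (genome-scale via the contig offset), `clip_side`,
#'   `side` (`proximal` for right clips, `distal` for left clips),
#'   `clip_len`, `clipped_contig`, `clipped_pos`, `clipped_strand`,
#'   `mate_contig`, `ambiguous`.
#' @export
find_split_reads <- function(records, reference, min_clip = 20L,
                             min_distance = 1000L) {
  empty <- data.frame(qname = character(0), contig = character(0),
                      breakpoint_pos = numeric(0), breakpoint_coord = numeric(0),
                      clip_side = character(0), side = character(0),
                      clip_len = integer(0), clipped_contig = character(0),
                      clipped_pos = numeric(0), clipped_strand = character(0),
                      mate_contig = character(0), ambiguous = logical(0))
  mapped <- records[!flag_has(records$flag, 4L) & records$cigar != "*", ,
                    drop = FALSE]
  if (!nrow(mapped)) return(empty)
  has_clip <- grepl("S", mapped$cigar, fixed = TRUE)
  cand <- mapped[has_clip, , drop = FALSE]
  if (!nrow(cand)) return(empty)
  subjects <- reference_subjects(reference)
  cache <- new.env(parent = emptyenv())
  out <- list()
  for (i in seq_len(nrow(cand))) {
    cs <- clip_structure(cand[i, ])
    rlen <- cigar_ref_length(cand$cigar[i])
    for (sidec in c("left", "right")) {
      sq <- if (sidec == "left") cs$left_seq else cs$right_seq
      if (nchar(sq) < min_clip) next
      hits <- if (!is.null(cache[[sq]])) cache[[sq]]
              else cache[[sq]] <- search_exact(sq, reference, subjects)
      bp <- if (sidec == "left") cand$pos[i] else cand$pos[i] + rlen - 1
      nonlocal <- hits[hits$contig != cand$contig[i] |
                         abs(hits$pos - bp) > min_distance, , drop = FALSE]
      ## a clip that maps only locally is not junction evidence; one that
      ## maps nowhere at all (a chimeric clip crossing a complex junction)
      ## still is - "did not map locally" - with an unknown clip locus
      if (!nrow(nonlocal) && nrow(hits)) next
      out[[length(out) + 1L]] <- data.frame(
        qname = cand$qname[i], contig = cand$contig[i],
        breakpoint_pos = bp,
        breakpoint_coord = reference[[cand$contig[i]]]$offset + bp,
        clip_side = sidec,
        side = if (sidec == "right") "proximal" else "distal",
        clip_len = nchar(sq),
        clipped_contig = if (nrow(nonlocal)) nonlocal$contig[1] else NA_character_,
        clipped_pos = if (nrow(nonlocal)) nonlocal$pos[1] else NA_real_,
        clipped_strand = if (nrow(nonlocal)) nonlocal$strand[1] else NA_character_,
        mate_contig = cand$mate_contig[i] %||% NA_character_,
        ambiguous = nrow(nonlocal) > 1L,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res[order(res$contig, res$breakpoint_pos), , drop = FALSE]
}

#' Summarize breakpoint evidence
#'
#' Tallies split reads by mate-anchor class and discordant-pair support at
#' each breakpoint, in the layout of a per-breakpoint evidence table.
#'
#' @param splits output of [find_split_reads()].
#' @param clusters output of [cluster_discordant()].
#' @param breakpoints data.frame with `label`, `contig`, `pos`; when NULL the
#'   modal split-read breakpoints per (contig, side) are used.
#' @param tol matching tolerance in bp (default 5 for splits; discordant
#'   clusters match when their window covers the breakpoint +- window width).
#' @return data.frame `breakpoint`, `class`, `count`.
#' @export
summarize_evidence <- function(splits, clusters, breakpoints = NULL, tol = 5) {
  if (is.null(breakpoints)) breakpoints <- modal_breakpoints(splits)
  if (!nrow(breakpoints))
    return(data.frame(breakpoint = character(0), class = character(0),
                      count = integer(0)))
  rows <- list()
  for (i in seq_len(nrow(breakpoints))) {
    b <- breakpoints[i, ]
    s <- splits[splits$contig == b$contig &
                  abs(splits$breakpoint_pos - b$pos) <= tol, , drop = FALSE]
    anchors <- sort(unique(c(s$mate_contig, b$contig)))
    for (a in anchors)
      rows[[length(rows) + 1L]] <- data.frame(
        breakpoint = b$label, class = paste0("split_mate_", a),
        count = sum(s$mate_contig == a, na.rm = TRUE))
    d <- clusters[clusters$contig == b$contig &
                    clusters$start - 200 <= b$pos &
                    clusters$end + 200 >= b$pos, , drop = FALSE]
    rows[[length(rows) + 1L]] <- data.frame(
      breakpoint = b$label, class = "discordant_pairs",
      count = if (nrow(d)) sum(d$support) else 0L)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## modal split-read breakpoint per (contig, side)
modal_breakpoints <- function(splits) {
  if (!nrow(splits))
    return(data.frame(label = character(0), contig = character(0),
                      pos = numeric(0)))
  keys <- unique(splits[, c("contig", "side")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    s <- splits[splits$contig == keys$contig[i] & splits$side == keys$side[i], ]
    tab <- table(s$breakpoint_pos)
    data.frame(label = paste0(keys$side[i], "@", keys$contig[i]),
               contig = keys$contig[i],
               pos = as.numeric(names(tab))[which.max(tab)],
               side = keys$side[i], support = max(tab),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Export intervals as BED
#'
#' Converts the package's 1-based inclusive intervals to BED's 0-based
#' half-open convention at the boundary, the only place that conversion
#' happens.
#'
#' @param intervals data.frame with `contig`, `start`, `end` (1-based
#'   inclusive) and optionally `support`/`peak_pos` columns (e.g.
#'   [cluster_discordant()] output).
#' @param path output BED path.
#' @export
write_bed <- function(intervals, path) {
  name <- if (!is.null(intervals$partner_contig))
    paste0("partner=", intervals$partner_contig) else "."
  score <- if (!is.null(intervals$support)) intervals$support else 0L
  bed <- data.frame(chrom = intervals$contig,
                    chromStart = format(intervals$start - 1, scientific = FALSE,
                                        trim = TRUE),
                    chromEnd = format(intervals$end, scientific = FALSE,
                                      trim = TRUE),
                    name = name, score = score)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
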