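#' Assemble a breakpoint consensus from split reads
#'
#' Builds a positional majority-vote consensus over all reads supporting one
#' breakpoint (same anchor contig, clip side, and breakpoint position within
#' `tol`). Records are placed on a common column scale anchored at their
#' aligned start minus the left clip, so the clipped tails line up across the
#' junction.
#'
#' @param splits evidence rows from [find_split_reads()] for one breakpoint.
#' @param records alignment frame the evidence came from.
#' @param tol breakpoint grouping tolerance (default 5 bp).
#' @param min_support minimum number of supporting reads (default 2).
#' @param max_tie_frac consensus is flagged low-confidence when more than
#'   this fraction of columns have tied votes (default 0.1).
#' @return list with `consensus` (character), `col1_ref` (contig-local
#'   reference position of consensus column 1 on the anchored contig),
#'   `contig`, `breakpoint_pos`, `support`, `low_confidence`.
#' @export
assemble_junction <- function(splits, records, tol = 5, min_support = 2L,
                              max_tie_frac = 0.1) {
  if (nrow(splits) < min_support)
    stop("need at least ", min_support, " supporting reads per breakpoint")
  bp <- as.numeric(names(sort(table(splits$breakpoint_pos),
                              decreasing = TRUE))[1])
  grp <- splits[abs(splits$breakpoint_pos - bp) <= tol, , drop = FALSE]
  if (nrow(grp) < min_support)
    stop("need at least ", min_support, " supporting reads per breakpoint")
  recs <- records[records$qname %in% grp$qname &
                    records$contig == grp$contig[1] &
                    grepl("S", records$cigar, fixed = TRUE), , drop = FALSE]
  offs <- numeric(nrow(recs)); seqs <- character(nrow(recs))
  for (i in seq_len(nrow(recs))) {
    cs <- clip_structure(recs[i, ])
    offs[i] <- recs$pos[i] - cs$left_clip
    seqs[i] <- recs$seq[i]
  }
  lo <- min(offs); hi <- max(offs + nchar(seqs) - 1)
  ncol <- hi - lo + 1
  counts <- matrix(0L, nrow = 4, ncol = ncol, dimnames = list(DNA_BASES, NULL))
  for (i in seq_along(seqs)) {
    ch <- strsplit(seqs[i], "")[[1]]
    idx <- cbind(match(ch, DNA_BASES), (offs[i] - lo) + seq_along(ch))
    ok <- !is.na(idx[, 1])
    for (r in which(ok)) counts[idx[r, 1], idx[r, 2]] <-
        counts[idx[r, 1], idx[r, 2]] + 1L
  }
  top <- apply(counts, 2, max)
  winner <- apply(counts, 2, which.max)
  ties <- colSums(counts == rep(top, each = 4)) > 1 & top > 0
  consensus <- paste(DNA_BASES[winner], collapse = "")
  list(consensus = consensus, col1_ref = lo, contig = grp$contig[1],
       breakpoint_pos = bp, support = nrow(grp),
       low_confidence = mean(ties) > max_tie_frac)
}

#' Segment a junction consensus against the reference
#'
#' Greedy left-to-right walk: at each unexplained position the longest exact
#' reference match of at least `min_match` bases (any contig, either strand)
#' is taken, extended maximally in both directions; adjacent segments may
#' therefore overlap in query coordinates, and that overlap is the junction
#' microhomology. Unexplained stretches are returned as gaps for micro-insert
#' / fold-back analysis.
#'
#' @param consensus junction consensus sequence.
#' @param reference `contig_set`.
#' @param min_match minimum seed/segment length (default 10).
#' @return list with `segments` (data.frame `q_start`, `q_end`, `contig`,
#'   `ref_start`, `ref_end`, `strand`, `ambiguous`) and `gaps` (data.frame
#'   `q_start`, `q_end`).
#' @export
segment_junction <- function(consensus, reference, min_match = 10L) {
  n <- nchar(consensus)
  subjects <- reference_subjects(reference)
  cons <- strsplit(consensus, "")[[1]]
  refchars <- lapply(reference, function(ctg) strsplit(ctg$sequence, "")[[1]])
  segs <- list(); gaps <- list()
  i <- 1L; gap_start <- NA_integer_
  close_gap <- function(upto) {
    if (!is.na(gap_start) && upto >= gap_start)
      gaps[[length(gaps) + 1L]] <<- data.frame(q_start = gap_start, q_end = upto)
    gap_start <<- NA_integer_
  }
  while (i + min_match - 1L <= n) {
    seed <- substr(consensus, i, i + min_match - 1L)
    hits <- search_exact(seed, reference, subjects)
    if (!nrow(hits)) {
      if (is.na(gap_start)) gap_start <- i
      i <- i + 1L
      next
    }
    ## extend every candidate maximally in both directions
    ext <- lapply(seq_len(nrow(hits)), function(j) {
      extend_hit(cons, i, refchars[[hits$contig[j]]], hits$pos[j],
                 hits$strand[j], min_match)
    })
    lens <- vapply(ext, function(e) e$q2 - e$q1 + 1L, integer(1))
    ## tie-break: contig order in the reference, then leftmost, then + strand
    ord <- order(-lens, match(hits$contig, names(reference)), hits$pos,
                 hits$strand)
    bestj <- ord[1]
    best <- ext[[bestj]]
    close_gap(i - 1L)
    segs[[length(segs) + 1L]] <- data.frame(
      q_start = best$q1, q_end = best$q2, contig = hits$contig[bestj],
      ref_start = best$r1, ref_end = best$r2, strand = hits$strand[bestj],
      ambiguous = sum(lens == lens[bestj]) > 1L, stringsAsFactors = FALSE)
    i <- best$q2 + 1L
  }
  close_gap(n)
  list(segments = if (length(segs)) do.call(rbind, segs) else
         data.frame(q_start = integer(0), q_end = integer(0),
                    contig = character(0), ref_start = integer(0),
                    ref_end = integer(0), strand = character(0),
                    ambiguous = logical(0)),
       gaps = if (length(gaps)) do.call(rbind, gaps) else
         data.frame(q_start = integer(0), q_end = integer(0)))
}

## maximal bidirectional exact extension of a seed hit
extend_hit <- function(cons, qpos, refch, rpos, strand, seed_len) {
  n <- length(cons); m <- length(refch)
  if (strand == "+") {
    q2 <- qpos + seed_len - 1L; r2 <- rpos + seed_len - 1L
    while (q2 < n && r2 < m && cons[q2 + 1L] == refch[r2 + 1L]) {
      q2 <- q2 + 1L; r2 <- r2 + 1L
    }
    q1 <- qpos; r1 <- rpos
    while (q1 > 1L && r1 > 1L && cons[q1 - 1L] == refch[r1 - 1L]) {
      q1 <- q1 - 1L; r1 <- r1 - 1L
    }
    list(q1 = q1, q2 = q2, r1 = r1, r2 = r2)
  } else {
    ## cons[q1..q2] == revcomp(ref[r1..r2]); query right ~ reference left
    r1 <- rpos; r2 <- rpos + seed_len - 1L
    q2 <- qpos + seed_len - 1L
    while (q2 < n && r1 > 1L && cons[q2 + 1L] == comp_base(refch[r1 - 1L])) {
      q2 <- q2 + 1L; r1 <- r1 - 1L
    }
    q1 <- qpos
    while (q1 > 1L && r2 < m && cons[q1 - 1L] == comp_base(refch[r2 + 1L])) {
      q1 <- q1 - 1L; r2 <- r2 + 1L
    }
    list(q1 = q1, q2 = q2, r1 = r1, r2 = r2)
  }
}

#' Microhomology between two adjacent junction segments
#'
#' The maximal k such that the last k bases of the left segment's reference
#' context equal the first k bases of the right segment's reference context:
#' the bases at the junction that are identical in both source references and
#' therefore cannot be assigned to either side.
#'
#' @param left_seg,right_seg one-row segment data.frames (as returned by
#'   [segment_junction()]): `contig`, `ref_start`, `ref_end`, `strand`.
#' @param reference `contig_set`.
#' @param max_k scan bound (default 50).
#' @return list with `length` and `sequence`.
#' @export
call_microhomology <- function(left_seg, right_seg, reference, max_k = 50L) {
  lbase <- function(j) seg_base_from_end(left_seg, j, reference)
  rbase <- function(j) seg_base_from_start(right_seg, j, reference)
  ## each k must be tested on its own: suffix_k == prefix_k is not a nested
  ## property (the aligned base pairs change with k)
  k <- 0L
  for (cand in seq_len(max_k)) {
    lb <- vapply(cand:1, lbase, character(1))
    rb <- vapply(1:cand, rbase, character(1))
    if (anyNA(lb) || anyNA(rb)) break
    if (all(lb == rb)) k <- cand
  }
  seqk <- if (k > 0) paste(vapply(k:1, lbase, character(1)), collapse = "") else ""
  list(length = k, sequence = seqk)
}

## j-th base counting back from the (junction-side) end of a segment,
## strand-aware; j=1 is the final base
seg_base_from_end <- function(seg, j, reference) {
  ctg <- reference[[seg$contig]]
  if (seg$strand == "+") {
    p <- seg$ref_end - j + 1L
    if (p < 1 || p > ctg$length) return(NA_character_)
    substr(ctg$sequence, p, p)
  } else {
    p <- seg$ref_start + j - 1L
    if (p < 1 || p > ctg$length) return(NA_character_)
    comp_base(substr(ctg$sequence, p, p))
  }
}

seg_base_from_start <- function(seg, j, reference) {
  ctg <- reference[[seg$contig]]
  if (seg$strand == "+") {
    p <- seg$ref_start + j - 1L
    if (p < 1 || p > ctg$length) return(NA_character_)
    substr(ctg$sequence, p, p)
  } else {
    p <- seg$ref_end - j + 1L
    if (p < 1 || p > ctg$length) return(NA_character_)
    comp_base(substr(ctg$sequence, p, p))
  }
}

#' Attribute an unexplained junction subsequence to a reference source
#'
#' Searches all reference contigs (both strands) for a unique exact hit of
#' the gap sequence, allowing the hit to extend leftward into the preceding
#' (donor) segment: template-switch micro-inserts typically share their first
#' bases with the donor end, so the true fragment is the gap plus that
#' overlap. The largest extension with a hit wins; a gap with no hit is
#' reported as unknown origin.
#'
#' @param gap_seq unexplained subsequence.
#' @param reference `contig_set`.
#' @param min_hit minimum attributable fragment length (default 10).
#' @param left_context sequence immediately left of the gap (donor end),
#'   used for overlap extension; `""` for none.
#' @param max_overlap largest overlap tried (default 30).
#' @return list `source_contig` (NA when unknown), `ref_start`, `ref_end`,
#'   `strand`, `length`, `overlap_with_donor`, `ambiguous`, `loci`.
#' @export
detect_micro_insert <- function(gap_seq, reference, min_hit = 10L,
                                left_context = "", max_overlap = 30L) {
  g <- nchar(gap_seq)
  unknown <- list(source_contig = NA_character_, ref_start = NA, ref_end = NA,
                  strand = NA_character_, length = g, overlap_with_donor = 0L,
                  ambiguous = FALSE, loci = NULL)
  if (g == 0L) return(NULL)
  lc <- nchar(left_context)
  for (e in seq(min(lc, max_overlap), 0L)) {
    ext <- paste0(substr(left_context, lc - e + 1L, lc), gap_seq)
    if (nchar(ext) < min_hit) next
    hits <- search_exact(ext, reference)
    if (!nrow(hits)) next
    return(list(source_contig = hits$contig[1],
                ref_start = hits$pos[1],
                ref_end = hits$pos[1] + nchar(ext) - 1L,
                strand = hits$strand[1], length = nchar(ext),
                overlap_with_donor = e, ambiguous = nrow(hits) > 1L,
                loci = hits))
  }
  unknown
}

#' Call a fold-back inversion at a junction
#'
#' An inverted acceptor block manifests either as a minus-strand acceptor
#' segment whose reference interval abuts the downstream acceptor segment, or
#' (for blocks shorter than the segmentation seed) as an unexplained gap
#' whose tail equals the reverse complement of the acceptor bases immediately
#' preceding the downstream segment. Only a match abutting the acceptor
#' breakpoint is called.
#'
#' @param candidate one-row minus-strand segment data.frame, or a character
#'   gap sequence for the fold-back test.
#' @param acceptor_ref the acceptor `contig`.
#' @param next_ref_start contig-local reference start of the downstream
#'   acceptor segment.
#' @return list `length`, `ref_start`, `ref_end` (0-length when absent).
#' @export
detect_inversion <- function(candidate, acceptor_ref, next_ref_start) {
  none <- list(length = 0L, ref_start = NA, ref_end = NA)
  if (is.data.frame(candidate)) {
    if (!nrow(candidate) || candidate$strand != "-") return(none)
    if (candidate$ref_end + 1L != next_ref_start) return(none)
    return(list(length = candidate$ref_end - candidate$ref_start + 1L,
                ref_start = candidate$ref_start, ref_end = candidate$ref_end))
  }
  gap <- as.character(candidate)
  g <- nchar(gap)
  if (g == 0L) return(none)
  best <- 0L
  for (k in seq_len(min(g, next_ref_start - 1L))) {
    tail_k <- substr(gap, g - k + 1L, g)
    ref_k <- contig_sub(acceptor_ref, next_ref_start - k, next_ref_start - 1L)
    if (tail_k == revcomp(ref_k)) best <- k
  }
  if (best == 0L) return(none)
  list(length = best, ref_start = next_ref_start - best,
       ref_end = next_ref_start - 1L)
}

#' Call junction-adjacent variants
#'
#' Aligns the acceptor-matching portion of a junction consensus against the
#' acceptor reference (Needleman-Wunsch via `Biostrings::pairwiseAlignment`)
#' and reports SNVs, deletions and insertions within the window.
#'
#' @param consensus junction consensus.
#' @param q_start query position where the acceptor portion begins.
#' @param acceptor_ref acceptor `contig`.
#' @param ref_start contig-local reference position matching `q_start`.
#' @param window window width on the acceptor side (default 50 bp).
#' @return data.frame `type` (snv/del/ins), `ref_pos` (contig-local), `ref`,
#'   `alt`, `len`; zero rows when the window matches the reference.
#' @export
call_junction_variants <- function(consensus, q_start, acceptor_ref, ref_start,
                                   window = 50L) {
  n <- nchar(consensus)
  qlen <- min(window, n - q_start + 1L)
  if (qlen < 1L) return(variant_frame())
  pat <- substr(consensus, q_start, q_start + qlen - 1L)
  slen <- min(qlen + 10L, acceptor_ref$length - ref_start + 1L)
  subj <- contig_sub(acceptor_ref, ref_start, ref_start + slen - 1L)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(pat), Biostrings::DNAString(subj),
    type = "global-local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -3, baseOnly = TRUE),
    gapOpening = 5, gapExtension = 2)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  spos <- ref_start + Biostrings::start(Biostrings::subject(aln)) - 1L
  out <- list()
  i <- 1L
  while (i <= length(p)) {
    if (p[i] == "-" && s[i] != "-") {            # deletion in consensus
      j <- i
      while (j < length(p) && p[j + 1L] == "-") j <- j + 1L
      out[[length(out) + 1L]] <- data.frame(
        type = "del", ref_pos = spos, ref = paste(s[i:j], collapse = ""),
        alt = "", len = j - i + 1L, stringsAsFactors = FALSE)
      spos <- spos + (j - i + 1L); i <- j + 1L
    } else if (s[i] == "-" && p[i] != "-") {     # insertion in consensus
      j <- i
      while (j < length(p) && s[j + 1L] == "-") j <- j + 1L
      out[[length(out) + 1L]] <- data.frame(
        type = "ins", ref_pos = spos - 1L, ref = "",
        alt = paste(p[i:j], collapse = ""), len = j - i + 1L,
        stringsAsFactors = FALSE)
      i <- j + 1L
    } else {
      if (p[i] != s[i])
        out[[length(out) + 1L]] <- data.frame(
          type = "snv", ref_pos = spos, ref = s[i], alt = p[i], len = 1L,
          stringsAsFactors = FALSE)
      spos <- spos + 1L; i <- i + 1L
    }
  }
  if (!length(out)) variant_frame() else do.call(rbind, out)
}

variant_frame <- function() {
  data.frame(type = character(0), ref_pos = numeric(0), ref = character(0),
             alt = character(0), len = integer(0))
}

#' Annotate the palindrome / hairpin context of a breakpoint
#'
#' Finds the maximal inverted repeat (arms reverse-complementary, central
#' loop of at most `max_loop` non-palindromic bases) whose span contains the
#' breakpoint. Hairpin heads formed by such palindromes are double-strand
#' break hotspots, so rearrangement breakpoints cluster near their centers.
#'
#' @param acceptor_ref acceptor `contig` (or a plain DNA string).
#' @param breakpoint_pos contig-local breakpoint position.
#' @param max_arm largest arm searched (default 200 bp).
#' @param max_loop largest loop allowed (default 8 bp).
#' @param min_arm smallest arm reported (default 20 bp).
#' @return list `arm_length`, `loop`, `center`, `start`, `end`,
#'   `breakpoint_distance` (breakpoint minus palindrome center), or NULL when
#'   no qualifying palindrome exists.
#' @export
annotate_palindrome <- function(acceptor_ref, breakpoint_pos, max_arm = 200L,
                                max_loop = 8L, min_arm = 20L) {
  seqstr <- if (inherits(acceptor_ref, "contig")) acceptor_ref$sequence
            else as.character(acceptor_ref)
  ch <- strsplit(seqstr, "")[[1]]
  n <- length(ch)
  bp <- breakpoint_pos
  best <- NULL
  for (g in 0:max_loop) {
    for (cpos in max(1, bp - max_arm):min(n, bp + max_arm)) {
      ## cpos = last base of the left arm; loop occupies cpos+1 .. cpos+g
      a <- 0L
      while (cpos - a >= 1L && cpos + g + a + 1L <= n &&
             a < max_arm &&
             ch[cpos - a] == comp_base(ch[cpos + g + a + 1L]))
        a <- a + 1L
      if (a < min_arm) next
      span_lo <- cpos - a + 1L; span_hi <- cpos + g + a
      if (bp < span_lo || bp > span_hi) next
      if (is.null(best) || a > best$arm_length)
        best <- list(arm_length = a,
                     loop = if (g > 0) substr(seqstr, cpos + 1L, cpos + g) else "",
                     center = cpos + (g + 1) / 2,
                     start = span_lo, end = span_hi,
                     breakpoint_distance = bp - (cpos + (g + 1) / 2))
    }
  }
  best
}
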