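#' Resolve an interchromosomal insertion from alignments
#'
#' End-to-end breakpoint resolution: split-read detection, per-breakpoint
#' consensus assembly, multi-reference segmentation, microhomology /
#' micro-insert / inversion / junction-variant calling, discordant-pair
#' corroboration and palindrome annotation, emitted as a single insertion
#' call.
#'
#' @param records alignment frame (e.g. from [project_alignments()] or
#'   [read_alignments()]).
#' @param reference `contig_set`.
#' @param acceptor acceptor contig name; when NULL it is inferred as the
#'   contig whose proximal and distal split-read breakpoints lie closest
#'   together (the insertion point), as opposed to the donor whose
#'   breakpoints sit an insert-length apart.
#' @param policy [filter_policy()] applied before detection.
#' @param min_clip,min_match detection/segmentation minima (defaults 20/10).
#' @param insert_threshold discordant insert threshold (default 700 bp).
#' @return list of class `insertion_call`; NULL when no split evidence.
#' @export
resolve_insertion <- function(records, reference, acceptor = NULL,
                              policy = filter_policy(), min_clip = 20L,
                              min_match = 10L, insert_threshold = 700) {
  recs <- apply_policy(records, policy)
  splits <- find_split_reads(recs, reference, min_clip)
  if (!nrow(splits)) return(NULL)
  if (is.null(acceptor)) acceptor <- infer_acceptor(splits)
  if (is.null(acceptor)) return(NULL)
  acc_ref <- reference[[acceptor]]

  prox_sp <- splits[splits$contig == acceptor & splits$side == "proximal", ,
                    drop = FALSE]
  dist_sp <- splits[splits$contig == acceptor & splits$side == "distal", ,
                    drop = FALSE]
  if (nrow(prox_sp) < 2L || nrow(dist_sp) < 2L) return(NULL)
  prox_cons <- assemble_junction(prox_sp, recs)
  dist_cons <- assemble_junction(dist_sp, recs)
  prox <- resolve_proximal(prox_cons, reference, acceptor, min_match)
  dist <- resolve_distal(dist_cons, reference, acceptor, min_match)
  if (is.null(prox) || is.null(dist)) return(NULL)
  if (!is.null(dist$donor_contig) && !is.null(prox$donor_contig) &&
      dist$donor_contig != prox$donor_contig)
    stop("composite event: junction donor contigs disagree (",
         prox$donor_contig, " vs ", dist$donor_contig, ")")

  don_ref <- reference[[prox$donor_contig]]
  d1 <- prox$donor_edge; d2 <- dist$donor_edge
  donor_start <- min(d1, d2); donor_end <- max(d1, d2)
  mi <- dist$micro_insert
  mi_net <- if (is.null(mi)) 0L else mi$length - mi$overlap_with_donor
  dels <- dist$variants[dist$variants$type == "del", , drop = FALSE]
  inserted_length <- (donor_end - donor_start + 1) + mi_net -
    (if (nrow(dels)) sum(dels$len) else 0L)

  if (!is.null(mi) && !is.na(mi$source_contig)) {
    src_off <- reference[[mi$source_contig]]$offset
    mi$coord_start <- src_off + mi$ref_start
    mi$coord_end <- src_off + mi$ref_end
  }
  inv <- dist$inversion
  if (inv$length > 0) {
    inv$coord_start <- acc_ref$offset + inv$ref_start
    inv$coord_end <- acc_ref$offset + inv$ref_end
  }
  pairs <- find_discordant_pairs(records, policy, insert_threshold)
  clusters <- cluster_discordant(pairs,
                                 exclusion = poor_alignment_regions(records))
  bps <- data.frame(label = c("proximal", "distal"),
                    contig = acceptor,
                    pos = c(prox$acceptor_break, dist$acc_resume))
  evidence <- summarize_evidence(splits, clusters, bps)
  variants <- dist$variants
  if (nrow(variants))
    variants$coord <- acc_ref$offset + variants$ref_pos
  pal <- annotate_palindrome(acc_ref, prox$acceptor_break)
  if (!is.null(pal)) {
    pal$center_coord <- acc_ref$offset + pal$center
    pal$breakpoint_coord <- acc_ref$offset + prox$acceptor_break
  }

  structure(list(
    acceptor_contig = acceptor,
    acceptor_break = prox$acceptor_break,
    acceptor_break_coord = acc_ref$offset + prox$acceptor_break,
    insertion_site = acc_ref$offset + c(prox$acceptor_break,
                                        prox$acceptor_break + 1),
    donor_contig = prox$donor_contig,
    donor_orientation = prox$donor_strand,
    donor_start = donor_start,
    donor_end = donor_end,
    donor_start_coord = don_ref$offset + donor_start,
    donor_end_coord = don_ref$offset + donor_end,
    donor_length = donor_end - donor_start + 1,
    inserted_length = inserted_length,
    microhomology = prox$microhomology,
    micro_insert = mi,
    inversion = inv,
    variants = variants,
    palindrome = pal,
    evidence = evidence,
    junctions = list(proximal = prox, distal = dist),
    low_confidence = prox_cons$low_confidence || dist_cons$low_confidence
  ), class = "insertion_call")
}

#' @export
print.insertion_call <- function(x, ...) {
  fmt <- function(v) format(v, big.mark = ",", scientific = FALSE)
  cat(sprintf("<insertion_call: %s bp of %s:%s-%s inserted at %s:%s-%s>\n",
              fmt(x$inserted_length), x$donor_contig,
              fmt(x$donor_start_coord), fmt(x$donor_end_coord),
              x$acceptor_contig, fmt(x$insertion_site[1]),
              fmt(x$insertion_site[2])))
  cat(sprintf("  microhomology %d bp (%s); micro-insert %s bp (overlap %s); inversion %d bp\n",
              x$microhomology$length, x$microhomology$sequence,
              if (is.null(x$micro_insert)) 0 else x$micro_insert$length,
              if (is.null(x$micro_insert)) 0 else x$micro_insert$overlap_with_donor,
              x$inversion$length))
  invisible(x)
}

## acceptor = contig whose proximal/distal modal breakpoints are closest
infer_acceptor <- function(splits, max_separation = 2000) {
  mb <- modal_breakpoints(splits)
  best <- NULL; best_d <- Inf
  for (ctg in unique(mb$contig)) {
    p <- mb[mb$contig == ctg & mb$side == "proximal", ]
    d <- mb[mb$contig == ctg & mb$side == "distal", ]
    if (!nrow(p) || !nrow(d)) next
    sep <- abs(p$pos[1] - d$pos[1])
    if (sep <= max_separation && sep < best_d) {
      best <- ctg; best_d <- sep
    }
  }
  best
}

## segmentation seed long enough that chance exact hits across the whole
## reference (both strands) are rare; never below the configured minimum
adaptive_seed_len <- function(reference, min_match) {
  total <- sum(vapply(reference, `[[`, numeric(1), "length"))
  max(min_match, as.integer(ceiling(log(200 * 2 * total) / log(4))))
}

## proximal junction: acceptor(+) prefix -> donor, microhomology at the seam.
## The acceptor side is fixed by the split-read anchors (the consensus column
## scale IS the acceptor coordinate system), so only the clipped side is
## searched; this keeps resolution stable even when the breakpoint sits in a
## palindrome whose minus-strand image shadows exact matching.
resolve_proximal <- function(cons, reference, acceptor, min_match = 10L) {
  b <- cons$breakpoint_pos
  q_b <- b - cons$col1_ref + 1L
  seed <- adaptive_seed_len(reference, min_match)
  sj <- segment_junction(cons$consensus, reference, seed)
  segs <- sj$segments
  ## the donor candidate must reach well into the clipped side and must not
  ## be the anchored acceptor diagonal itself
  anchor_diag <- cons$col1_ref - 1L
  cand <- segs[segs$q_end >= q_b + min_match &
                 segs$q_start >= q_b - 30L &
                 !(segs$contig == acceptor & segs$strand == "+" &
                     abs((segs$ref_start - segs$q_start) - anchor_diag) <= 2L), ,
               drop = FALSE]
  if (!nrow(cand)) return(NULL)
  don_seg <- cand[which.max(cand$q_end - cand$q_start), , drop = FALSE]
  acc_pseudo <- data.frame(contig = acceptor, ref_start = b - q_b + 1L,
                           ref_end = b, strand = "+")
  uh <- call_microhomology(acc_pseudo, don_seg, reference)
  list(acceptor_break = b,
       donor_contig = don_seg$contig,
       donor_strand = don_seg$strand,
       ## left-assignment convention: the donor designation includes the
       ## shared bases, so the reported edge is the maximal-extension start
       donor_edge = if (don_seg$strand == "+") don_seg$ref_start
                    else don_seg$ref_end,
       microhomology = uh,
       segments = segs, consensus = cons$consensus)
}

## distal junction: donor tail -> [micro-insert] -> [fold-back inversion] ->
## acceptor(+) remainder with junction variants. The acceptor resume
## coordinate comes from the split-read anchors; the junction interval
## between the donor segment and the anchor is analyzed as a string.
resolve_distal <- function(cons, reference, acceptor, min_match = 10L,
                           variant_window = 50L) {
  a1 <- cons$breakpoint_pos
  q_a <- a1 - cons$col1_ref + 1L
  acc_ref <- reference[[acceptor]]
  seed <- adaptive_seed_len(reference, min_match)
  sj <- segment_junction(cons$consensus, reference, seed)
  segs <- sj$segments
  anchor_diag <- cons$col1_ref - 1L
  cand <- segs[segs$q_start <= max(1L, q_a - min_match) &
                 segs$q_end <= q_a + 30L &
                 !(segs$contig == acceptor & segs$strand == "+" &
                     abs((segs$ref_start - segs$q_start) - anchor_diag) <= 2L), ,
               drop = FALSE]
  if (!nrow(cand)) return(NULL)
  don_seg <- cand[which.max(cand$q_end - cand$q_start), , drop = FALSE]

  ## unexplained junction interval between donor end and the acceptor resume
  gap_str <- if (q_a - 1L >= don_seg$q_end + 1L)
    substr(cons$consensus, don_seg$q_end + 1L, q_a - 1L) else ""
  ## fold-back inversion at the tail of the gap, abutting the resume point
  inv <- detect_inversion(gap_str, acc_ref, a1)
  if (inv$length > 0L)
    gap_str <- substr(gap_str, 1L, nchar(gap_str) - inv$length)
  ## remaining gap: micro-insert with possible donor-end overlap
  mi <- NULL
  if (nchar(gap_str) > 0L) {
    ctx_len <- min(30L, don_seg$q_end)
    ctx <- substr(cons$consensus, don_seg$q_end - ctx_len + 1L, don_seg$q_end)
    mi <- detect_micro_insert(gap_str, reference, min_hit = min_match,
                              left_context = ctx)
  }
  variants <- call_junction_variants(cons$consensus, q_a, acc_ref, a1,
                                     window = variant_window)
  list(donor_contig = don_seg$contig,
       donor_strand = don_seg$strand,
       donor_edge = if (don_seg$strand == "+") don_seg$ref_end
                    else don_seg$ref_start,
       micro_insert = mi,
       inversion = inv,
       acc_resume = a1,
       variants = variants,
       segments = segs, consensus = cons$consensus)
}

#' Emit VCF 4.2 records for an insertion call
#'
#' Writes four mate-paired breakend (BND) records — two per junction — plus
#' one symbolic INS record, and a derivative-chromosome notation string
#' `der(acceptor)dir ins(acceptor;donor)(bands)`.
#'
#' @param call an `insertion_call`.
#' @param reference `contig_set`.
#' @param path optional output path for the VCF text.
#' @param bands optional character vector `c(acceptor=, donor=)` of
#'   cytogenetic band labels for the notation string (config metadata, not
#'   computed).
#' @return list with `vcf` (character lines) and `notation`.
#' @export
emit_call <- function(call, reference, path = NULL, bands = NULL) {
  acc <- reference[[call$acceptor_contig]]
  don <- reference[[call$donor_contig]]
  base_at <- function(ctg, local) contig_sub(ctg, local, local)
  b <- call$acceptor_break
  bc <- call$acceptor_break_coord
  ds_l <- call$donor_start; de_l <- call$donor_end
  ds <- call$donor_start_coord; de <- call$donor_end_coord
  mi_seq <- if (!is.null(call$micro_insert) &&
                !is.na(call$micro_insert$source_contig)) {
    src <- reference[[call$micro_insert$source_contig]]
    s <- contig_sub(src, call$micro_insert$ref_start, call$micro_insert$ref_end)
    if (identical(call$micro_insert$strand, "-")) revcomp(s) else s
  } else ""
  fmtc <- function(x) format(x, scientific = FALSE, trim = TRUE)

  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=insjunction",
    vapply(reference, function(ctg)
      sprintf("##contig=<ID=%s,length=%s>", ctg$name,
              fmtc(ctg$offset + ctg$length)), character(1)),
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"Mate breakend\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Inserted length\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
    "##INFO=<ID=HOMLEN,Number=1,Type=Integer,Description=\"Microhomology length\">",
    "##INFO=<ID=HOMSEQ,Number=1,Type=String,Description=\"Microhomology sequence\">",
    "##INFO=<ID=INSSEQ,Number=1,Type=String,Description=\"Junction micro-insert\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rb <- base_at(acc, b)
  rd1 <- base_at(don, ds_l)
  rd2 <- base_at(don, de_l)
  ra2 <- base_at(acc, b + 1)
  hom <- sprintf("HOMLEN=%d%s", call$microhomology$length,
                 if (call$microhomology$length > 0)
                   paste0(";HOMSEQ=", call$microhomology$sequence) else "")
  recs <- c(
    sprintf("%s\t%s\tbnd_P1\t%s\t%s[%s:%s[\t.\tPASS\tSVTYPE=BND;MATEID=bnd_P2;%s",
            acc$name, fmtc(bc), rb, rb, don$name, fmtc(ds), hom),
    sprintf("%s\t%s\tbnd_P2\t%s\t]%s:%s]%s\t.\tPASS\tSVTYPE=BND;MATEID=bnd_P1;%s",
            don$name, fmtc(ds), rd1, acc$name, fmtc(bc), rd1, hom),
    sprintf("%s\t%s\tbnd_D1\t%s\t%s%s[%s:%s[\t.\tPASS\tSVTYPE=BND;MATEID=bnd_D2%s",
            don$name, fmtc(de), rd2, rd2, mi_seq, acc$name, fmtc(bc + 1),
            if (nzchar(mi_seq)) paste0(";INSSEQ=", mi_seq) else ""),
    sprintf("%s\t%s\tbnd_D2\t%s\t]%s:%s]%s%s\t.\tPASS\tSVTYPE=BND;MATEID=bnd_D1%s",
            acc$name, fmtc(bc + 1), ra2, don$name, fmtc(de), mi_seq, ra2,
            if (nzchar(mi_seq)) paste0(";INSSEQ=", mi_seq) else ""),
    sprintf("%s\t%s\tins_1\t%s\t<INS>\t.\tPASS\tSVTYPE=INS;END=%s;SVLEN=%s",
            acc$name, fmtc(bc), rb, fmtc(bc), fmtc(call$inserted_length)))
  acc_band <- if (!is.null(bands)) bands[["acceptor"]] else ""
  don_band <- if (!is.null(bands)) bands[["donor"]] else ""
  notation <- sprintf("der(%s)dir ins(%s;%s)(%s;%s)",
                      acc$name, acc$name, don$name, acc_band, don_band)
  out <- list(vcf = c(hdr, recs), notation = notation)
  if (!is.null(path)) writeLines(out$vcf, path)
  out
}

#' Parse breakend records from a VCF
#'
#' Minimal reader used to round-trip the emitted call: returns the BND
#' records with their mate coordinates and bracket orientations.
#'
#' @param lines VCF text lines (or a file path).
#' @return data.frame `id`, `contig`, `pos`, `mate_id`, `mate_contig`,
#'   `mate_pos`, `orientation` (e.g. `"t["` / `"]t"`).
#' @export
read_vcf_bnd <- function(lines) {
  if (length(lines) == 1L && file.exists(lines)) lines <- readLines(lines)
  body <- lines[!startsWith(lines, "#")]
  f <- strsplit(body, "\t", fixed = TRUE)
  out <- list()
  for (r in f) {
    if (!grepl("SVTYPE=BND", r[8])) next
    alt <- r[5]
    m <- regmatches(alt, regexec("([][])([^:]+):([0-9]+)([][])", alt))[[1]]
    orientation <- if (grepl("^[][]", alt)) paste0(m[2], "t") else
      paste0("t", m[2])
    out[[length(out) + 1L]] <- data.frame(
      id = r[3], contig = r[1], pos = as.numeric(r[2]),
      mate_id = sub(".*MATEID=([^;]+).*", "\\1", r[8]),
      mate_contig = m[3], mate_pos = as.numeric(m[4]),
      orientation = orientation, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
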