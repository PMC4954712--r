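#' Build synthetic reference contigs
#'
#' Generates deterministic random reference contigs from a configuration, or
#' from the packaged preset `"cmtx3"`. Each contig carries an `offset` so that
#' local coordinates map onto genome-scale positions; the preset places the
#' acceptor insertion point at chrX-style coordinate 139,502,948 and the donor
#' segment start at 145,768,312 with segment length 77,856 bp. The preset
#' acceptor additionally carries a 180 bp palindrome (88 bp inverted-repeat
#' arms around a central non-palindromic TATC loop) spanning the insertion
#' point, emulating the hairpin-forming breakpoint context of the Xq27.1
#' insertion hotspot.
#'
#' @param config either the string `"cmtx3"` or a list with element `contigs`,
#'   itself a list of `list(name=, length=, offset=)` entries.
#' @param seed integer seed; mandatory, all randomness flows through it.
#' @return a `contig_set`.
#' @export
build_reference <- function(config = "cmtx3", seed) {
  if (identical(config, "cmtx3")) return(cmtx3_reference(seed))
  stopifnot(is.list(config), !is.null(config$contigs))
  specs <- config$contigs
  nm <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate contig names in config")
  offs <- vapply(specs, function(s) as.numeric(s$offset %||% 0), numeric(1))
  if (any(offs < 0)) stop("offsets must be non-negative (coordinates must stay positive)")
  with_seed(seed, {
    contig_set(lapply(specs, function(s) {
      contig(s$name, random_dna(s$length), s$offset %||% 0)
    }))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Geometry of the packaged cmtx3 preset (all coordinates genome-scale,
## realized on mini-contigs via offsets).
CMTX3 <- list(
  acceptor = "chrX_mini", donor = "chr8_mini", third = "chr12_mini",
  acceptor_len = 200000L, donor_len = 200000L, third_len = 5000L,
  acceptor_break = 139502948,           # insertion between this base and +1
  acceptor_offset = 139502948 - 100000, # local break at 100,000
  donor_start = 145768312,
  insert_len = 77856,                   # printed length, treated as authoritative
  donor_offset = 145768312 - 61000,     # local donor start at 61,000
  third_offset = 50258000,              # micro-insert source near 12q13.12
  micro_insert_start = 50260001,        # 19 bp fragment
  micro_insert_len = 19L,
  micro_insert_overlap = 10L,
  microhomology = 2L,
  inversion_len = 12L,
  snv_pos = 139502968, snv_ref = "T", snv_alt = "G",
  del_pos = 139502976, del_len = 1L,
  palindrome_start = 139502863,         # 88 + 4 (TATC) + 88 = 180 bp
  palindrome_arm = 88L,
  palindrome_loop = "TATC",
  bands = c(acceptor = "q27.1", donor = "q24.3")
)

#' The packaged cmtx3 junction specification
#'
#' @return a `junction_spec` describing the preset rearrangement: 2 bp
#'   proximal microhomology, a 19 bp third-chromosome micro-insert whose first
#'   10 bp overlap the donor end, a 12 bp acceptor inversion at the distal
#'   junction, one junction SNV (T>G) and one 1 bp deletion.
#' @export
cmtx3_spec <- function() {
  p <- CMTX3
  junction_spec(
    acceptor_contig = p$acceptor,
    acceptor_break = p$acceptor_break,
    donor_contig = p$donor,
    donor_segment = genomic_interval(p$donor, p$donor_start,
                                     p$donor_start + p$insert_len - 1),
    donor_orientation = "+",
    proximal_microhomology_len = p$microhomology,
    micro_insert = list(
      source = genomic_interval(p$third, p$micro_insert_start,
                                p$micro_insert_start + p$micro_insert_len - 1),
      length = p$micro_insert_len,
      overlap_with_donor = p$micro_insert_overlap),
    acceptor_inversion_len = p$inversion_len,
    junction_snv = list(pos = p$snv_pos, ref = p$snv_ref, alt = p$snv_alt),
    junction_deletion = list(pos = p$del_pos, len = p$del_len)
  )
}

## Build the preset reference. The acceptor left palindrome arm is laid out
## first; bases whose right-arm images are constrained (SNV reference base,
## literal "AA" microhomology, junction guard bases) are fixed on the left arm
## before the right arm is filled in as its reverse complement, so the
## palindrome stays intact while every planted junction length is exactly
## maximal.
cmtx3_reference <- function(seed) {
  p <- CMTX3
  refs <- with_seed(seed, {
    list(acc = strsplit(random_dna(p$acceptor_len), "")[[1]],
         don = random_dna(p$donor_len),
         thr = random_dna(p$third_len),
         picks = sample(DNA_BASES, 64, replace = TRUE))
  })
  acc <- refs$acc
  pick_not <- local({
    i <- 0L
    function(excl) {
      cand <- setdiff(DNA_BASES, excl)
      i <<- i + 1L
      cand[1L + (which(DNA_BASES == refs$picks[i]) %% length(cand))]
    }
  })
  b <- p$acceptor_break - p$acceptor_offset            # local 100,000
  ps <- p$palindrome_start - p$acceptor_offset         # local palindrome start
  arm <- p$palindrome_arm
  loop <- strsplit(p$palindrome_loop, "")[[1]]
  loop_s <- ps + arm                                   # local loop start
  pe <- ps + 2L * arm + length(loop) - 1L              # local palindrome end
  pair_sum <- ps + pe                                  # partner(l) = pair_sum - l

  ## literal proximal microhomology "AA" at the acceptor end
  acc[(b - 1):b] <- c("A", "A")
  ## SNV reference base 'T' lives on the right arm: plant its partner
  snv_l <- p$snv_pos - p$acceptor_offset
  acc[pair_sum - snv_l] <- comp_base(p$snv_ref)        # image base -> 'T'
  ## guard: base after the inverted block must not extend the fold-back
  ## (A[b+inv+1] != comp(A[b]))
  g1 <- pair_sum - (b + p$inversion_len + 1L)
  if (comp_base(acc[g1]) == comp_base(acc[b])) acc[g1] <- pick_not(acc[b])
  ## guard: A[b+inv] != comp(A[b+1])
  g2 <- pair_sum - (b + p$inversion_len)
  if (comp_base(acc[g2]) == comp_base(acc[b + 1L])) acc[g2] <- pick_not(acc[b + 1L])
  ## guard: unambiguous 1 bp deletion (A[del] != A[del+1])
  dl <- p$del_pos - p$acceptor_offset
  i1 <- pair_sum - dl; i0 <- pair_sum - (dl + 1L)
  if (acc[i1] == acc[i0]) acc[i1] <- pick_not(acc[i0])
  ## loop and right arm
  acc[loop_s:(loop_s + length(loop) - 1L)] <- loop
  acc[(loop_s + length(loop)):pe] <- comp_base(acc[(loop_s - 1L):ps])
  ## palindrome arms maximal: flanking bases must not pair
  if (acc[ps - 1L] == comp_base(acc[pe + 1L]))
    acc[ps - 1L] <- pick_not(comp_base(acc[pe + 1L]))

  contig_set(
    contig(p$acceptor, paste(acc, collapse = ""), p$acceptor_offset),
    contig(p$donor, refs$don, p$donor_offset),
    contig(p$third, refs$thr, p$third_offset)
  )
}

set_bases <- function(seqstr, at, values) {
  ch <- strsplit(seqstr, "")[[1]]
  ch[at] <- values
  paste(ch, collapse = "")
}

## pick a base different from all of `excl`, deterministically (first in
## alphabet order); used for guard edits inside build_mutant_haplotype
base_not <- function(excl) setdiff(DNA_BASES, excl)[1]

#' Build the mutant (insertion-carrying) acceptor haplotype
#'
#' Concatenates acceptor prefix, oriented donor segment, micro-insert tail,
#' inverted acceptor block and acceptor remainder (with junction SNV and
#' deletion applied), realizing the junction specification. Planted homologies
#' are written into the reference (`harmonize = TRUE`): the donor start is
#' edited to share the microhomology bases with the acceptor end, and the
#' micro-insert source start is edited to share its overlap bases with the
#' donor end. The microhomology is carried once at the junction (that single
#' shared copy is what makes the breakpoint assignment ambiguous), so the
#' haplotype length is
#' `acceptor + donor + (micro_insert - overlap) - deletion - microhomology`.
#'
#' Reference bases immediately flanking every planted boundary are edited,
#' when needed, so that each planted homology/segment length is exactly
#' maximal: without those guard bases a random genome would extend a planted
#' length with probability ~1/4 per boundary and exact parameter recovery
#' would be impossible by construction.
#'
#' @param reference a `contig_set`.
#' @param spec a `junction_spec` whose coordinates lie within `reference`.
#' @param name name for the mutant contig.
#' @param harmonize edit reference bases to realize homologies and guards
#'   (default TRUE). With FALSE the reference is used as-is.
#' @return list with `haplotype` (a `contig`), `reference` (the possibly
#'   edited `contig_set`), and `truth` (the spec plus a segment map from
#'   haplotype coordinates back to reference genome coordinates).
#' @export
build_mutant_haplotype <- function(reference, spec, name = NULL,
                                   harmonize = TRUE) {
  stopifnot(inherits(spec, "junction_spec"))
  for (cn in c(spec$acceptor_contig, spec$donor_contig,
               if (!is.null(spec$micro_insert)) spec$micro_insert$source$contig))
    if (!cn %in% names(reference))
      stop("spec references unknown contig: ", cn)

  accc <- reference[[spec$acceptor_contig]]
  donc <- reference[[spec$donor_contig]]
  acc <- strsplit(accc$sequence, "")[[1]]
  don <- strsplit(donc$sequence, "")[[1]]
  b <- spec$acceptor_break - accc$offset
  ds <- spec$donor_segment$start - donc$offset
  de <- spec$donor_segment$end - donc$offset
  if (b < 1 || b >= length(acc)) stop("acceptor break outside contig")
  if (ds < 1 || de > length(don)) stop("donor segment outside contig")
  DL <- de - ds + 1L
  uh <- spec$proximal_microhomology_len
  inv <- spec$acceptor_inversion_len
  minus <- identical(spec$donor_orientation, "-")
  mi <- spec$micro_insert
  milen <- if (is.null(mi)) 0L else mi$length
  ov <- if (is.null(mi)) 0L else mi$overlap_with_donor
  if (milen > 0 && ov > milen - 1L)
    stop("micro-insert overlap must leave at least 1 unshared base")
  if (DL <= uh + ov + 2L) stop("donor segment too short for the requested homologies")
  if (b - uh < 1) stop("acceptor too short for the requested microhomology")
  if (b + inv + 1L > length(acc)) stop("inversion extends past the acceptor end")

  ## oriented donor accessors: insert position j (1..DL along insert direction)
  ins_idx <- function(j) if (minus) de - j + 1L else ds + j - 1L
  ins_get <- function(j) {
    i <- ins_idx(j)
    if (i < 1 || i > length(don)) return(NA_character_)
    if (minus) comp_base(don[i]) else don[i]
  }
  ins_set <- function(j, base) {
    i <- ins_idx(j)
    don[i] <<- if (minus) comp_base(base) else base
  }

  thr <- NULL; mi_s <- mi_e <- NA_integer_
  if (milen > 0) {
    thrc <- reference[[mi$source$contig]]
    thr <- strsplit(thrc$sequence, "")[[1]]
    mi_s <- mi$source$start - thrc$offset
    mi_e <- mi$source$end - thrc$offset
    if (mi_s < 1 || mi_e > length(thr)) stop("micro-insert source outside contig")
  }

  snv <- spec$junction_snv; del <- spec$junction_deletion
  snv_l <- if (is.null(snv)) NA else snv$pos - accc$offset
  del_l <- if (is.null(del)) NA else del$pos - accc$offset
  del_n <- if (is.null(del)) 0L else del$len
  if (!is.null(snv) && snv_l <= b + inv + 1L)
    stop("junction SNV must lie distal to the inverted block")
  if (!is.null(del) && del_l <= b + inv + 1L)
    stop("junction deletion must lie distal to the inverted block")

  if (harmonize) {
    ## realize homologies
    if (uh > 0) for (i in seq_len(uh)) ins_set(i, acc[b - uh + i])
    if (ov > 0) for (i in seq_len(ov)) thr[mi_s + i - 1L] <- ins_get(DL - ov + i)
    ## acceptor-side inversion guards
    if (inv >= 1) {
      if (acc[b + inv + 1L] == comp_base(acc[b]))
        acc[b + inv + 1L] <- base_not(c(comp_base(acc[b]),
                                        if (!is.null(snv) && snv_l == b + inv + 1L) NA))
      if (inv >= 2 && acc[b + inv] == comp_base(acc[b + 1L]))
        acc[b + inv] <- base_not(comp_base(acc[b + 1L]))
    }
    ## SNV reference base
    if (!is.null(snv) && acc[snv_l] != snv$ref) acc[snv_l] <- snv$ref
    ## deletion boundary guard (unique leftmost placement)
    if (!is.null(del) && del_l + del_n <= length(acc) &&
        all(acc[del_l:(del_l + del_n - 1L)] == acc[del_l + del_n]))
      acc[del_l + del_n] <- base_not(acc[del_l])

    ## boundary guards: each planted length must be exactly maximal
    first_after_donor <-
      if (milen - ov > 0) thr[mi_s + ov] else if (inv > 0) comp_base(acc[b + inv]) else acc[b + inv + 1L]
    if (ins_idx(DL + 1L) >= 1 && ins_idx(DL + 1L) <= length(don) &&
        ins_get(DL + 1L) == first_after_donor)
      ins_set(DL + 1L, base_not(first_after_donor))
    g1 <- ins_get(uh + 1L)
    if (!is.na(g1) && g1 %in% c(acc[b], acc[b + 1L]))
      ins_set(uh + 1L, base_not(c(acc[b], acc[b + 1L])))
    g2 <- ins_get(0L)
    if (!is.na(g2) && g2 == acc[b - uh] && b - uh >= 1)
      ins_set(0L, base_not(acc[b - uh]))
    if (milen > 0) {
      if (mi_s - 1L >= 1 && DL - ov >= 1 && thr[mi_s - 1L] == ins_get(DL - ov))
        thr[mi_s - 1L] <- base_not(ins_get(DL - ov))
      after_mi <- if (inv > 0) comp_base(acc[b + inv]) else acc[b + inv + 1L]
      if (mi_e + 1L <= length(thr) && thr[mi_e + 1L] == after_mi)
        thr[mi_e + 1L] <- base_not(after_mi)
      if (inv > 0 && thr[mi_e] == comp_base(acc[b + inv + 1L]))
        thr[mi_e] <- base_not(comp_base(acc[b + inv + 1L]))
      ## without an inversion the acceptor remainder directly follows the
      ## micro-insert; stop its match from creeping left into the insert and
      ## from mimicking a 1 bp fold-back of the acceptor end
      if (inv == 0 && thr[mi_e] %in% c(acc[b], comp_base(acc[b])))
        thr[mi_e] <- base_not(c(acc[b], comp_base(acc[b])))
    } else if (inv > 0) {
      ## donor end directly abuts the inverted block
      if (ins_get(DL) == comp_base(acc[b + inv + 1L]))
        ins_set(DL, base_not(c(comp_base(acc[b + inv + 1L]), first_after_donor)))
    }
  }

  ## assemble the haplotype
  left <- acc[1:b]
  donor_part <- vapply((uh + 1L):DL, ins_get, character(1))
  mi_part <- if (milen - ov > 0) thr[(mi_s + ov):mi_e] else character(0)
  inv_part <- if (inv > 0) rev(comp_base(acc[(b + 1L):(b + inv)])) else character(0)
  right <- acc[(b + inv + 1L):length(acc)]
  if (!is.null(snv)) right[snv_l - (b + inv)] <- snv$alt
  if (!is.null(del)) right <- right[-((del_l - (b + inv)):(del_l - (b + inv) + del_n - 1L))]
  hap_seq <- paste(c(left, donor_part, mi_part, inv_part, right), collapse = "")

  exp_len <- length(acc) + DL - uh + (milen - ov) - del_n
  stopifnot(nchar(hap_seq) == exp_len)

  ## segment map: haplotype coordinates -> reference genome coordinates
  segs <- list()
  add_seg <- function(h1, h2, ctg, r1, r2, strand, role) {
    if (h2 < h1) return(invisible())
    segs[[length(segs) + 1L]] <<- data.frame(
      hap_start = h1, hap_end = h2, contig = ctg,
      ref_start = r1, ref_end = r2, strand = strand, role = role,
      stringsAsFactors = FALSE)
  }
  ## reference coordinates in the map are contig-local (1-based); genome-scale
  ## positions are recovered downstream via each contig's offset
  add_seg(1, b, accc$name, 1, b, "+", "acceptor_left")
  h <- b
  if (minus) {
    add_seg(h + 1, h + DL - uh, donc$name, ds, de - uh, "-", "donor")
  } else {
    add_seg(h + 1, h + DL - uh, donc$name, ds + uh, de, "+", "donor")
  }
  h <- h + DL - uh
  if (milen - ov > 0) {
    add_seg(h + 1, h + milen - ov, mi$source$contig, mi_s + ov, mi_e, "+",
            "micro_insert")
    h <- h + (milen - ov)
  }
  if (inv > 0) {
    add_seg(h + 1, h + inv, accc$name, b + 1, b + inv, "-", "inverted_acceptor")
    h <- h + inv
  }
  if (is.null(del)) {
    add_seg(h + 1, exp_len, accc$name, b + inv + 1, length(acc), "+",
            "acceptor_right")
  } else {
    n1 <- del_l - 1L - (b + inv)        # bases before the deletion
    add_seg(h + 1, h + n1, accc$name, b + inv + 1, del_l - 1, "+",
            "acceptor_right")
    add_seg(h + n1 + 1, exp_len, accc$name, del_l + del_n, length(acc), "+",
            "acceptor_right")
  }
  seg_map <- do.call(rbind, segs)

  new_ref <- reference
  new_ref[[spec$acceptor_contig]] <- contig(accc$name, paste(acc, collapse = ""),
                                            accc$offset)
  new_ref[[spec$donor_contig]] <- contig(donc$name, paste(don, collapse = ""),
                                         donc$offset)
  if (milen > 0)
    new_ref[[mi$source$contig]] <- contig(mi$source$contig,
                                          paste(thr, collapse = ""),
                                          reference[[mi$source$contig]]$offset)
  class(new_ref) <- "contig_set"

  hap_name <- name %||% paste0(accc$name, "_ins")
  list(haplotype = contig(hap_name, hap_seq, 0),
       reference = new_ref,
       truth = list(spec = spec, segments = seg_map, haplotype = hap_name))
}

#' Identity truth map for a wild-type haplotype
#'
#' @param ctg a reference `contig` used unchanged as a haplotype.
#' @param name optional haplotype name.
#' @return truth list with a single full-length segment.
#' @export
wildtype_truth <- function(ctg, name = NULL) {
  nm <- name %||% ctg$name
  list(spec = NULL,
       segments = data.frame(
         hap_start = 1, hap_end = ctg$length, contig = ctg$name,
         ref_start = 1, ref_end = ctg$length,
         strand = "+", role = "reference", stringsAsFactors = FALSE),
       haplotype = nm)
}
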