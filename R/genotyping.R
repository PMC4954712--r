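#' Derive a junction spec from a resolved insertion call
#'
#' Lets downstream assay design rebuild the derivative (mutant) haplotype
#' from a call plus the reference, without access to the generator's truth.
#'
#' @param call an `insertion_call`.
#' @return a `junction_spec`.
#' @export
call_to_spec <- function(call) {
  snvs <- call$variants[call$variants$type == "snv", , drop = FALSE]
  dels <- call$variants[call$variants$type == "del", , drop = FALSE]
  mi <- call$micro_insert
  junction_spec(
    acceptor_contig = call$acceptor_contig,
    acceptor_break = call$acceptor_break_coord,
    donor_contig = call$donor_contig,
    donor_segment = genomic_interval(call$donor_contig,
                                     call$donor_start_coord,
                                     call$donor_end_coord),
    donor_orientation = call$donor_orientation,
    proximal_microhomology_len = call$microhomology$length,
    micro_insert = if (!is.null(mi) && !is.na(mi$source_contig))
      list(source = genomic_interval(mi$source_contig,
                                     mi$coord_start, mi$coord_end),
           length = mi$length, overlap_with_donor = mi$overlap_with_donor)
      else NULL,
    acceptor_inversion_len = call$inversion$length,
    junction_snv = if (nrow(snvs))
      list(pos = snvs$coord[1], ref = snvs$ref[1], alt = snvs$alt[1]) else NULL,
    junction_deletion = if (nrow(dels))
      list(pos = dels$coord[1], len = dels$len[1]) else NULL)
}

#' Place a multiplex genotyping assay from target product sizes
#'
#' Solves four primer sites around a resolved insertion so that (i) the
#' acceptor forward/reverse pair spans the insertion point and yields the
#' wild-type product on the unrearranged haplotype, (ii) acceptor-forward
#' with a donor-internal reverse primer crosses the proximal junction at the
#' requested size, and (iii) a donor-internal forward primer with
#' acceptor-reverse crosses the distal junction at the requested size. Site
#' offsets are solved exactly from the size specification and verified by
#' in-silico PCR on both haplotypes.
#'
#' @param call an `insertion_call` or `junction_spec`.
#' @param reference `contig_set` consistent with the call.
#' @param size_spec named numeric vector
#'   `c(wild_type=, proximal_junction=, distal_junction=)` of target product
#'   lengths (bp).
#' @param primer_len primer length (default 21 nt).
#' @param max_product largest amplifiable product (default 2000 bp).
#' @return list of class `pcr_assay`: `$primers` (data.frame `name`,
#'   `sequence`, `template_side`), `$size_spec`, `$wild`, `$mutant` (the two
#'   template contigs), `$sites` (solved site coordinates).
#' @export
place_assay <- function(call, reference,
                        size_spec = c(wild_type = 340, proximal_junction = 595,
                                      distal_junction = 235),
                        primer_len = 21L, max_product = 2000L) {
  stopifnot(all(c("wild_type", "proximal_junction", "distal_junction") %in%
                  names(size_spec)))
  wl <- size_spec[["wild_type"]]
  pp <- size_spec[["proximal_junction"]]
  dp <- size_spec[["distal_junction"]]
  if (wl < 2 * primer_len + 2)
    stop("wild-type product must exceed twice the primer length")
  if (pp < 2 * primer_len + 2 || dp < 2 * primer_len + 2)
    stop("junction products must exceed twice the primer length")
  spec <- if (inherits(call, "insertion_call")) call_to_spec(call) else call
  stopifnot(inherits(spec, "junction_spec"))
  der <- build_mutant_haplotype(reference, spec, name = "derivative",
                                harmonize = FALSE)
  acc <- reference[[spec$acceptor_contig]]
  H <- der$haplotype
  segs <- der$truth$segments
  b <- spec$acceptor_break - acc$offset
  donor_rows <- segs[segs$role == "donor", ]
  don_h1 <- donor_rows$hap_start[1]; don_h2 <- donor_rows$hap_end[1]

  ## wild-type amplicon centered on the insertion point
  f <- b - floor(wl / 2) + 1L
  r <- f + wl - 1L
  if (f < 1 || r > acc$length) stop("insertion point too close to contig end")
  if (r - primer_len + 1L <= b)
    stop("wild-type product too short to place the reverse primer distal to the break")
  ## acceptor-reverse site must also bind the derivative (outside inverted /
  ## variant-bearing bases); locate it on the derivative
  accR_h <- hap_pos_of(segs, spec$acceptor_contig, (r - primer_len + 1L):r)
  if (anyNA(accR_h) || any(diff(accR_h) != 1L))
    stop("acceptor reverse-primer site is disrupted on the derivative; widen size_spec")

  ## proximal junction product: acc.F ... donor-internal reverse
  hp <- f + pp - 1L                      # derivative position of don.R 3' end
  if (hp - primer_len + 1L <= b || hp > don_h2)
    stop("donor segment shorter than required internal-primer offsets")
  ## distal junction product: donor-internal forward ... acc.R
  hr <- accR_h[primer_len]               # derivative position of acc.R site end
  hf <- hr - dp + 1L                     # derivative position of don.F site start
  if (hf < don_h1 || hf + primer_len - 1L > don_h2)
    stop("donor segment shorter than required internal-primer offsets")

  primers <- data.frame(
    name = c("acc.F", "acc.R", "don.F", "don.R"),
    sequence = c(contig_sub(acc, f, f + primer_len - 1L),
                 revcomp(contig_sub(acc, r - primer_len + 1L, r)),
                 contig_sub(H, hf, hf + primer_len - 1L),
                 revcomp(contig_sub(H, hp - primer_len + 1L, hp))),
    template_side = c("acceptor_left", "acceptor_right", "donor_end",
                      "donor_start"),
    stringsAsFactors = FALSE)
  assay <- structure(list(primers = primers, size_spec = size_spec,
                          wild = acc, mutant = H,
                          sites = list(acc_f = f, acc_r = r, don_f_hap = hf,
                                       don_r_hap = hp)),
                     class = "pcr_assay")
  ## solve-then-verify: the placed sites must reproduce the requested sizes
  wt <- insilico_pcr(list(wild = acc), primers, max_product)
  mu <- insilico_pcr(list(mutant = H), primers, max_product)
  if (!setequal(wt$length, wl) ||
      !setequal(mu$length, c(pp, dp)))
    stop("placed assay failed in-silico verification (ambiguous primer sites)")
  assay
}

## derivative positions of given contig-local reference positions (plus
## strand segments only); NA when not representable
hap_pos_of <- function(segs, ctg, ref_pos) {
  out <- rep(NA_real_, length(ref_pos))
  plus <- segs[segs$contig == ctg & segs$strand == "+", , drop = FALSE]
  for (i in seq_len(nrow(plus))) {
    sel <- ref_pos >= plus$ref_start[i] & ref_pos <= plus$ref_end[i]
    out[sel] <- plus$hap_start[i] + (ref_pos[sel] - plus$ref_start[i])
  }
  out
}

#' In-silico multiplex PCR
#'
#' Binds every primer by exact full-length match (forward on the plus strand,
#' reverse as its reverse complement downstream) and reports every convergent
#' placement with a product of at most `max_product` bp. The product length
#' convention is inclusive of both primer 5' ends, matching gel sizes.
#'
#' @param templates named list of `contig`s (or plain sequences) amplified
#'   together, e.g. a sample's haplotypes.
#' @param primers data.frame with `name` and `sequence`.
#' @param max_product largest product reported (default 2000 bp).
#' @return data.frame `template`, `fwd_primer`, `rev_primer`, `start`, `end`,
#'   `length`.
#' @export
insilico_pcr <- function(templates, primers, max_product = 2000L) {
  if (inherits(templates, "contig")) templates <- list(templates)
  if (is.null(names(templates)))
    names(templates) <- vapply(templates, function(t)
      if (inherits(t, "contig")) t$name else "template", character(1))
  out <- list()
  for (tn in names(templates)) {
    tpl <- templates[[tn]]
    seqstr <- if (inherits(tpl, "contig")) tpl$sequence else as.character(tpl)
    subj <- Biostrings::DNAString(seqstr)
    fwd <- list(); rev <- list()
    for (i in seq_len(nrow(primers))) {
      p <- primers$sequence[i]
      fs <- Biostrings::start(Biostrings::matchPattern(Biostrings::DNAString(p), subj))
      rs <- Biostrings::start(Biostrings::matchPattern(
        Biostrings::reverseComplement(Biostrings::DNAString(p)), subj))
      if (length(fs))
        fwd[[length(fwd) + 1L]] <- data.frame(primer = primers$name[i],
                                              start = fs, plen = nchar(p))
      if (length(rs))
        rev[[length(rev) + 1L]] <- data.frame(primer = primers$name[i],
                                              end = rs + nchar(p) - 1L,
                                              plen = nchar(p))
    }
    if (!length(fwd) || !length(rev)) next
    fwd <- do.call(rbind, fwd); rev <- do.call(rbind, rev)
    for (i in seq_len(nrow(fwd))) for (j in seq_len(nrow(rev))) {
      len <- rev$end[j] - fwd$start[i] + 1L
      if (len >= fwd$plen[i] + rev$plen[j] && len <= max_product)
        out[[length(out) + 1L]] <- data.frame(
          template = tn, fwd_primer = fwd$primer[i], rev_primer = rev$primer[j],
          start = fwd$start[i], end = rev$end[j], length = len,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(template = character(0), fwd_primer = character(0),
                      rev_primer = character(0), start = numeric(0),
                      end = numeric(0), length = numeric(0)))
  do.call(rbind, out)
}

#' Label amplicons by product size
#'
#' Matches each product length against the assay size specification, the same
#' reading a gel lane gives.
#'
#' @param amplicons output of [insilico_pcr()].
#' @param size_spec named product-size vector (see [place_assay()]).
#' @return the amplicons with a `span` column (`wild_type`,
#'   `proximal_junction`, `distal_junction` or `other`).
#' @export
label_amplicons <- function(amplicons, size_spec) {
  m <- match(amplicons$length, size_spec)
  amplicons$span <- ifelse(is.na(m), "other", names(size_spec)[m])
  amplicons
}

#' Genotype call from an amplicon set
#'
#' Implements the multiplex-assay genotype logic: a single wild-type product
#' marks a non-carrier (hemizygous male or homozygous female); the two
#' junction-crossing products without the wild-type product mark an affected
#' hemizygous male; all three products mark a carrier female; any other
#' combination is inconsistent.
#'
#' @param amplicons labelled amplicons (see [label_amplicons()]), or a
#'   character vector of span labels.
#' @param sex `"male"` or `"female"`.
#' @return character: `non_carrier`, `affected_hemizygous`, `carrier_female`
#'   or `inconsistent`.
#' @export
call_genotype <- function(amplicons, sex) {
  spans <- if (is.data.frame(amplicons)) amplicons$span else amplicons
  s <- sort(unique(spans))
  if (identical(s, "wild_type")) return("non_carrier")
  if (sex == "male" &&
      identical(s, sort(c("proximal_junction", "distal_junction"))))
    return("affected_hemizygous")
  if (sex == "female" &&
      identical(s, sort(c("wild_type", "proximal_junction",
                          "distal_junction"))))
    return("carrier_female")
  "inconsistent"
}

#' Genotype a simulated cohort with a placed assay
#'
#' Each sample's template set is its X haplotypes (mutant copies plus
#' wild-type copies); the multiplex reaction is run in silico and the
#' genotype called from the labelled products.
#'
#' @param cohort output of [simulate_cohort()].
#' @param assay a `pcr_assay` from [place_assay()].
#' @param max_product largest product reported (default 2000 bp).
#' @return data.frame `sample_id`, `sex`, `affection`, `genotype`,
#'   `amplicons` (comma-separated product sizes).
#' @export
genotype_cohort <- function(cohort, assay, max_product = 2000L) {
  out <- lapply(seq_len(nrow(cohort)), function(i) {
    s <- cohort[i, ]
    tpl <- c(rep(list(assay$mutant), s$carrier_alleles),
             rep(list(assay$wild), s$n_x - s$carrier_alleles))
    names(tpl) <- sprintf("X%d", seq_along(tpl))
    amps <- insilico_pcr(tpl, assay$primers, max_product)
    amps <- label_amplicons(amps, assay$size_spec)
    data.frame(sample_id = s$sample_id, sex = s$sex, affection = s$affection,
               genotype = call_genotype(amps, s$sex),
               amplicons = paste(sort(unique(amps$length)), collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Segregation concordance under an X-linked model
#'
#' Counts samples whose genotype matches their clinical status under
#' X-linked inheritance (affected males must be hemizygous carriers,
#' unaffected males non-carriers, carrier females heterozygous; female
#' carriers are considered asymptomatic) and audits parent-child
#' transmission: a male mutant genotype with a non-carrier listed mother is a
#' male-to-male transmission violation.
#'
#' @param genotypes output of [genotype_cohort()].
#' @param pedigree pedigree data.frame (`id`, `father`, `mother`); NULL for a
#'   founder-only cohort.
#' @return list `n`, `concordant`, `discordant`, `discordant_ids`,
#'   `transmission_violations`.
#' @export
segregation_check <- function(genotypes, pedigree = NULL) {
  if (!nrow(genotypes))
    return(list(n = 0L, concordant = 0L, discordant = 0L,
                discordant_ids = character(0),
                transmission_violations = character(0)))
  expected <- ifelse(
    genotypes$affection == "affected" & genotypes$sex == "male",
    "affected_hemizygous",
    ifelse(genotypes$affection == "carrier" & genotypes$sex == "female",
           "carrier_female", "non_carrier"))
  ok <- genotypes$genotype == expected
  viol <- character(0)
  if (!is.null(pedigree) && nrow(pedigree)) {
    check_pedigree_acyclic(pedigree)
    carrier_calls <- c("affected_hemizygous", "carrier_female")
    gmap <- setNames(genotypes$genotype, genotypes$sample_id)
    for (i in seq_len(nrow(pedigree))) {
      id <- pedigree$id[i]; mo <- pedigree$mother[i]
      if (!nzchar(mo %||% "") || is.na(mo)) next
      if (!id %in% names(gmap) || !mo %in% names(gmap)) next
      if (gmap[[id]] %in% carrier_calls && !gmap[[mo]] %in% carrier_calls)
        viol <- c(viol, id)
    }
  }
  list(n = nrow(genotypes), concordant = sum(ok), discordant = sum(!ok),
       discordant_ids = genotypes$sample_id[!ok],
       transmission_violations = viol)
}

check_pedigree_acyclic <- function(pedigree) {
  parents <- function(id) {
    r <- pedigree[pedigree$id == id, ]
    if (!nrow(r)) return(character(0))
    p <- c(r$father[1], r$mother[1])
    p[!is.na(p) & nzchar(p)]
  }
  for (id in pedigree$id) {
    seen <- character(0); frontier <- parents(id)
    while (length(frontier)) {
      if (id %in% frontier) stop("pedigree contains a cycle involving ", id)
      seen <- union(seen, frontier)
      frontier <- setdiff(unique(unlist(lapply(frontier, parents))), seen)
    }
  }
  invisible(TRUE)
}

#' Control-panel screening report
#'
#' Counts X chromosomes screened (two per female, one per male) and carrier
#' X chromosomes found.
#'
#' @param genotypes output of [genotype_cohort()] for the control panel.
#' @return list `n_female`, `n_male`, `x_chromosomes`, `carrier_x`.
#' @export
screen_panel <- function(genotypes) {
  nf <- sum(genotypes$sex == "female")
  nm <- sum(genotypes$sex == "male")
  carrier_x <- sum(genotypes$genotype == "carrier_female") +
    sum(genotypes$genotype == "affected_hemizygous")
  list(n_female = nf, n_male = nm, x_chromosomes = 2L * nf + nm,
       carrier_x = carrier_x)
}
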