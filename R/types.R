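#' @importFrom stats rnorm runif sd t.test setNames aggregate
#' @importFrom utils read.delim write.table head tail
NULL

.datatable.aware <- TRUE

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' Plain-character convenience wrapper (A/C/G/T only) used throughout the
#' package where full `Biostrings` objects would be overhead.
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  out <- chartr("ACGT", "TGCA", x)
  vapply(strsplit(out, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

comp_base <- function(x) chartr("ACGT", "TGCA", x)

#' Construct a contig
#'
#' A contig is a named DNA sequence plus a coordinate offset: local base `i`
#' (1-based) has genome coordinate `offset + i`. This lets desk-scale
#' mini-contigs carry genome-scale (hg19-style) positions.
#'
#' @param name contig label, e.g. `"chrX_mini"`.
#' @param sequence DNA string over A/C/G/T.
#' @param offset non-negative integer coordinate offset.
#' @return an object of class `contig` with fields `name`, `sequence`,
#'   `offset`, `length`.
#' @export
contig <- function(name, sequence, offset = 0) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  sequence <- toupper(as.character(sequence))
  if (nchar(sequence) < 1L) stop("contig sequence must have length >= 1")
  if (grepl("[^ACGT]", sequence)) stop("contig alphabet restricted to A/C/G/T")
  offset <- as.numeric(offset)
  if (is.na(offset) || offset < 0) stop("offset must be non-negative")
  structure(list(name = name, sequence = sequence, offset = offset,
                 length = nchar(sequence)),
            class = "contig")
}

#' @export
print.contig <- function(x, ...) {
  cat(sprintf("<contig %s: %d bp, offset %s>\n", x$name, x$length,
              format(x$offset, big.mark = ",", scientific = FALSE)))
  invisible(x)
}

#' Bundle contigs into a reference set
#'
#' @param ... `contig` objects.
#' @return named list of contigs, class `contig_set`.
#' @export
contig_set <- function(...) {
  contigs <- list(...)
  if (length(contigs) == 1L && is.list(contigs[[1]]) &&
      !inherits(contigs[[1]], "contig")) {
    contigs <- contigs[[1]]
  }
  stopifnot(all(vapply(contigs, inherits, logical(1), "contig")))
  nm <- vapply(contigs, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate contig names: ",
                              paste(nm[duplicated(nm)], collapse = ", "))
  names(contigs) <- nm
  class(contigs) <- "contig_set"
  contigs
}

#' @export
`[.contig_set` <- function(x, i) {
  out <- unclass(x)[i]
  class(out) <- "contig_set"
  out
}

## genome coordinate <-> local position helpers
local_pos <- function(ctg, genome_pos) genome_pos - ctg$offset
genome_pos <- function(ctg, local) ctg$offset + local

contig_sub <- function(ctg, from, to) {
  stopifnot(from >= 1, to <= ctg$length, from <= to)
  substr(ctg$sequence, from, to)
}

#' Construct a genomic interval
#'
#' 1-based, inclusive on both ends (matching hg19-style positions as printed
#' in the literature); conversion to 0-based half-open happens only at BED
#' export.
#'
#' @param contig contig label.
#' @param start,end 1-based inclusive genome coordinates, `start <= end`.
#' @param strand `"+"` or `"-"`.
#' @return list of class `genomic_interval` with an extra `length` field.
#' @export
genomic_interval <- function(contig, start, end, strand = "+") {
  start <- as.numeric(start); end <- as.numeric(end)
  if (is.na(start) || is.na(end) || start > end)
    stop("invalid interval: need start <= end")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  structure(list(contig = contig, start = start, end = end, strand = strand,
                 length = end - start + 1),
            class = "genomic_interval")
}

intervals_overlap <- function(a, b) {
  a$contig == b$contig && a$start <= b$end && b$start <= a$end
}

#' Describe a planted rearrangement junction
#'
#' Full description of an interchromosomal insertion with the junction
#' micro-architecture seen at MMBIR/FoSTeS-repaired breakpoints: proximal
#' microhomology shared by acceptor and donor, an optional short micro-insert
#' from a third contig whose first bases overlap the donor end, an optional
#' short inversion of acceptor sequence immediately distal to the insertion,
#' and optional junction-adjacent SNV / single-base deletion.
#'
#' @param acceptor_contig,donor_contig contig labels.
#' @param acceptor_break genome coordinate on the acceptor after which the
#'   insertion occurs (insert sits between `acceptor_break` and
#'   `acceptor_break + 1`).
#' @param donor_segment `genomic_interval` on the donor contig.
#' @param donor_orientation `"+"` or `"-"` orientation of the inserted copy.
#' @param proximal_microhomology_len bases shared by acceptor end and donor
#'   start (single physical copy at the junction).
#' @param micro_insert `NULL` or list(`source` = genomic_interval on a third
#'   contig, `length`, `overlap_with_donor`).
#' @param acceptor_inversion_len bases of acceptor sequence inverted
#'   immediately distal to the junction.
#' @param junction_snv `NULL` or list(`pos`, `ref`, `alt`) on the acceptor.
#' @param junction_deletion `NULL` or list(`pos`, `len`) on the acceptor.
#' @return object of class `junction_spec`.
#' @export
junction_spec <- function(acceptor_contig, acceptor_break,
                          donor_contig, donor_segment,
                          donor_orientation = "+",
                          proximal_microhomology_len = 0,
                          micro_insert = NULL,
                          acceptor_inversion_len = 0,
                          junction_snv = NULL,
                          junction_deletion = NULL) {
  stopifnot(inherits(donor_segment, "genomic_interval"))
  if (donor_segment$length < 1) stop("donor segment must be >= 1 bp")
  if (proximal_microhomology_len < 0) stop("microhomology length must be >= 0")
  if (acceptor_inversion_len < 0) stop("inversion length must be >= 0")
  if (!is.null(micro_insert)) {
    stopifnot(inherits(micro_insert$source, "genomic_interval"))
    if (is.null(micro_insert$length))
      micro_insert$length <- micro_insert$source$length
    if (micro_insert$length != micro_insert$source$length)
      stop("micro_insert length must equal its source interval length")
    if (is.null(micro_insert$overlap_with_donor))
      micro_insert$overlap_with_donor <- 0
    if (micro_insert$overlap_with_donor > micro_insert$length)
      stop("overlap_with_donor must be <= micro_insert length")
  }
  if (!is.null(junction_snv)) {
    if (identical(junction_snv$ref, junction_snv$alt))
      stop("junction SNV ref and alt must differ")
  }
  if (!is.null(junction_deletion)) {
    if (junction_deletion$len < 1) stop("junction deletion length must be >= 1")
    if (!is.null(junction_snv)) {
      dl <- junction_deletion
      if (junction_snv$pos >= dl$pos && junction_snv$pos <= dl$pos + dl$len - 1)
        stop("overlapping edits: SNV lies inside deleted bases")
    }
  }
  structure(list(
    acceptor_contig = acceptor_contig,
    acceptor_break = as.numeric(acceptor_break),
    donor_contig = donor_contig,
    donor_segment = donor_segment,
    donor_orientation = donor_orientation,
    proximal_microhomology_len = as.integer(proximal_microhomology_len),
    micro_insert = micro_insert,
    acceptor_inversion_len = as.integer(acceptor_inversion_len),
    junction_snv = junction_snv,
    junction_deletion = junction_deletion
  ), class = "junction_spec")
}

#' @export
print.junction_spec <- function(x, ...) {
  cat(sprintf(
    paste0("<junction_spec: %s:%s | %s:%s-%s (%s), uh=%d, micro-insert=%s",
           " (overlap %s), inversion=%d>\n"),
    x$acceptor_contig,
    format(x$acceptor_break, big.mark = ",", scientific = FALSE),
    x$donor_contig,
    format(x$donor_segment$start, big.mark = ",", scientific = FALSE),
    format(x$donor_segment$end, big.mark = ",", scientific = FALSE),
    x$donor_orientation, x$proximal_microhomology_len,
    if (is.null(x$micro_insert)) "none" else x$micro_insert$length,
    if (is.null(x$micro_insert)) "-" else x$micro_insert$overlap_with_donor,
    x$acceptor_inversion_len))
  invisible(x)
}

## run expr with a temporary RNG state seeded from `seed`
with_seed <- function(seed, expr) {
  if (is.null(seed)) stop("a seed is mandatory for all randomized operations")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}
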