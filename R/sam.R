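#' Construct an alignment frame
#'
#' The package's in-memory alignment container: a plain data.frame with one
#' row per SAM record and columns `qname`, `mate` (1/2), `flag`, `contig`,
#' `pos` (1-based leftmost), `mapq`, `cigar`, `mate_contig`, `mate_pos`,
#' `isize`, `seq`. Validates the core SAM invariants (query-consuming CIGAR
#' lengths sum to the sequence length; `pos >= 1`; `mapq` in [0, 60]).
#'
#' @param df data.frame with the columns above.
#' @return the validated data.frame, class `c("aln_frame", "data.frame")`.
#' @export
alignment_frame <- function(df) {
  needed <- c("qname", "flag", "contig", "pos", "mapq", "cigar", "seq")
  miss <- setdiff(needed, names(df))
  if (length(miss)) stop("alignment frame missing columns: ",
                         paste(miss, collapse = ", "))
  if (is.null(df$mate)) df$mate <- ifelse(bitwAnd(df$flag, 128L) > 0L, 2L, 1L)
  if (is.null(df$mate_contig)) df$mate_contig <- rep(NA_character_, nrow(df))
  if (is.null(df$mate_pos)) df$mate_pos <- rep(NA_real_, nrow(df))
  if (is.null(df$isize)) df$isize <- rep(0L, nrow(df))
  if (any(df$pos < 1)) stop("alignment pos must be >= 1")
  if (any(df$mapq < 0 | df$mapq > 60)) stop("mapq must lie in [0, 60]")
  qlen <- cigar_query_length(df$cigar)
  bad <- !is.na(qlen) & nchar(df$seq) > 0L & df$seq != "*" & qlen != nchar(df$seq)
  if (any(bad))
    stop("CIGAR query length disagrees with sequence length for ",
         sum(bad), " record(s), e.g. line ", which(bad)[1])
  rownames(df) <- NULL
  class(df) <- c("aln_frame", "data.frame")
  df
}

## flag accessors
flag_has <- function(flag, bit) bitwAnd(flag, bit) > 0L
aln_is_duplicate <- function(df) flag_has(df$flag, 1024L)
aln_is_secondary <- function(df) flag_has(df$flag, 256L)
aln_is_supplementary <- function(df) flag_has(df$flag, 2048L)
aln_is_reverse <- function(df) flag_has(df$flag, 16L)

## parse CIGAR strings into per-record op/length lists
cigar_parse <- function(cigars) {
  lapply(cigars, function(cg) {
    if (is.na(cg) || cg == "*") return(NULL)
    ops <- gregexpr("\\d+[MIDNSHP=X]", cg)[[1]]
    if (ops[1] == -1 || sum(attr(ops, "match.length")) != nchar(cg))
      stop("unparseable CIGAR: ", cg)
    tok <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    list(op = substr(tok, nchar(tok), nchar(tok)),
         len = as.integer(substr(tok, 1, nchar(tok) - 1L)))
  })
}

cigar_query_length <- function(cigars) {
  vapply(cigar_parse(cigars), function(p) {
    if (is.null(p)) return(NA_integer_)
    sum(p$len[p$op %in% c("M", "I", "S", "=", "X")])
  }, integer(1))
}

cigar_ref_length <- function(cigars) {
  vapply(cigar_parse(cigars), function(p) {
    if (is.null(p)) return(NA_integer_)
    sum(p$len[p$op %in% c("M", "D", "N", "=", "X")])
  }, integer(1))
}

## aligned (reference-consuming match) blocks of each record, as a list of
## data.frames with ref_start/ref_end
cigar_match_blocks <- function(pos, cigars) {
  parsed <- cigar_parse(cigars)
  lapply(seq_along(parsed), function(i) {
    p <- parsed[[i]]
    if (is.null(p)) return(NULL)
    ref <- pos[i]
    out <- list()
    for (j in seq_along(p$op)) {
      if (p$op[j] %in% c("M", "=", "X")) {
        out[[length(out) + 1L]] <- c(ref, ref + p$len[j] - 1L)
        ref <- ref + p$len[j]
      } else if (p$op[j] %in% c("D", "N")) ref <- ref + p$len[j]
    }
    if (!length(out)) return(NULL)
    m <- do.call(rbind, out)
    data.frame(ref_start = m[, 1], ref_end = m[, 2])
  })
}

#' Soft/hard-clip structure of an alignment record
#'
#' @param record one row of an alignment frame (or a list with `cigar` and
#'   `seq`).
#' @return list with `left_clip`, `right_clip` (bp, soft + hard) and
#'   `left_seq` / `right_seq` (the soft-clipped subsequences, `""` if none).
#' @export
clip_structure <- function(record) {
  p <- cigar_parse(record$cigar)[[1]]
  if (is.null(p)) stop("record has no valid CIGAR")
  n <- length(p$op)
  lc <- 0L; ls <- 0L
  i <- 1L
  while (i <= n && p$op[i] %in% c("S", "H")) {
    lc <- lc + p$len[i]
    if (p$op[i] == "S") ls <- ls + p$len[i]
    i <- i + 1L
  }
  rc <- 0L; rs <- 0L
  i <- n
  while (i >= 1L && p$op[i] %in% c("S", "H")) {
    rc <- rc + p$len[i]
    if (p$op[i] == "S") rs <- rs + p$len[i]
    i <- i - 1L
  }
  sq <- record$seq
  list(left_clip = lc, right_clip = rc,
       left_seq = if (ls > 0L && !is.na(sq) && sq != "*") substr(sq, 1L, ls) else "",
       right_seq = if (rs > 0L && !is.na(sq) && sq != "*")
         substr(sq, nchar(sq) - rs + 1L, nchar(sq)) else "")
}

#' Read-quality filter policy
#'
#' Operationalizes "high quality read pairs": minimum mapping quality,
#' duplicate and secondary exclusion. Supplementary records are kept by
#' default because split-read detection depends on them.
#'
#' @param min_mapq minimum MAPQ (default 20).
#' @param exclude_duplicates drop duplicate-flagged records (default TRUE).
#' @param exclude_secondary drop secondary records (default TRUE).
#' @param keep_supplementary keep supplementary records (default TRUE).
#' @return list of class `filter_policy`.
#' @export
filter_policy <- function(min_mapq = 20L, exclude_duplicates = TRUE,
                          exclude_secondary = TRUE, keep_supplementary = TRUE) {
  if (min_mapq < 0 || min_mapq > 60) stop("min_mapq must lie in [0, 60]")
  structure(list(min_mapq = min_mapq,
                 exclude_duplicates = exclude_duplicates,
                 exclude_secondary = exclude_secondary,
                 keep_supplementary = keep_supplementary),
            class = "filter_policy")
}

#' Apply a filter policy to alignment records
#'
#' @param records alignment frame.
#' @param policy a [filter_policy()].
#' @return the filtered alignment frame, original order preserved.
#' @export
apply_policy <- function(records, policy = filter_policy()) {
  keep <- records$mapq >= policy$min_mapq
  if (policy$exclude_duplicates) keep <- keep & !aln_is_duplicate(records)
  if (policy$exclude_secondary) keep <- keep & !aln_is_secondary(records)
  if (!policy$keep_supplementary) keep <- keep & !aln_is_supplementary(records)
  records[keep, , drop = FALSE]
}

#' Write alignments as SAM
#'
#' Emits @SQ header lines carrying contig lengths and @CO lines recording
#' each contig's coordinate offset, then one record per row.
#'
#' @param records alignment frame.
#' @param path output `.sam` path.
#' @param reference `contig_set` used for the @SQ header.
#' @export
write_alignments <- function(records, path, reference) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           vapply(reference, function(ctg)
             sprintf("@SQ\tSN:%s\tLN:%d", ctg$name, ctg$length), character(1)),
           vapply(reference, function(ctg)
             sprintf("@CO\toffset %s=%s", ctg$name,
                     format(ctg$offset, scientific = FALSE)), character(1)))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t*",
                  records$qname, records$flag, records$contig,
                  as.integer(records$pos), as.integer(records$mapq),
                  records$cigar,
                  ifelse(is.na(records$mate_contig), "*",
                         ifelse(records$mate_contig == records$contig, "=",
                                records$mate_contig)),
                  as.integer(ifelse(is.na(records$mate_pos), 0, records$mate_pos)),
                  as.integer(records$isize),
                  ifelse(is.na(records$seq) | records$seq == "", "*", records$seq))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read alignments from SAM or BAM
#'
#' SAM text is parsed directly; BAM goes through `Rsamtools::scanBam`. Records
#' are validated against the @SQ header and yielded in file order after
#' applying the filter policy.
#'
#' @param path `.sam` or `.bam` file with @SQ headers.
#' @param policy a [filter_policy()]; use
#'   `filter_policy(0, FALSE, FALSE, TRUE)` for no filtering.
#' @return an alignment frame.
#' @export
read_alignments <- function(path, policy = filter_policy()) {
  df <- if (grepl("\\.bam$", path, ignore.case = TRUE)) read_bam_records(path)
        else read_sam_records(path)
  apply_policy(alignment_frame(df), policy)
}

read_sam_records <- function(path) {
  x <- readLines(path)
  hdr <- x[startsWith(x, "@")]
  sq <- hdr[startsWith(hdr, "@SQ")]
  contigs <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
  body <- x[!startsWith(x, "@")]
  body <- body[nzchar(body)]
  if (!length(body))
    return(data.frame(qname = character(0), flag = integer(0),
                      contig = character(0), pos = numeric(0),
                      mapq = integer(0), cigar = character(0),
                      mate_contig = character(0), mate_pos = numeric(0),
                      isize = integer(0), seq = character(0)))
  f <- strsplit(body, "\t", fixed = TRUE)
  nf <- vapply(f, length, integer(1))
  if (any(nf < 11L))
    stop("unparseable SAM record at line ",
         which(!startsWith(x, "@"))[which(nf < 11L)[1]], " of ", path)
  g <- function(i) vapply(f, `[[`, character(1), i)
  df <- data.frame(
    qname = g(1), flag = as.integer(g(2)), contig = g(3),
    pos = as.numeric(g(4)), mapq = as.integer(g(5)), cigar = g(6),
    mate_contig = g(7), mate_pos = as.numeric(g(8)), isize = as.integer(g(9)),
    seq = g(10), stringsAsFactors = FALSE)
  df$mate_contig[df$mate_contig == "="] <- df$contig[df$mate_contig == "="]
  df$mate_contig[df$mate_contig == "*"] <- NA_character_
  if (length(contigs)) {
    unknown <- !df$contig %in% c(contigs, "*")
    if (any(unknown))
      stop("record maps to contig absent from @SQ header: ",
           unique(df$contig[unknown])[1])
  }
  df
}

read_bam_records <- function(path) {
  b <- Rsamtools::scanBam(path)[[1]]
  mc <- as.character(b$mrnm)
  data.frame(
    qname = b$qname, flag = as.integer(b$flag),
    contig = as.character(b$rname), pos = as.numeric(b$pos),
    mapq = as.integer(b$mapq), cigar = b$cigar,
    mate_contig = mc, mate_pos = as.numeric(b$mpos),
    isize = ifelse(is.na(b$isize), 0L, b$isize),
    seq = as.character(b$seq), stringsAsFactors = FALSE)
}
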