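#' Windowed depth of coverage
#'
#' Mean aligned-base depth per fixed window across an interval. Depth counts
#' reference-consuming aligned bases (CIGAR M/=/X), not read starts, so the
#' total aligned-base mass is conserved across windows.
#'
#' @param records alignment frame.
#' @param interval a `genomic_interval` (contig-local coordinates) to profile.
#' @param window_size window width in bp (default 1000).
#' @param reference optional `contig_set` to validate the interval against.
#' @return list of class `depth_profile`: `$windows` (data.frame `start`,
#'   `end`, `depth`), `$contig`, `$window_size`, `$mean_depth`.
#' @export
windowed_depth <- function(records, interval, window_size = 1000L,
                           reference = NULL) {
  stopifnot(inherits(interval, "genomic_interval"))
  if (!is.null(reference)) {
    ctg <- reference[[interval$contig]]
    if (is.null(ctg)) stop("interval contig absent from reference")
    if (interval$end > ctg$length) stop("interval outside contig")
  }
  lo <- interval$start; hi <- interval$end
  n <- hi - lo + 1
  cover <- numeric(n + 1)   # difference array over [lo, hi]
  recs <- records[records$contig == interval$contig &
                    !flag_has(records$flag, 4L) & records$cigar != "*", ,
                  drop = FALSE]
  if (nrow(recs)) {
    simple <- grepl("^[0-9]+M$", recs$cigar)
    ## fast path: single full-match block
    if (any(simple)) {
      s <- pmax(recs$pos[simple], lo)
      e <- pmin(recs$pos[simple] + as.numeric(sub("M", "", recs$cigar[simple])) - 1, hi)
      ok <- s <= e
      si <- s[ok] - lo + 1; ei <- e[ok] - lo + 2
      for (tab in list(table(si), -table(ei))) {
        at <- as.numeric(names(tab))
        cover[at] <- cover[at] + as.numeric(tab)
      }
    }
    other <- which(!simple)
    if (length(other)) {
      blocks <- cigar_match_blocks(recs$pos[other], recs$cigar[other])
      for (bl in blocks) {
        if (is.null(bl)) next
        s <- pmax(bl$ref_start, lo); e <- pmin(bl$ref_end, hi)
        ok <- s <= e
        for (j in which(ok)) {
          cover[s[j] - lo + 1] <- cover[s[j] - lo + 1] + 1
          cover[e[j] - lo + 2] <- cover[e[j] - lo + 2] - 1
        }
      }
    }
  }
  depth <- cumsum(cover[seq_len(n)])
  w0 <- seq(lo, hi, by = window_size)
  w1 <- pmin(w0 + window_size - 1, hi)
  wdepth <- vapply(seq_along(w0), function(i)
    mean(depth[(w0[i] - lo + 1):(w1[i] - lo + 1)]), numeric(1))
  structure(list(
    contig = interval$contig, window_size = as.integer(window_size),
    windows = data.frame(start = w0, end = w1, depth = wdepth),
    mean_depth = mean(depth)), class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf("<depth_profile %s: %d windows of %d bp, mean depth %.1fx>\n",
              x$contig, nrow(x$windows), x$window_size, x$mean_depth))
  invisible(x)
}

#' Per-region depth summaries
#'
#' Mean and standard deviation of window depths inside each named region
#' (the upstream / insert / downstream layout of a copy-gain assessment).
#'
#' @param profile a `depth_profile`.
#' @param regions named list of `genomic_interval`s on the profiled contig.
#' @return data.frame `region`, `mean`, `sd`, `n_windows`.
#' @export
region_summary <- function(profile, regions) {
  out <- lapply(names(regions), function(nm) {
    rg <- regions[[nm]]
    w <- profile$windows
    sel <- w$start >= rg$start & w$end <= rg$end
    if (!any(sel)) stop("region '", nm, "' contains no profiled windows")
    data.frame(region = nm, mean = mean(w$depth[sel]),
               sd = if (sum(sel) > 1) sd(w$depth[sel]) else 0,
               n_windows = sum(sel), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Fold-change copy-gain call
#'
#' Compares mean depth over a candidate insert region against the mean of
#' its flank means. A heterologous insertion duplicating the region adds one
#' copy on top of the two autosomal copies, so the expected fold change under
#' that trisomy is 1.5; the default call threshold 1.35 is the midpoint
#' between no gain (1.0) and trisomy (1.5) minus sampling slack.
#'
#' @param profile a `depth_profile`.
#' @param insert_region `genomic_interval` of the candidate gained region.
#' @param flank_regions named list of flank `genomic_interval`s.
#' @param gain_threshold minimum fold change called as gained (default 1.35).
#' @return list of class `copy_gain_call`: `fold_change`, `expected_fold`,
#'   `gained`, `insert_mean`, `flank_mean`, `summary`.
#' @export
fold_change_call <- function(profile, insert_region, flank_regions,
                             gain_threshold = 1.35) {
  regions <- c(list(insert = insert_region), flank_regions)
  summ <- region_summary(profile, regions)
  ins <- summ$mean[summ$region == "insert"]
  fl <- summ$mean[summ$region != "insert"]
  if (any(fl <= 0)) stop("zero flank depth; fold change undefined")
  fold <- ins / mean(fl)
  structure(list(fold_change = fold, expected_fold = 1.5,
                 gained = fold >= gain_threshold,
                 insert_mean = ins, flank_mean = mean(fl), summary = summ),
            class = "copy_gain_call")
}

#' @export
print.copy_gain_call <- function(x, ...) {
  cat(sprintf("<copy_gain_call: fold %.2f (insert %.1fx vs flank %.1fx) -> %s>\n",
              x$fold_change, x$insert_mean, x$flank_mean,
              if (x$gained) "GAINED" else "no gain"))
  invisible(x)
}
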