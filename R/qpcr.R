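#' Comparative-Ct relative expression
#'
#' Implements the comparative Ct (delta-delta-Ct) method with the replicate
#' structure of a plate experiment: technical replicates are averaged first,
#' each extraction then yields dCt = Ct(target) - Ct(housekeeping), the
#' calibrator sample's mean dCt is subtracted (ddCt), and the fold change is
#' 2^(-ddCt) under the standard assumption of amplification efficiency 2.
#' The calibrator's own fold is exactly 1. Per-sample spread and the
#' two-sample t-test against the calibrator are computed on extraction-level
#' folds.
#'
#' @param ct_table Ct data.frame (`sample`, `gene`, `extraction`, `tech_rep`,
#'   `ct`; NA = undetermined).
#' @param target target gene name.
#' @param housekeeping housekeeping gene name; must be detected in every
#'   sample.
#' @param calibrator calibrator sample id (fold set to 1).
#' @param var_equal classical equal-variance t-test (default TRUE); FALSE
#'   gives Welch.
#' @return data.frame `sample`, `gene`, `fold`, `sd`, `p_value`,
#'   `n_extractions`, `detected`.
#' @export
ddct <- function(ct_table, target, housekeeping, calibrator,
                 var_equal = TRUE) {
  samples <- unique(ct_table$sample)
  if (!calibrator %in% samples) stop("calibrator sample absent from table")
  hk <- extraction_means(ct_table, housekeeping)
  if (!all(samples %in% hk$sample) || anyNA(hk$ct))
    stop("housekeeping gene undetermined in at least one sample")
  tg <- extraction_means(ct_table, target)

  dct <- merge(tg, hk, by = c("sample", "extraction"),
               suffixes = c("_t", "_h"))
  dct$dct <- dct$ct_t - dct$ct_h
  cal <- dct$dct[dct$sample == calibrator & !is.na(dct$dct)]
  if (!length(cal)) {
    cal_mean <- NA_real_
  } else cal_mean <- mean(cal)
  cal_folds <- 2^(-(cal - cal_mean))

  out <- lapply(samples, function(s) {
    d <- dct$dct[dct$sample == s]
    d <- d[!is.na(d)]
    detected <- length(d) > 0
    if (!detected)
      return(data.frame(sample = s, gene = target, fold = NA_real_,
                        sd = NA_real_, p_value = NA_real_,
                        n_extractions = 0L, detected = FALSE,
                        stringsAsFactors = FALSE))
    folds <- 2^(-(d - cal_mean))
    fold <- 2^(-(mean(d) - cal_mean))
    p <- if (s == calibrator || length(d) < 2L || length(cal_folds) < 2L)
      NA_real_
    else tryCatch(t.test(folds, cal_folds, var.equal = var_equal)$p.value,
                  error = function(e) NA_real_)   # zero-variance replicates
    data.frame(sample = s, gene = target, fold = fold,
               sd = if (length(folds) > 1) sd(folds) else NA_real_,
               p_value = p, n_extractions = length(d), detected = TRUE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

## technical replicates -> per-extraction mean Ct; extractions mixing
## undetermined and numeric wells are dropped with a warning
extraction_means <- function(ct_table, gene) {
  g <- ct_table[ct_table$gene == gene, , drop = FALSE]
  if (!nrow(g)) stop("gene absent from Ct table: ", gene)
  key <- paste(g$sample, g$extraction)
  nas <- tapply(is.na(g$ct), key, sum)
  tot <- tapply(g$ct, key, length)
  mixed <- nas > 0 & nas < tot
  if (any(mixed)) {
    warning("mixed undetermined/numeric wells for ", gene, " in ",
            sum(mixed), " extraction(s); extraction dropped")
  }
  mean_ct <- tapply(g$ct, key, function(x) {
    if (any(is.na(x))) NA_real_ else mean(x)
  })
  ks <- strsplit(names(mean_ct), " ")
  data.frame(sample = vapply(ks, `[[`, character(1), 1),
             extraction = vapply(ks, `[[`, character(1), 2),
             ct = as.numeric(mean_ct), stringsAsFactors = FALSE)
}

#' Detection report for a gene
#'
#' A gene is not detected in a sample when every one of its wells carries
#' the undetermined sentinel; its fold is then reported as not detected
#' rather than 0 or infinity.
#'
#' @param ct_table Ct data.frame.
#' @param gene gene name.
#' @return data.frame `sample`, `n_wells`, `n_undetermined`, `detected`.
#' @export
detect_undetermined <- function(ct_table, gene) {
  g <- ct_table[ct_table$gene == gene, , drop = FALSE]
  if (!nrow(g)) stop("gene absent from Ct table: ", gene)
  und <- tapply(is.na(g$ct), g$sample, sum)
  tot <- tapply(g$ct, g$sample, length)
  data.frame(sample = names(tot), n_wells = as.integer(tot),
             n_undetermined = as.integer(und),
             detected = as.integer(und) < as.integer(tot),
             row.names = NULL, stringsAsFactors = FALSE)
}
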