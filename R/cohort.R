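#' Simulate a genotyped cohort under X-linked inheritance
#'
#' Assigns mutant-haplotype copies to pedigree members from their declared
#' status: affected males are hemizygous carriers (1 copy on their single X),
#' carrier females heterozygous (1 of 2), unaffected individuals carry none.
#' Transmission consistency is audited: a child's mutant X must be traceable
#' to its mother (no male-to-male transmission), so an affected or carrier
#' child whose listed mother is a non-carrier is rejected.
#'
#' @param pedigree data.frame with columns `id`, `father`, `mother` (`""` or
#'   NA for founders), `sex` (`male`/`female`), `status`
#'   (`affected`/`carrier`/`unaffected`); an optional `carrier_alleles`
#'   column overrides the status-derived allele count.
#' @param seed mandatory seed (kept for interface symmetry; assignment from
#'   statuses is deterministic).
#' @return data.frame of samples: `sample_id`, `sex`, `carrier_alleles`,
#'   `affection`, `n_x` (number of X haplotypes).
#' @export
simulate_cohort <- function(pedigree, seed) {
  if (!nrow(pedigree))
    return(data.frame(sample_id = character(0), sex = character(0),
                      carrier_alleles = integer(0), affection = character(0),
                      n_x = integer(0)))
  stopifnot(all(c("id", "sex", "status") %in% names(pedigree)))
  if (is.null(pedigree$father)) pedigree$father <- ""
  if (is.null(pedigree$mother)) pedigree$mother <- ""
  with_seed(seed, NULL)
  n_x <- ifelse(pedigree$sex == "male", 1L, 2L)
  alleles <- if (!is.null(pedigree$carrier_alleles))
    as.integer(pedigree$carrier_alleles)
  else ifelse(pedigree$status %in% c("affected", "carrier"), 1L, 0L)
  bad <- pedigree$status == "affected" & pedigree$sex == "male" & alleles == 0L
  if (any(bad))
    stop("affected male requested with 0 mutant alleles: ",
         paste(pedigree$id[bad], collapse = ", "))
  if (any(alleles > n_x))
    stop("carrier_alleles exceeds number of X haplotypes")
  ## X-linked transmission audit: the mutant X of any non-founder must come
  ## from a carrier mother
  mi <- match(pedigree$mother, pedigree$id)
  has_mother <- !is.na(mi) & nzchar(pedigree$mother %||% "")
  mother_alleles <- ifelse(has_mother, alleles[mi], NA_integer_)
  viol <- alleles > 0L & has_mother & mother_alleles == 0L
  if (any(viol))
    stop("X-linked inconsistency (mutant allele with non-carrier mother): ",
         paste(pedigree$id[viol], collapse = ", "))
  data.frame(sample_id = pedigree$id, sex = pedigree$sex,
             carrier_alleles = alleles, affection = pedigree$status,
             n_x = n_x, stringsAsFactors = FALSE)
}

#' Founder-only pedigree with a requested composition
#'
#' @param n_affected_males,n_carrier_females,n_unaffected_males,n_unaffected_females
#'   cohort composition counts.
#' @return pedigree data.frame for [simulate_cohort()].
#' @export
composition_pedigree <- function(n_affected_males = 0L, n_carrier_females = 0L,
                                 n_unaffected_males = 0L,
                                 n_unaffected_females = 0L) {
  mk <- function(n, prefix, sex, status) {
    if (n == 0L) return(NULL)
    data.frame(id = sprintf("%s%03d", prefix, seq_len(n)), father = "",
               mother = "", sex = sex, status = status,
               stringsAsFactors = FALSE)
  }
  out <- rbind(mk(n_affected_males, "AM", "male", "affected"),
               mk(n_carrier_females, "CF", "female", "carrier"),
               mk(n_unaffected_males, "UM", "male", "unaffected"),
               mk(n_unaffected_females, "UF", "female", "unaffected"))
  if (is.null(out))
    out <- data.frame(id = character(0), father = character(0),
                      mother = character(0), sex = character(0),
                      status = character(0))
  out
}

#' Random multi-generation pedigree under X-linked transmission
#'
#' Simulates genealogies forward in time: founder couples (one carrier
#' founder female), children inherit their maternal X at random, carrier
#' males are affected, carrier females are asymptomatic carriers.
#'
#' @param n_generations number of generations below the founders.
#' @param mean_children mean number of children per couple (Poisson, min 1).
#' @param seed mandatory seed.
#' @return pedigree data.frame with `id`, `father`, `mother`, `sex`,
#'   `status` and the realized `carrier_alleles`.
#' @export
random_pedigree <- function(n_generations = 3L, mean_children = 3, seed) {
  with_seed(seed, {
    ped <- data.frame(id = c("F0", "M0"), father = "", mother = "",
                      sex = c("female", "male"), alleles = c(1L, 0L),
                      stringsAsFactors = FALSE)
    couples <- list(c(mother = "F0", father = "M0"))
    counter <- 0L
    for (g in seq_len(n_generations)) {
      nxt <- list()
      for (cp in couples) {
        mom <- ped[ped$id == cp[["mother"]], ]
        n_kids <- max(1L, stats::rpois(1, mean_children))
        for (k in seq_len(n_kids)) {
          counter <- counter + 1L
          sex <- sample(c("male", "female"), 1L)
          ## child's maternal X is one of the mother's two at random
          inherit <- mom$alleles > 0L && runif(1) < mom$alleles / 2
          kid <- sprintf("G%d_%03d", g, counter)
          ped <- rbind(ped, data.frame(
            id = kid, father = cp[["father"]], mother = cp[["mother"]],
            sex = sex, alleles = as.integer(inherit),
            stringsAsFactors = FALSE))
          ## carriers marry in an unrelated spouse and found the next couple
          if (g < n_generations && runif(1) < 0.6) {
            counter <- counter + 1L
            spouse <- sprintf("S%d_%03d", g, counter)
            ped <- rbind(ped, data.frame(
              id = spouse, father = "", mother = "",
              sex = if (sex == "male") "female" else "male", alleles = 0L,
              stringsAsFactors = FALSE))
            nxt[[length(nxt) + 1L]] <-
              if (sex == "male") c(mother = spouse, father = kid)
              else c(mother = kid, father = spouse)
          }
        }
      }
      couples <- nxt
      if (!length(couples)) break
    }
    ped$status <- ifelse(ped$alleles > 0L,
                         ifelse(ped$sex == "male", "affected", "carrier"),
                         "unaffected")
    ped$carrier_alleles <- ped$alleles
    ped$alleles <- NULL
    ped
  })
}

#' Read / write pedigree tables
#'
#' Tab-separated with columns `id`, `father`, `mother`, `sex`, `status`.
#' @param path TSV path.
#' @export
read_pedigree <- function(path) {
  p <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  p
}

#' @rdname read_pedigree
#' @param pedigree pedigree data.frame.
#' @export
write_pedigree <- function(pedigree, path) {
  write.table(pedigree, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simulate a comparative-Ct (qRT-PCR) cycle-threshold table
#'
#' Emits the replicate structure of a comparative-Ct experiment: 3 RNA
#' extractions per sample, each assayed in technical triplicate, for every
#' target gene plus the housekeeping gene. A planted fold change of f lowers
#' the target Ct by log2(f) relative to the calibrator; genes marked not
#' detected (fold NA) carry the undetermined sentinel in every cell.
#'
#' @param samples character vector of sample ids.
#' @param genes character vector of target genes.
#' @param fold_changes named list: `fold_changes[[gene]][sample]` giving each
#'   sample's true fold relative to the calibrator (NA = not detected; a
#'   single unnamed value recycles over samples).
#' @param housekeeping name of the housekeeping gene (default "RN18S").
#' @param housekeeping_ct its true Ct (default 12).
#' @param base_ct target-gene Ct in the calibrator (default 24).
#' @param noise_sd extraction-level Ct noise standard deviation (>= 0).
#' @param tech_sd technical-replicate noise (default `noise_sd / 3`).
#' @param seed mandatory seed.
#' @param n_extractions,n_tech replicate structure (defaults 3 and 3).
#' @return data.frame `sample`, `gene`, `extraction`, `tech_rep`, `ct`
#'   (numeric; NA is the undetermined sentinel).
#' @export
simulate_ct_table <- function(samples, genes, fold_changes,
                              housekeeping = "RN18S", housekeeping_ct = 12,
                              base_ct = 24, noise_sd = 0.1,
                              tech_sd = noise_sd / 3, seed,
                              n_extractions = 3L, n_tech = 3L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  bad_fold <- unlist(lapply(fold_changes, function(f) any(!is.na(f) & f <= 0)))
  if (any(bad_fold)) stop("fold changes must be > 0 or NA (not detected)")
  with_seed(seed, {
    rows <- list()
    for (s in samples) {
      for (g in c(genes, housekeeping)) {
        if (g == housekeeping) {
          true_ct <- housekeeping_ct
        } else {
          f <- fold_changes[[g]]
          f <- if (!is.null(names(f))) f[[s]] else f[[1]]
          true_ct <- if (is.na(f)) NA_real_ else base_ct - log2(f)
        }
        for (e in seq_len(n_extractions)) {
          e_eff <- if (noise_sd > 0) rnorm(1, 0, noise_sd) else 0
          ct <- if (is.na(true_ct)) rep(NA_real_, n_tech)
                else true_ct + e_eff +
                  (if (tech_sd > 0) rnorm(n_tech, 0, tech_sd) else 0)
          rows[[length(rows) + 1L]] <- data.frame(
            sample = s, gene = g, extraction = e, tech_rep = seq_len(n_tech),
            ct = ct, stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })
}

#' Read / write Ct tables
#'
#' Tab-separated `sample`, `gene`, `extraction`, `tech_rep`, `ct`; the
#' undetermined sentinel string maps to NA in memory.
#'
#' @param path TSV path.
#' @param sentinel undetermined-well sentinel (default "Undetermined").
#' @export
read_ct_table <- function(path, sentinel = "Undetermined") {
  ct <- read.delim(path, stringsAsFactors = FALSE)
  ct$ct <- suppressWarnings(as.numeric(ifelse(ct$ct == sentinel, NA, ct$ct)))
  ct
}

#' @rdname read_ct_table
#' @param ct Ct data.frame.
#' @export
write_ct_table <- function(ct, path, sentinel = "Undetermined") {
  ct$ct <- ifelse(is.na(ct$ct), sentinel, format(ct$ct, digits = 10))
  write.table(ct, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
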