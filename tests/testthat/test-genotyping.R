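## shared assay fixture built once per file
local({
  refs <- mini_reference(401)
  spec <- cmtx3_like_spec(refs)
  mut <- build_mutant_haplotype(refs, spec)
  assay <<- place_assay(spec, mut$reference,
                        size_spec = c(wild_type = 340, proximal_junction = 595,
                                      distal_junction = 235))
  assay_refs <<- mut$reference
})

test_that("assay placement reproduces the specified product sizes exactly", {
  amps_wt <- insilico_pcr(list(X = assay$wild), assay$primers)
  expect_equal(amps_wt$length, 340)
  amps_mu <- insilico_pcr(list(X = assay$mutant), assay$primers)
  expect_setequal(amps_mu$length, c(595, 235))
  expect_error(place_assay(cmtx3_like_spec(mini_reference(401)), assay_refs,
                           size_spec = c(wild_type = 40,
                                         proximal_junction = 595,
                                         distal_junction = 235)),
               "twice the primer length")
})

test_that("randomized size specifications solve and verify", {
  refs <- mini_reference(403)
  spec <- cmtx3_like_spec(refs)
  mut <- build_mutant_haplotype(refs, spec)
  set.seed(7)
  for (i in 1:6) {
    sz <- c(wild_type = sample(200:500, 1),
            proximal_junction = sample(300:900, 1),
            distal_junction = sample(150:400, 1))
    a <- place_assay(spec, mut$reference, size_spec = sz)
    expect_equal(insilico_pcr(list(a$wild), a$primers)$length,
                 unname(sz["wild_type"]))
    expect_setequal(insilico_pcr(list(a$mutant), a$primers)$length,
                    unname(sz[c("proximal_junction", "distal_junction")]))
  }
})

test_that("in-silico PCR enumerates convergent placements only", {
  primers <- data.frame(name = c("F", "R"),
                        sequence = c("ACGTACGTACGTACGTACGTA",
                                     "TTGCATGCATGCATGCATGCA"))
  blank <- contig("t", strrep("C", 500), 0)
  expect_equal(nrow(insilico_pcr(list(blank), primers)), 0)
  ## planted convergent pair with brute-force-verified length
  tpl <- paste0(strrep("C", 100), primers$sequence[1], strrep("G", 58),
                revcomp(primers$sequence[2]), strrep("C", 100))
  amp <- insilico_pcr(list(contig("t", tpl, 0)), primers)
  expect_equal(nrow(amp), 1)
  expect_equal(amp$length, 21 + 58 + 21)
  expect_equal(amp$start, 101)
  ## product count is invariant under template reverse-complementation
  amp2 <- insilico_pcr(list(contig("t", revcomp(tpl), 0)), primers)
  expect_equal(nrow(amp2), nrow(amp))
  expect_equal(amp2$length, amp$length)
})

test_that("genotype calls are a pure function of sex and amplicon span set", {
  spans <- c("wild_type", "proximal_junction", "distal_junction")
  combos <- unlist(lapply(0:3, function(k)
    combn(spans, k, simplify = FALSE)), recursive = FALSE)
  legend <- function(sex, s) {
    s <- sort(s)
    if (identical(s, "wild_type")) "non_carrier"
    else if (sex == "male" && identical(s, sort(spans[2:3])))
      "affected_hemizygous"
    else if (sex == "female" && identical(s, sort(spans))) "carrier_female"
    else "inconsistent"
  }
  for (sex in c("male", "female")) for (s in combos)
    expect_equal(call_genotype(s, sex), legend(sex, s))
})

test_that("genotyped cohort reproduces the three gel patterns", {
  ped <- composition_pedigree(1, 1, 1, 1)
  cohort <- simulate_cohort(ped, seed = 1)
  g <- genotype_cohort(cohort, assay)
  expect_equal(g$genotype[g$sample_id == "AM001"], "affected_hemizygous")
  expect_equal(g$amplicons[g$sample_id == "AM001"], "235,595")
  expect_equal(g$genotype[g$sample_id == "CF001"], "carrier_female")
  expect_equal(g$amplicons[g$sample_id == "CF001"], "235,340,595")
  expect_equal(g$genotype[g$sample_id == "UM001"], "non_carrier")
  expect_equal(g$amplicons[g$sample_id == "UM001"], "340")
  expect_equal(g$genotype[g$sample_id == "UF001"], "non_carrier")
})

test_that("segregation analysis counts concordance and flags violations", {
  ped <- composition_pedigree(25, 30, 30, 20)
  cohort <- simulate_cohort(ped, seed = 2)
  g <- genotype_cohort(cohort, assay)
  seg <- segregation_check(g)
  expect_equal(seg$n, 105)
  expect_equal(seg$concordant, 105)
  expect_equal(seg$discordant, 0)

  empty <- segregation_check(g[0, ])
  expect_equal(empty$n, 0)

  ## planted father-to-son transmission is flagged
  ped2 <- data.frame(id = c("dad", "mom", "son"),
                     father = c("", "", "dad"), mother = c("", "", "mom"),
                     sex = c("male", "female", "male"),
                     status = c("affected", "unaffected", "affected"))
  expect_error(simulate_cohort(ped2, seed = 1), "X-linked inconsistency")
  g2 <- data.frame(sample_id = ped2$id, sex = ped2$sex,
                   affection = ped2$status,
                   genotype = c("affected_hemizygous", "non_carrier",
                                "affected_hemizygous"))
  seg2 <- segregation_check(g2, ped2)
  expect_equal(seg2$transmission_violations, "son")
  ## cycles are rejected
  cyc <- data.frame(id = c("a", "b"), father = c("b", "a"),
                    mother = c("", ""), sex = "male", status = "unaffected")
  expect_error(segregation_check(g2, cyc), "cycle")
})

test_that("control panel accounting equals 2F + M X chromosomes", {
  ped <- composition_pedigree(0, 0, 123, 252)
  cohort <- simulate_cohort(ped, seed = 3)
  g <- genotype_cohort(cohort, assay)
  panel <- screen_panel(g)
  expect_equal(panel$x_chromosomes, 627)
  expect_equal(panel$carrier_x, 0)
  expect_equal(screen_panel(g[0, ])$x_chromosomes, 0)
  set.seed(5)
  for (i in 1:5) {
    nf <- sample(0:50, 1); nm <- sample(0:50, 1)
    gg <- data.frame(sex = c(rep("female", nf), rep("male", nm)),
                     genotype = "non_carrier")
    expect_equal(screen_panel(gg)$x_chromosomes, 2 * nf + nm)
  }
})
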