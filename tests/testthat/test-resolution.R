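lab_var <- function(sample, gene, key, zygosity = "het",
                    consequence = "missense", label = "known_pathogenic",
                    protein = NA_character_) {
  data.frame(sample = sample, gene = gene, key = key, zygosity = zygosity,
             consequence = consequence, label = label, protein = protein,
             stringsAsFactors = FALSE)
}

del_call <- function(sample, gene, span) {
  out <- data.frame(sample = sample, gene = gene, type = "deletion",
                    span = span, first_target = NA, last_target = NA,
                    n_targets = 1L, mean_ratio = 0.5,
                    stringsAsFactors = FALSE)
  class(out) <- c("cnv_calls", "data.frame")
  out
}

test_that("inheritance models decide the solved configurations", {
  gm <- default_gene_table()
  # homozygous recessive allele
  hom <- resolve_family(family_case("F1", "S1"),
                        lab_var("S1", "CNGB1", "k1", "hom"))
  expect_equal(hom$status, "solved")
  expect_equal(hom$model, "AR")
  expect_equal(hom$gene, "CNGB1")
  expect_equal(hom$segregation, "not_available")

  # compound heterozygote of a small variant and an exon deletion
  chet_cnv <- resolve_family(
    family_case("F2", "S2"),
    lab_var("S2", "EYS", "k2", "het", "frameshift"),
    del_call("S2", "EYS", "Ex.19"))
  expect_equal(chet_cnv$status, "solved")
  expect_equal(chet_cnv$model, "AR")

  # two heterozygous small variants
  chet <- resolve_family(family_case("F3", "S3"),
                         rbind(lab_var("S3", "USH2A", "k3"),
                               lab_var("S3", "USH2A", "k4")))
  expect_equal(chet$status, "solved")

  # one pathogenic allele only
  single <- resolve_family(family_case("F4", "S4"),
                           lab_var("S4", "CNGB1", "k5", "het",
                                   "noncanonical_splice",
                                   "potentially_pathogenic"))
  expect_equal(single$status, "partial")
  expect_equal(single$gene, "CNGB1")

  # one allele in each of two genes, neither completed
  two <- resolve_family(family_case("F5", "S5"),
                        rbind(lab_var("S5", "EYS", "k6"),
                              lab_var("S5", "USH2A", "k7")))
  expect_equal(two$status, "uncertain_two_genes")
  expect_setequal(two$gene, c("EYS", "USH2A"))

  # hemizygous XL allele in a male index solves; not in a female
  xl_m <- resolve_family(family_case("F6", "S6", sex = "M"),
                         lab_var("S6", "RP2", "k8", "hemi",
                                 label = "potentially_pathogenic"))
  expect_equal(xl_m$status, "solved")
  expect_equal(xl_m$model, "XL")
  xl_f <- resolve_family(family_case("F6b", "S6", sex = "F"),
                         lab_var("S6", "RP2", "k8", "het",
                                 label = "potentially_pathogenic"))
  expect_equal(xl_f$status, "partial")

  # dominant-hotspot truncation solves with one allele; outside does not
  ad <- resolve_family(family_case("F7", "S7"),
                       lab_var("S7", "RP1", "k9", "het", "frameshift",
                               protein = "p.Ser812Valfs*36"))
  expect_equal(ad$status, "solved")
  expect_equal(ad$model, "AD")
  ad_out <- resolve_family(family_case("F8", "S8"),
                           lab_var("S8", "RP1", "k10", "het", "frameshift",
                                   protein = "p.His136Argfs*8"))
  expect_equal(ad_out$status, "partial")

  # nothing pathogenic
  none <- resolve_family(family_case("F9", "S9"),
                         lab_var("S9", "EYS", "k11",
                                 label = "benign_frequency"))
  expect_equal(none$status, "unsolved")
})

test_that("contradictory zygosity is flagged for review, not hidden", {
  res <- resolve_family(family_case("F1", "S1"),
                        rbind(lab_var("S1", "EYS", "k1", "hom"),
                              lab_var("S1", "EYS", "k2", "het")))
  expect_true(res$review)
  expect_equal(res$status, "solved")
})

test_that("resolution is invariant to variant-list order", {
  v <- rbind(lab_var("S1", "USH2A", "a"),
             lab_var("S1", "USH2A", "b"),
             lab_var("S1", "EYS", "c"))
  r1 <- resolve_family(family_case("F1", "S1"), v)
  r2 <- resolve_family(family_case("F1", "S1"), v[c(3, 1, 2), ])
  expect_equal(r1[c("status", "model", "gene")],
               r2[c("status", "model", "gene")])
})

test_that("second-allele search walks gene-first, then genome-wide", {
  prior <- "USH2A:c.2276G>T"
  base <- lab_var("S1", "USH2A", prior, "het")
  case <- family_case("F1", "S1", prior_allele = prior)

  # phase 1: a second allele in the prior gene
  hit1 <- second_allele_search(case, rbind(base,
    lab_var("S1", "USH2A", "USH2A:fs", "het", "frameshift",
            "lof_pathogenic")))
  expect_equal(attr(hit1, "phase"), 1L)
  expect_equal(hit1$key, "USH2A:fs")

  # phase 1 also sees deletion events in the gene
  hit_cnv <- second_allele_search(case, base,
                                  del_call("S1", "USH2A", "Ex.45-49"))
  expect_equal(attr(hit_cnv, "phase"), 1L)
  expect_equal(hit_cnv$allele_type, "cnv")

  # phase 2: gene switch when the prior gene yields nothing
  hit2 <- second_allele_search(case, rbind(base,
    lab_var("S1", "RP1", "RP1:fs", "het", "frameshift", "lof_pathogenic",
            protein = "p.Ser812Valfs*36")))
  expect_equal(attr(hit2, "phase"), 2L)
  expect_equal(hit2$gene, "RP1")

  # nothing anywhere: empty candidate set
  empty <- second_allele_search(case, base)
  expect_equal(nrow(empty), 0)

  expect_error(second_allele_search(
    family_case("F1", "S1", prior_allele = "EYS:missing"), base),
    "absent from the index call set")
})

test_that("segregation checks relatives against the causal configuration", {
  v <- rbind(lab_var("S1", "USH2A", "a"), lab_var("S1", "USH2A", "b"),
             # parents carry one allele each, affected sib both
             lab_var("P1", "USH2A", "a"), lab_var("P2", "USH2A", "b"),
             lab_var("A1", "USH2A", "a"), lab_var("A1", "USH2A", "b"))
  rel <- data.frame(sample = c("P1", "P2", "A1"),
                    affected = c(FALSE, FALSE, TRUE),
                    stringsAsFactors = FALSE)
  res <- resolve_family(family_case("F1", "S1", relatives = rel), v)
  expect_equal(res$segregation, "consistent")

  # an unaffected sib carrying both alleles is inconsistent
  v2 <- rbind(v, lab_var("U1", "USH2A", "a"), lab_var("U1", "USH2A", "b"))
  rel2 <- rbind(rel, data.frame(sample = "U1", affected = FALSE))
  res2 <- resolve_family(family_case("F1", "S1", relatives = rel2), v2)
  expect_equal(res2$segregation, "inconsistent")

  # dominant RP1 tolerates an unaffected carrier (incomplete penetrance)
  vd <- rbind(lab_var("S1", "RP1", "r", "het", "frameshift",
                      protein = "p.Ser812Valfs*36"),
              lab_var("U1", "RP1", "r", "het", "frameshift",
                      protein = "p.Ser812Valfs*36"))
  reld <- data.frame(sample = "U1", affected = FALSE,
                     stringsAsFactors = FALSE)
  resd <- resolve_family(family_case("F2", "S1", relatives = reld), vd)
  expect_equal(resd$segregation, "consistent")
  # ... but only for penetrance-exempt genes
  cfg <- default_config(); cfg$penetrance_exempt_genes <- character(0)
  resd2 <- resolve_family(family_case("F2", "S1", relatives = reld), vd,
                          config = cfg)
  expect_equal(resd2$segregation, "inconsistent")

  expect_equal(resolve_family(family_case("F3", "S1"), v)$segregation,
               "not_available")
})

test_that("reclassification rules fire on gene and model", {
  mk <- function(gene, model) {
    structure(list(family = "F", status = "solved", model = model,
                   gene = gene, alleles = NULL,
                   segregation = "not_available", flags = character(0),
                   review = FALSE, has_prior = FALSE),
              class = "rp_resolution")
  }
  expect_equal(apply_reclassification(mk("USH2A", "AR"))$flags,
               "usher_followup")
  expect_equal(apply_reclassification(mk("ABCA4", "AR"))$flags,
               "cone_rod_dystrophy")
  expect_equal(apply_reclassification(mk("RP2", "XL"))$flags, "x_linked")
  expect_equal(apply_reclassification(mk("RP1", "AD"))$flags,
               "autosomal_dominant")
  expect_equal(apply_reclassification(mk("EYS", "AR"))$flags, character(0))
  partial <- mk("USH2A", NA_character_)
  partial$status <- "partial"
  expect_equal(apply_reclassification(partial)$flags, character(0))
})

test_that("cohort summaries report detection and prior-allele rates", {
  mk <- function(status, prior = FALSE, gene = "EYS") {
    structure(list(family = "F", status = status, model = "AR",
                   gene = gene, alleles = NULL,
                   segregation = "not_available", flags = character(0),
                   review = FALSE, has_prior = prior),
              class = "rp_resolution")
  }
  res <- c(replicate(13, mk("solved", prior = TRUE), simplify = FALSE),
           replicate(14, mk("solved"), simplify = FALSE),
           replicate(5, mk("partial"), simplify = FALSE))
  s <- cohort_summary(res, 47)
  expect_equal(s$n_solved, 27)
  expect_equal(round(s$detection_rate_pct, 1), 57.4)
  expect_equal(s$n_solved_with_prior, 13)
  expect_equal(round(s$pct_solved_with_prior, 1), 48.1)
  expect_error(cohort_summary(res, 10), "smaller")
  z <- cohort_summary(list())
  expect_equal(z$n_solved, 0)
  expect_equal(z$detection_rate_pct, 0)
})

test_that("the curated cohort table reproduces the published outcomes", {
  fix <- load_cohort_fixture()
  expect_equal(nrow(fix$table), 27)
  res <- resolve_cohort_fixture(fix)
  status <- vapply(res, function(r) r$status, "")
  expect_true(all(status == "solved"))
  expect_equal(res[["RP-1201"]]$model, "XL")
  expect_true("x_linked" %in% res[["RP-1201"]]$flags)
  expect_equal(res[["RP-1772"]]$model, "AD")
  expect_true("autosomal_dominant" %in% res[["RP-1772"]]$flags)
  expect_true("cone_rod_dystrophy" %in% res[["RP-1543"]]$flags)
  for (f in c("RP-1735", "RP-1979", "RP-0338", "RP-0344")) {
    expect_true("usher_followup" %in% res[[f]]$flags, label = f)
  }
  # deletion alleles enter the configurations of the three CNV families
  for (f in c("RP-2112", "RP-1706", "RP-1929")) {
    expect_true("cnv" %in% res[[f]]$alleles$allele_type, label = f)
  }
  # solved families with a microarray-known first allele
  expect_equal(sum(vapply(res, function(r) r$has_prior, TRUE)), 13)
})
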