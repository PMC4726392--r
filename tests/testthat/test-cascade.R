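test_that("region filter keeps captured coding space and the whitelist", {
  panel <- get_panel()
  wl <- panel_whitelist(panel)
  cep <- wl[wl$gene == "CEP290", ]
  ex13 <- panel$regions[panel$regions$label == "EYS_ex13", ]
  v <- rbind(
    panel_var(panel, "EYS_ex13"),                      # missense in exon
    # intronic change 25 bp past the exon boundary: beyond the 20 bp flank
    var_row(gene = "EYS", chrom = ex13$chrom, pos = ex13$end + 5L,
            consequence = "noncanonical_splice"),
    # whitelisted deep-intronic position
    var_row(gene = "CEP290", chrom = cep$chrom, pos = cep$pos,
            consequence = "deep_intronic"),
    # deep-intronic away from any whitelist position
    var_row(gene = "EYS", chrom = ex13$chrom, pos = ex13$end + 500L,
            consequence = "deep_intronic"),
    # UTR consequence is excluded even at an in-panel coordinate
    panel_var(panel, "ABCA4_ex1", consequence = "utr")
  )
  out <- filter_by_region(v, panel)
  expect_equal(out$label,
               c(NA, "out_of_region", NA, "out_of_region", "out_of_region"))
  expect_error(filter_by_region(var_row(pos = NA), panel),
               "without coordinates")
})

test_that("frequency filter retains rare and unobserved variants", {
  v <- rbind(
    var_row(maf_exac = 0.00001),                      # rare in one db
    var_row(maf_1000g = 0.0016, maf_exac = 0.0003),   # max 0.0016 <= 0.005
    var_row(),                                        # no db record at all
    var_row(maf_exac = 0.01),                         # common
    var_row(maf_1000g = 0.005)                        # boundary: inclusive
  )
  out <- filter_by_maf(v, 0.005)
  expect_equal(out$label,
               c(NA, NA, NA, "benign_frequency", NA))
})

test_that("known-database membership needs an rs id plus a database hit", {
  v <- rbind(
    var_row(rs_id = "rs80338902", hgmd = TRUE),  # rs + HGMD -> known
    var_row(),                                   # novel, continues
    var_row(rs_id = "rs123")                     # rs but no db, continues
  )
  out <- classify_known(v)
  expect_equal(out$label, c("known_pathogenic", NA, NA))
  expect_equal(out$novel, c(FALSE, TRUE, FALSE))
  # literal both-databases policy
  cfg <- default_config(); cfg$require_both_dbs <- TRUE
  out2 <- classify_known(v, cfg)
  expect_true(is.na(out2$label[1]))
  v$lovd[1] <- TRUE
  out3 <- classify_known(v, cfg)
  expect_equal(out3$label[1], "known_pathogenic")
})

test_that("truncating consequences are pathogenic regardless of scores", {
  v <- rbind(
    var_row(consequence = "nonsense", protein = "p.Arg653*"),
    var_row(consequence = "canonical_splice"),
    var_row(consequence = "frameshift"),
    var_row(consequence = "synonymous")
  )
  out <- classify_by_consequence(v)
  expect_equal(out$label,
               c("lof_pathogenic", "lof_pathogenic", "lof_pathogenic", NA))
})

test_that("population-control screen excludes observed novel variants", {
  v <- rbind(
    var_row(spv_present = FALSE),
    var_row(spv_present = TRUE),
    var_row(spv_present = TRUE, rs_id = "rs1", hgmd = TRUE) # known: skipped
  )
  v <- classify_known(v)
  out <- screen_population_controls(v)
  expect_equal(out$label[1:2], c(NA, "benign_population"))
  expect_equal(out$label[3], "known_pathogenic")
  # frequency-threshold policy variant
  pol <- list(mode = "frequency", max_freq = 0.01)
  v2 <- classify_known(rbind(var_row(spv_present = TRUE, spv_freq = 0.002),
                             var_row(spv_present = TRUE, spv_freq = 0.05)))
  out2 <- screen_population_controls(v2, pol)
  expect_equal(out2$label, c(NA, "benign_population"))
})

# hand-evaluated eight-variant fixture: expected labels derived by
# applying the six rules manually, frozen here as the oracle
cascade_fixture <- function(panel) {
  rbind(
    panel_var(panel, "EYS_ex13", maf_exac = 1e-5, rs_id = "rs111",
              hgmd = TRUE),                                # known
    panel_var(panel, "USH2A_ex1", maf_1000g = 0.2,
              rs_id = "rs2"),                              # common
    panel_var(panel, "ABCA4_ex1", consequence = "utr"),    # out of region
    panel_var(panel, "CNGA1_ex3", consequence = "nonsense"), # LOF
    panel_var(panel, "PDE6A_ex2", spv_present = TRUE),     # in controls
    panel_var(panel, "CERKL_ex1", spv_present = FALSE, sift_call = "D",
              sift_score = 0.01, polyphen_call = "Pr.D",
              polyphen_score = 0.98, agvgd_class = "C65",
              mt_call = "D"),                              # 4 votes
    panel_var(panel, "RDH12_ex1", spv_present = FALSE, sift_call = "T",
              sift_score = 0.4, polyphen_call = "B",
              polyphen_score = 0.1, agvgd_class = "C15",
              mt_call = "D"),                              # 1 vote
    panel_var(panel, "EYS_ex14", offset = 160L + 500L,
              consequence = "deep_intronic")               # off-whitelist
  )
}

test_that("the full cascade reproduces the hand-derived labels", {
  panel <- get_panel()
  v <- cascade_fixture(panel)
  report <- run_cascade(v, panel)
  expect_equal(report$variants$label, c(
    "known_pathogenic", "benign_frequency", "out_of_region",
    "lof_pathogenic", "benign_population", "potentially_pathogenic",
    "uncertain", "out_of_region"
  ))
  expect_equal(report$variants$votes[6:7], c(4L, 1L))
  # per-stage bookkeeping: 8 -> 6 -> 5 -> 4 open -> 3 open -> 2 open
  sc <- report$stage_counts
  expect_equal(sc$stage, c("region", "maf", "known_db", "consequence",
                           "population_controls", "consensus"))
  expect_equal(sc$n_in, c(8L, 6L, 5L, 4L, 3L, 2L))
  expect_equal(sc$n_retained, c(6L, 5L, 4L, 3L, 2L, 1L))
  expect_equal(nrow(candidate_calls(report)), 3)
  # every input classified exactly once
  expect_equal(sum(!is.na(report$variants$label)), nrow(v))
})

test_that("an empty variant table yields an empty report", {
  panel <- get_panel()
  report <- run_cascade(cascade_fixture(panel)[0, ], panel)
  expect_equal(nrow(report$variants), 0)
  expect_true(all(report$stage_counts$n_in == 0))
})

test_that("a common synonymous SNP is removed before any consensus", {
  panel <- get_panel()
  v <- panel_var(panel, "EYS_ex13", consequence = "synonymous",
                 maf_1000g = 0.2)
  report <- run_cascade(v, panel)
  expect_equal(report$variants$label, "benign_frequency")
  expect_true(is.na(report$variants$votes))
})

test_that("stages are monotone and exhaustive on generated cohorts", {
  dir <- file.path(tempdir(), "cascade-prop")
  generate_cohort(sim_config(seed = 303, n_families = 10L), dir = dir)
  v <- suppressWarnings(
    read_variants(file.path(dir, "cohort.vcf"),
                  file.path(dir, "annotations.tsv")))
  panel <- read_panel(file.path(dir, "panel.bed"),
                      file.path(dir, "genes.tsv"))
  report <- run_cascade(v, panel)
  sc <- report$stage_counts
  # monotone: each stage retains a subset of its input
  expect_true(all(sc$n_retained <= sc$n_in))
  expect_true(all(diff(sc$n_in) <= 0))
  # exhaustive: every call classified exactly once
  expect_equal(sum(is.na(report$variants$label)), 0)
  expect_equal(nrow(report$variants), nrow(v))
  expect_true(all(report$variants$label %in% c(
    "known_pathogenic", "lof_pathogenic", "potentially_pathogenic",
    "benign_population", "benign_frequency", "out_of_region", "uncertain")))
})

test_that("region and frequency filters commute", {
  panel <- get_panel()
  v <- cascade_fixture(panel)
  a <- filter_by_maf(filter_by_region(v, panel))
  b <- filter_by_region(filter_by_maf(v), panel)
  expect_equal(is.na(a$label), is.na(b$label))
})
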