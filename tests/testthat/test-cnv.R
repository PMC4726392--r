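make_ratios <- function(panel, targets, ratio, eligible = TRUE,
                        sample = "S01", ref_depth = 300) {
  out <- data.frame(target = targets, ratio = ratio,
                    eligible = eligible, ref_depth = ref_depth,
                    stringsAsFactors = FALSE)
  attr(out, "sample") <- sample
  class(out) <- c("cnv_ratios", "data.frame")
  out
}

test_that("normalization is a per-sample median rescale", {
  mat <- matrix(c(100, 200, 300, 400, 500,
                  300, 600, 900, 1200, 1500,
                  100, 200, 300, 400, 500,
                  110, 190, 310, 420, 480), nrow = 5,
                dimnames = list(paste0("EYS_ex", 1:5), paste0("S", 1:4)))
  norm <- normalize_coverage(mat)
  # hand-computed: each column divided by its median (300, 900, 300, 310)
  expect_equal(norm[, 1], mat[, 1] / 300)
  expect_equal(norm[, 2], mat[, 2] / 900)
  expect_equal(norm[, 4], mat[, 4] / 310)
  # identical samples normalize identically; scaling is removed
  expect_equal(norm[, 1], norm[, 3])
  expect_equal(norm[, 1], norm[, 2])
  expect_error(normalize_coverage(mat[, 1, drop = FALSE]),
               "at least 2 samples")
  mat[, 2] <- 0
  expect_error(normalize_coverage(mat), "S2")
})

test_that("ratios compare a sample against its run-mate median", {
  # flat depths keep per-sample medians fixed when single targets change
  base <- matrix(300, nrow = 6, ncol = 6,
                 dimnames = list(paste0("EYS_ex", 1:6), paste0("S", 1:6)))
  norm <- normalize_coverage(base)
  rt <- compute_ratios(norm, "S1")
  expect_equal(rt$ratio, rep(1, 6))
  expect_true(all(rt$eligible))

  half <- base
  half["EYS_ex2", "S1"] <- 150
  rt2 <- compute_ratios(normalize_coverage(half), "S1")
  expect_equal(rt2$ratio[rt2$target == "EYS_ex2"], 0.5)

  # run-mate median below 100x masks the target whatever the ratio
  low <- base
  low["EYS_ex3", ] <- 90
  low["EYS_ex3", "S1"] <- 30
  rt3 <- compute_ratios(normalize_coverage(low), "S1")
  expect_false(rt3$eligible[rt3$target == "EYS_ex3"])
  expect_true(all(rt3$eligible[rt3$target != "EYS_ex3"]))

  zero <- base
  zero["EYS_ex4", setdiff(colnames(base), "S1")] <- 0
  rt4 <- compute_ratios(normalize_coverage(zero), "S1")
  expect_true(is.na(rt4$ratio[rt4$target == "EYS_ex4"]))
  expect_false(rt4$eligible[rt4$target == "EYS_ex4"])

  expect_warning(compute_ratios(normalize_coverage(base[, 1:2]), "S1"),
                 "run-mate")
})

test_that("threshold calls are strict and adjacent targets merge", {
  panel <- get_panel()
  eys <- paste0("EYS_ex", 1:20)
  r <- rep(1, 20)
  r[13:14] <- c(0.52, 0.48)
  calls <- call_cnvs(make_ratios(panel, eys, r), panel)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$type, "deletion")
  expect_equal(calls$span, "Ex.13-14")
  expect_equal(calls$n_targets, 2L)
  expect_equal(calls$mean_ratio, 0.5)

  # boundary ratios produce no call ("fell below" / "rose above")
  r2 <- rep(1, 20); r2[5] <- 0.7; r2[6] <- 1.2
  expect_equal(nrow(call_cnvs(make_ratios(panel, eys, r2), panel)), 0)

  # single-exon duplication
  r3 <- rep(1, 20); r3[7] <- 1.5
  dup <- call_cnvs(make_ratios(panel, eys, r3), panel)
  expect_equal(dup$type, "duplication")
  expect_equal(dup$span, "Ex.7")

  # five consecutive exons merge into one event
  ush <- paste0("USH2A_ex", 40:55)
  r4 <- rep(1, 16); r4[6:10] <- 0.5 # exons 45..49
  del <- call_cnvs(make_ratios(panel, ush, r4), panel)
  expect_equal(del$span, "Ex.45-49")
  expect_equal(del$n_targets, 5L)

  # same type, same gene, but not adjacent: two events
  r5 <- rep(1, 20); r5[c(3, 9)] <- 0.4
  two <- call_cnvs(make_ratios(panel, eys, r5), panel)
  expect_equal(nrow(two), 2)

  # ineligible targets never produce calls
  r6 <- rep(0.4, 20)
  none <- call_cnvs(make_ratios(panel, eys, r6, eligible = FALSE), panel)
  expect_equal(nrow(none), 0)
})

test_that("caller agrees with a brute-force recomputation", {
  panel <- get_panel()
  labels <- c(paste0("EYS_ex", 1:6), paste0("USH2A_ex", 1:4))
  for (seed in 1:8) {
    set.seed(seed)
    mat <- matrix(rpois(10 * 8, 300), nrow = 10,
                  dimnames = list(labels, paste0("S", 1:8)))
    # plant occasional events and low-coverage rows
    if (seed %% 2 == 0) mat[2:3, 1] <- rpois(2, 150)
    if (seed %% 3 == 0) mat[8, 1] <- rpois(1, 500)
    if (seed %% 4 == 0) mat[5, ] <- rpois(8, 60)
    calls <- detect_cnvs(mat, panel, samples = "S1")
    oracle <- brute_force_cnv(mat, panel, "S1")
    expect_equal(nrow(calls), length(oracle), label = paste("seed", seed))
    for (k in seq_along(oracle)) {
      expect_equal(calls$type[k], oracle[[k]]$type)
      expect_equal(calls$first_target[k], oracle[[k]]$first)
      expect_equal(calls$last_target[k], oracle[[k]]$last)
      expect_equal(calls$mean_ratio[k], oracle[[k]]$mean_ratio)
    }
  }
})

test_that("calls are invariant to rescaling any sample's depths", {
  panel <- get_panel()
  labels <- paste0("EYS_ex", 1:8)
  set.seed(99)
  mat <- matrix(rpois(8 * 6, 400), nrow = 8,
                dimnames = list(labels, paste0("S", 1:6)))
  mat[4:5, 2] <- rpois(2, 200)
  calls <- detect_cnvs(mat, panel, samples = "S2")
  scaled <- mat
  scaled[, 2] <- as.integer(mat[, 2] * 3)
  calls2 <- detect_cnvs(scaled, panel, samples = "S2")
  expect_equal(calls2, calls)
  # identical samples give zero calls
  flat <- matrix(rep(c(250L, 300L, 350L, 400L), 6), nrow = 4,
                 dimnames = list(paste0("EYS_ex", 1:4), paste0("S", 1:6)))
  expect_equal(nrow(detect_cnvs(flat, panel)), 0)
})

test_that("restriction keeps only candidate sample-gene pairs", {
  panel <- get_panel()
  labels <- c(paste0("EYS_ex", 1:4), paste0("USH2A_ex", 1:4))
  base <- matrix(rep(400L, 8 * 6), nrow = 8,
                 dimnames = list(labels, paste0("S", 1:6)))
  mat <- base
  mat["USH2A_ex2", "S1"] <- 200L # het-deletion scale drop
  mat["EYS_ex3", "S1"] <- 200L
  case_table <- data.frame(sample = "S1", gene = "USH2A",
                           stringsAsFactors = FALSE)
  res <- detect_cnvs(mat, panel, case_table = case_table)
  expect_equal(unique(res$gene), "USH2A")
  full <- detect_cnvs(mat, panel, samples = "S1")
  expect_setequal(full$gene, c("EYS", "USH2A"))
  # restriction never adds calls: restricted set is a subset
  expect_true(all(paste(res$sample, res$gene, res$span) %in%
                    paste(full$sample, full$gene, full$span)))
  # a sample with no candidate gene is skipped entirely
  none <- detect_cnvs(mat, panel,
                      case_table = data.frame(sample = "S2", gene = "EYS"))
  expect_equal(nrow(none), 0)
})

test_that("spiked heterozygous deletions are recovered at depth", {
  panel <- get_panel()
  events <- data.frame(sample = 1L, gene = "EYS", exon_from = 10L,
                       exon_to = 11L, copy = 1L)
  found <- 0L; fp <- 0L
  for (i in 1:10) {
    run <- simulate_coverage_run(panel, 8, events, depth_mean = 200,
                                 seed = 7000 + i)
    sub <- panel$regions$label[panel$regions$gene == "EYS"]
    calls <- detect_cnvs(run$matrix[sub, ], panel, samples = "S01")
    hit <- calls$type == "deletion" & calls$span == "Ex.10-11"
    found <- found + any(hit)
    fp <- fp + sum(!hit)
  }
  expect_equal(found, 10L) # sensitivity 1.0 across replicates
  expect_true(fp <= 1)     # stray calls bounded
})
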