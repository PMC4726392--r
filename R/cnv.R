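#' Library-size normalization of a coverage matrix
#'
#' Divides each sample's column by that sample's median target depth, so
#' columns become dimensionless relative coverages comparable across
#' samples of one run. The median is robust to the handful of targets a
#' real copy-number event shifts.
#'
#' @param mat Non-negative matrix, targets x samples (dimnames required).
#' @return The normalized numeric matrix; the raw input is retained in
#'   `attr(, "raw")` for downstream depth eligibility masking.
#' @export
normalize_coverage <- function(mat) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  if (ncol(mat) < 2) {
    stop("at least 2 samples are required for ratio computation",
         call. = FALSE)
  }
  if (any(mat < 0)) stop("depths must be non-negative", call. = FALSE)
  med <- apply(mat, 2L, stats::median)
  zero <- med <= 0
  if (any(zero)) {
    stop("sample(s) with non-positive median depth: ",
         paste(colnames(mat)[zero], collapse = ", "), call. = FALSE)
  }
  norm <- sweep(mat, 2L, med, "/")
  attr(norm, "raw") <- mat
  norm
}

#' Cross-sample coverage ratios for one test sample
#'
#' For each target, the test sample's normalized coverage divided by the
#' median normalized coverage of its run-mates. Targets whose run-mate
#' median raw depth falls below `min_ref_coverage` (default 100x) are
#' masked ineligible to avoid unreliable calls; a zero reference median
#' leaves the ratio undefined and the target ineligible.
#'
#' @param normalized Output of [normalize_coverage()].
#' @param test_sample Sample id (column) to test.
#' @param min_ref_coverage Minimum run-mate median raw depth (default
#'   100).
#' @param raw Raw depth matrix; defaults to the attribute stored by
#'   [normalize_coverage()].
#' @return A `cnv_ratios` object: data frame with `target`, `ratio`,
#'   `eligible`, `ref_depth`, plus the sample id as an attribute.
#' @export
compute_ratios <- function(normalized, test_sample, min_ref_coverage = 100,
                           raw = attr(normalized, "raw")) {
  if (!test_sample %in% colnames(normalized)) {
    stop("unknown test sample: ", test_sample, call. = FALSE)
  }
  if (is.null(raw)) stop("raw depth matrix required for eligibility",
                         call. = FALSE)
  others <- setdiff(colnames(normalized), test_sample)
  if (length(others) < 1) {
    stop("ratio computation needs at least one run-mate", call. = FALSE)
  }
  if (length(others) < 3) {
    warning(sprintf("only %d run-mate(s); ratios will be unstable",
                    length(others)), call. = FALSE)
  }
  ref_norm <- apply(normalized[, others, drop = FALSE], 1L, stats::median)
  ref_depth <- apply(raw[, others, drop = FALSE], 1L, stats::median)
  ratio <- ifelse(ref_norm > 0, normalized[, test_sample] / ref_norm, NA_real_)
  out <- data.frame(
    target = rownames(normalized),
    ratio = unname(ratio),
    eligible = unname(ref_depth >= min_ref_coverage & ref_norm > 0),
    ref_depth = unname(ref_depth),
    stringsAsFactors = FALSE
  )
  attr(out, "sample") <- test_sample
  class(out) <- c("cnv_ratios", "data.frame")
  out
}

exon_number <- function(label) {
  as.integer(sub("^.*_(?:ex|di)([0-9]+)$", "\\1", label))
}

span_label <- function(first_label, last_label) {
  a <- exon_number(first_label)
  b <- exon_number(last_label)
  if (is.na(a) || is.na(b) || a == b) {
    sprintf("Ex.%s", ifelse(is.na(a), first_label, a))
  } else {
    sprintf("Ex.%d-%d", a, b)
  }
}

#' Call copy-number events from a ratio track
#'
#' Per-target calls use strict thresholds: a deletion where the ratio
#' falls below `del_threshold` (default 0.7), a duplication where it
#' rises above `dup_threshold` (default 1.2); a ratio exactly at a
#' threshold is no call. Only eligible targets are considered. Calls on
#' targets adjacent in the panel's per-gene exon order, of the same type,
#' merge into one event (no gap tolerance); each event reports its span
#' and mean ratio.
#'
#' @param ratios A `cnv_ratios` object from [compute_ratios()].
#' @param panel An `rp_panel` supplying gene/exon adjacency.
#' @param del_threshold,dup_threshold Ratio thresholds.
#' @return A data frame of class `cnv_calls`: `sample`, `gene`, `type`,
#'   `span`, `first_target`, `last_target`, `n_targets`, `mean_ratio`.
#' @export
call_cnvs <- function(ratios, panel, del_threshold = 0.7,
                      dup_threshold = 1.2) {
  r <- panel$regions
  m <- match(r$label, ratios$target)
  calls <- list()
  for (g in unique(r$gene[!is.na(m)])) {
    sel <- which(r$gene == g & !is.na(m))
    # panel order within the gene is exon order
    trk <- ratios[m[sel], ]
    state <- ifelse(!trk$eligible | is.na(trk$ratio), "none",
             ifelse(trk$ratio < del_threshold, "deletion",
             ifelse(trk$ratio > dup_threshold, "duplication", "none")))
    runs <- rle(state)
    stop_idx <- cumsum(runs$lengths)
    start_idx <- stop_idx - runs$lengths + 1L
    for (k in seq_along(runs$values)) {
      if (runs$values[k] == "none") next
      i0 <- start_idx[k]; i1 <- stop_idx[k]
      calls[[length(calls) + 1L]] <- data.frame(
        sample = attr(ratios, "sample"),
        gene = g,
        type = runs$values[k],
        span = span_label(trk$target[i0], trk$target[i1]),
        first_target = trk$target[i0],
        last_target = trk$target[i1],
        n_targets = i1 - i0 + 1L,
        mean_ratio = mean(trk$ratio[i0:i1]),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(calls)) do.call(rbind, calls) else empty_cnv_calls()
  rownames(out) <- NULL
  class(out) <- c("cnv_calls", "data.frame")
  out
}

empty_cnv_calls <- function() {
  data.frame(
    sample = character(), gene = character(), type = character(),
    span = character(), first_target = character(),
    last_target = character(), n_targets = integer(),
    mean_ratio = numeric(), stringsAsFactors = FALSE
  )
}

#' Restrict CNV calls to candidate (sample, gene) pairs
#'
#' The diagnostic protocol analyzes copy number only in genes where a
#' sample already carries exactly one heterozygous pathogenic small
#' variant (a candidate for a second, structural allele). Given a case
#' table of such pairs, keeps only matching calls; with `restrict =
#' FALSE` semantics (pass `case_table = NULL` to [detect_cnvs()]) the
#' full call set is returned unchanged.
#'
#' @param calls A `cnv_calls` data frame.
#' @param case_table Data frame with columns `sample`, `gene`.
#' @return The filtered `cnv_calls`.
#' @export
restrict_to_candidates <- function(calls, case_table) {
  stopifnot(all(c("sample", "gene") %in% names(case_table)))
  keep <- paste(calls$sample, calls$gene) %in%
    paste(case_table$sample, case_table$gene)
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the coverage-ratio CNV caller over a run
#'
#' Normalizes the run's coverage matrix, computes per-sample ratio tracks
#' against run-mates and calls merged events. In restricted mode (a
#' `case_table` of sample/gene pairs) only candidate pairs are reported,
#' mirroring the diagnostic protocol; unrestricted mode analyzes every
#' sample.
#'
#' @param mat Raw coverage matrix, targets x samples.
#' @param panel An `rp_panel`.
#' @param samples Samples to test (default: all columns).
#' @param config Configuration list (thresholds and eligibility).
#' @param case_table Optional restriction table (`sample`, `gene`).
#' @return A `cnv_calls` data frame over the tested samples.
#' @export
detect_cnvs <- function(mat, panel, samples = colnames(mat),
                        config = default_config(), case_table = NULL) {
  norm <- normalize_coverage(mat)
  if (!is.null(case_table)) {
    samples <- intersect(samples, unique(case_table$sample))
  }
  calls <- lapply(samples, function(s) {
    ratios <- compute_ratios(norm, s, config$cnv$min_ref_coverage)
    call_cnvs(ratios, panel, config$cnv$del_threshold,
              config$cnv$dup_threshold)
  })
  out <- if (length(calls)) do.call(rbind, calls) else empty_cnv_calls()
  rownames(out) <- NULL
  if (!is.null(case_table)) out <- restrict_to_candidates(out, case_table)
  class(out) <- c("cnv_calls", "data.frame")
  out
}
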