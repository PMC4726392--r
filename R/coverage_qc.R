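#' Percent of bases covered at or above a depth threshold
#'
#' @param depths Numeric vector of per-base depths.
#' @param threshold Depth counted as covered (inclusive; default 10).
#' @return Percentage in `[0, 100]`.
#' @export
pct_covered <- function(depths, threshold = 10) {
  if (length(depths) == 0) {
    stop("empty depth vector", call. = FALSE)
  }
  100 * mean(depths >= threshold)
}

#' Per-gene, per-sample coverage quality control
#'
#' From a long per-base depth table computes, per (gene, sample), the
#' percent of coding bases covered at or above the threshold; per sample,
#' the mean depth and overall percent covered; and per gene, the
#' quartiles across samples of the percent-covered statistic (the numbers
#' behind a per-gene coverage boxplot). Quartiles use linear
#' interpolation between order statistics.
#'
#' @param depth_table Data frame with columns `gene`, `pos`, `sample`,
#'   `depth`.
#' @param threshold Depth counted as covered (default 10).
#' @return A `coverage_qc` object: list with `per_gene_sample`,
#'   `per_sample`, `per_gene` data frames and the threshold.
#' @export
coverage_qc <- function(depth_table, threshold = 10) {
  stopifnot(all(c("gene", "pos", "sample", "depth") %in% names(depth_table)))
  if (any(depth_table$depth < 0)) {
    stop("depths must be non-negative", call. = FALSE)
  }
  covered <- depth_table$depth >= threshold
  agg <- stats::aggregate(covered,
                          by = list(gene = depth_table$gene,
                                    sample = depth_table$sample),
                          FUN = mean)
  per_gene_sample <- data.frame(gene = agg$gene, sample = agg$sample,
                                pct_covered = 100 * agg$x,
                                stringsAsFactors = FALSE)
  per_gene_sample <- per_gene_sample[order(per_gene_sample$gene,
                                           per_gene_sample$sample), ]
  rownames(per_gene_sample) <- NULL

  sm <- stats::aggregate(depth_table$depth,
                         by = list(sample = depth_table$sample), FUN = mean)
  sc <- stats::aggregate(covered, by = list(sample = depth_table$sample),
                         FUN = mean)
  per_sample <- data.frame(sample = sm$sample, mean_depth = sm$x,
                           pct_covered = 100 * sc$x[match(sm$sample,
                                                          sc$sample)],
                           stringsAsFactors = FALSE)
  rownames(per_sample) <- NULL

  qs <- do.call(rbind, lapply(split(per_gene_sample$pct_covered,
                                    per_gene_sample$gene), function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(q1 = q[1], median = q[2], q3 = q[3])
  }))
  per_gene <- data.frame(gene = rownames(qs), qs, stringsAsFactors = FALSE)
  rownames(per_gene) <- NULL

  structure(list(per_gene_sample = per_gene_sample,
                 per_sample = per_sample,
                 per_gene = per_gene,
                 threshold = threshold),
            class = "coverage_qc")
}

#' @export
print.coverage_qc <- function(x, ...) {
  cat(sprintf("coverage_qc: %d gene(s) x %d sample(s), threshold %gx\n",
              nrow(x$per_gene), nrow(x$per_sample), x$threshold))
  invisible(x)
}

#' Boxplot statistics of per-sample coverage for one gene
#'
#' Five-number summary of the percent-covered values of one gene across
#' samples, with outliers flagged by the 1.5 x IQR rule: values below
#' `Q1 - 1.5 IQR` or above `Q3 + 1.5 IQR`. Quartiles use linear
#' interpolation between order statistics (quantile type 7).
#'
#' @param qc A `coverage_qc` object.
#' @param gene Gene symbol.
#' @return List with `min`, `q1`, `median`, `q3`, `max`, `iqr`,
#'   `lower_fence`, `upper_fence` and the `outliers` vector.
#' @export
gene_boxplot_stats <- function(qc, gene) {
  v <- qc$per_gene_sample$pct_covered[qc$per_gene_sample$gene == gene]
  if (length(v) == 0) stop("no QC rows for gene ", gene, call. = FALSE)
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lower <- q[1] - 1.5 * iqr
  upper <- q[3] + 1.5 * iqr
  list(min = min(v), q1 = q[1], median = q[2], q3 = q[3], max = max(v),
       iqr = iqr, lower_fence = lower, upper_fence = upper,
       outliers = v[v < lower | v > upper])
}

#' Fraction of genes with every base covered
#'
#' Percent of genes whose coding bases are all covered at or above the QC
#' threshold, reported per sample and pooled over the cohort (a gene
#' counts as fully covered in the pooled figure when it is fully covered
#' in every sample).
#'
#' @param qc A `coverage_qc` object.
#' @return List with `per_sample` (data frame `sample`,
#'   `pct_genes_fully_covered`) and `pooled` (scalar percent).
#' @export
fully_covered_fraction <- function(qc) {
  g <- qc$per_gene_sample
  full <- g$pct_covered >= 100
  agg <- stats::aggregate(full, by = list(sample = g$sample), FUN = mean)
  per_sample <- data.frame(sample = agg$sample,
                           pct_genes_fully_covered = 100 * agg$x,
                           stringsAsFactors = FALSE)
  by_gene <- stats::aggregate(full, by = list(gene = g$gene), FUN = all)
  list(per_sample = per_sample, pooled = 100 * mean(by_gene$x))
}
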