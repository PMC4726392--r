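#' Read a targets-by-samples coverage matrix
#'
#' The TSV has a header row naming the samples of one sequencing run and a
#' first column (`target`) naming panel target labels. Depths must be
#' non-negative integers; row and column order is preserved.
#'
#' @param tsv_path Path to the coverage TSV.
#' @return An integer matrix with target labels as row names and sample ids
#'   as column names.
#' @export
read_coverage_matrix <- function(tsv_path) {
  df <- utils::read.delim(tsv_path, stringsAsFactors = FALSE,
                          check.names = FALSE, colClasses = "character",
                          na.strings = c("NA", ""))
  if (names(df)[1] != "target") {
    stop("first column of a coverage matrix must be 'target'", call. = FALSE)
  }
  targets <- df[[1]]
  dup <- targets[duplicated(targets)]
  if (length(dup)) {
    stop("duplicate target label: ", dup[1], call. = FALSE)
  }
  samples <- names(df)[-1]
  mat <- matrix(NA_integer_, nrow = length(targets), ncol = length(samples),
                dimnames = list(targets, samples))
  for (j in seq_along(samples)) {
    raw <- df[[j + 1L]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val))
    if (length(bad)) {
      stop(sprintf("missing or non-numeric depth at target '%s', sample '%s'",
                   targets[bad[1]], samples[j]), call. = FALSE)
    }
    if (any(val < 0) || any(val != round(val))) {
      k <- which(val < 0 | val != round(val))[1]
      stop(sprintf("depth must be a non-negative integer at target '%s', sample '%s'",
                   targets[k], samples[j]), call. = FALSE)
    }
    mat[, j] <- as.integer(val)
  }
  mat
}

#' Write a coverage matrix
#'
#' Inverse of [read_coverage_matrix()]; a write-then-read round trip
#' reproduces the matrix exactly.
#'
#' @param mat Integer matrix, targets x samples, with dimnames.
#' @param tsv_path Output path.
#' @export
write_coverage_matrix <- function(mat, tsv_path) {
  df <- data.frame(target = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(tsv_path)
}
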