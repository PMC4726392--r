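#' @importFrom stats median quantile rbinom rnbinom runif setNames
NULL

# canonical variant key shared by VCF and annotation table
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

# columns of the annotation sidecar table; numeric/logical columns are typed
# on read so that empty fields become NA (missing, never zero)
ann_numeric_cols <- c(
  "maf_1000g", "maf_evs", "maf_exac", "spv_freq", "sift_score",
  "polyphen_score", "codon",
  "hsf_wt", "hsf_mut", "bdgp_wt", "bdgp_mut",
  "ast_wt", "ast_mut", "ng2_wt", "ng2_mut"
)
ann_logical_cols <- c(
  "hgmd", "lovd", "spv_present",
  "hsf_site_lost", "hsf_cryptic", "bdgp_site_lost", "bdgp_cryptic",
  "ast_site_lost", "ast_cryptic", "ng2_site_lost", "ng2_cryptic",
  "ese_motif_lost"
)
ann_character_cols <- c(
  "gene", "consequence", "rs_id", "protein",
  "sift_call", "polyphen_call", "agvgd_class", "mt_call"
)

consequence_levels <- c(
  "nonsense", "frameshift", "canonical_splice", "noncanonical_splice",
  "missense", "synonymous", "utr", "intergenic", "deep_intronic", "other"
)

#' Read per-sample annotated variants from a VCF plus annotation table
#'
#' The VCF supplies variant sites and per-sample genotypes; site-level
#' annotations (gene, consequence, database frequencies, predictor scores,
#' known-mutation-database membership, population-control presence) travel
#' in a sidecar TSV keyed by `chrom`, `pos`, `ref`, `alt`. One row is
#' returned per carried ALT allele per sample; reference and missing
#' genotypes are dropped. Zygosity is derived from the genotype string:
#' `het` for one ALT copy of two, `hom` for two, `hemi` for haploid calls.
#'
#' Annotation fields left empty in the TSV stay `NA`: a missing database
#' frequency means "no record", which the frequency filter treats as a
#' pass, and is never coerced to zero. Sites present in the VCF but absent
#' from the annotation table are kept with empty annotations and collected
#' into a warning report available as `attr(x, "unannotated")`.
#'
#' @param vcf_path Path to a VCF 4.x file (plain text; biallelic records).
#' @param annotation_tsv_path Path to the annotation TSV.
#' @return A data frame of class `rp_variants`, one row per (sample,
#'   variant), with a `key` column and all annotation columns.
#' @export
read_variants <- function(vcf_path, annotation_tsv_path) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (any(grepl(",", fix$ALT, fixed = TRUE))) {
    stop("multi-allelic VCF records are not supported; split them first",
         call. = FALSE)
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt)
  key <- variant_key(fix$CHROM, fix$POS, fix$REF, fix$ALT)

  rows <- list()
  for (s in samples) {
    g <- gt[, s]
    alleles <- strsplit(gsub("|", "/", g, fixed = TRUE), "/", fixed = TRUE)
    n_alt <- vapply(alleles, function(a) sum(a == "1"), 0L)
    ploidy <- vapply(alleles, function(a) sum(a %in% c("0", "1")), 0L)
    carrier <- !is.na(g) & n_alt > 0L
    if (!any(carrier)) next
    zyg <- ifelse(ploidy[carrier] == 1L, "hemi",
                  ifelse(n_alt[carrier] == 2L, "hom", "het"))
    rows[[s]] <- data.frame(
      sample = s,
      chrom = fix$CHROM[carrier],
      pos = as.integer(fix$POS[carrier]),
      ref = fix$REF[carrier],
      alt = fix$ALT[carrier],
      key = key[carrier],
      zygosity = zyg,
      stringsAsFactors = FALSE
    )
  }
  calls <- if (length(rows)) do.call(rbind, rows) else data.frame(
    sample = character(), chrom = character(), pos = integer(),
    ref = character(), alt = character(), key = character(),
    zygosity = character(), stringsAsFactors = FALSE
  )
  rownames(calls) <- NULL

  ann <- read_annotations(annotation_tsv_path)
  m <- match(calls$key, ann$key)
  unannotated <- sort(unique(calls$key[is.na(m)]))
  if (length(unannotated)) {
    warning("VCF site(s) missing from annotation table: ",
            paste(unannotated, collapse = ", "), call. = FALSE)
  }
  out <- cbind(calls, ann[m, setdiff(names(ann), c("chrom", "pos", "ref",
                                                   "alt", "key")),
                          drop = FALSE])
  rownames(out) <- NULL
  class(out) <- c("rp_variants", "data.frame")
  attr(out, "unannotated") <- unannotated
  out
}

read_annotations <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", na.strings = c("NA", ""))
  needed <- c("chrom", "pos", "ref", "alt")
  if (!all(needed %in% names(ann))) {
    stop("annotation table must have columns chrom, pos, ref, alt",
         call. = FALSE)
  }
  for (col in c(ann_numeric_cols, ann_logical_cols, ann_character_cols)) {
    if (!col %in% names(ann)) ann[[col]] <- NA
  }
  for (col in ann_numeric_cols) {
    raw <- ann[[col]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- !is.na(raw) & is.na(val)
    if (any(bad)) {
      stop(sprintf("unparsable numeric value '%s' in column '%s'",
                   raw[bad][1], col), call. = FALSE)
    }
    ann[[col]] <- val
  }
  for (col in ann_logical_cols) {
    ann[[col]] <- as.logical(ann[[col]])
  }
  maf_bad <- lapply(c("maf_1000g", "maf_evs", "maf_exac"), function(col) {
    v <- ann[[col]]
    which(!is.na(v) & (v < 0 | v > 1))
  })
  if (any(lengths(maf_bad) > 0)) {
    stop("MAF values must lie in [0, 1]", call. = FALSE)
  }
  ann$pos <- as.integer(ann$pos)
  ann$key <- variant_key(ann$chrom, ann$pos, ann$ref, ann$alt)
  if (anyDuplicated(ann$key)) {
    stop("duplicate annotation key: ", ann$key[duplicated(ann$key)][1],
         call. = FALSE)
  }
  ann
}

#' Write an annotation sidecar table
#'
#' Emits the site-level annotation TSV consumed by [read_variants()]. `NA`
#' values are written as empty fields so that a write-read round trip keeps
#' missing annotations missing.
#'
#' @param ann Data frame with at least `chrom`, `pos`, `ref`, `alt`.
#' @param path Output path.
#' @export
write_annotations <- function(ann, path) {
  cols <- c("chrom", "pos", "ref", "alt", ann_character_cols,
            ann_numeric_cols, ann_logical_cols)
  for (col in cols) if (!col %in% names(ann)) ann[[col]] <- NA
  utils::write.table(ann[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

# minimal plain-text VCF 4.2 writer: one biallelic row per site, GT-only
# FORMAT, genotypes supplied as a sites x samples character matrix with NA
# for no-calls. Kept internal; reading goes through vcfR.
write_vcf <- function(sites, gt, path, contigs = NULL) {
  stopifnot(nrow(sites) == nrow(gt))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=panelrp",
    if (!is.null(contigs)) sprintf("##contig=<ID=%s>", contigs),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(gt)), collapse = "\t")
  )
  gt[is.na(gt)] <- "./."
  body <- cbind(sites$chrom, sites$pos,
                ifelse(is.na(sites$id), ".", sites$id),
                sites$ref, sites$alt, ".", "PASS", ".", "GT", gt)
  lines <- apply(body, 1L, paste, collapse = "\t")
  writeLines(c(header, lines), path)
  invisible(path)
}
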