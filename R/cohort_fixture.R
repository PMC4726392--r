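#' Load the curated solved-families allele table
#'
#' The package ships a transcription of the published causal-allele table
#' of a 47-family autosomal recessive RP diagnostic cohort (the 27
#' families in which a molecular diagnosis was reached), with one row per
#' family: gene, both alleles with HGVS nomenclature, the detection
#' method per allele (`aC` genotyping microarray, `H` capture panel), the
#' literature reference and the segregation outcome. A `sex` column is a
#' synthetic augmentation: the published table has none, and only the
#' family resolved through the X-linked route is marked `M` (stated in
#' the source cohort's narrative).
#'
#' Alleles written `Deletion Ex.<i>-<j>` are exon-level copy-number
#' events and are returned as deletion calls rather than small variants.
#' Consequences are derived from the protein nomenclature (`fs` =
#' frameshift, terminal `*` = nonsense, `splicing defect` = canonical
#' splice, otherwise missense); all listed alleles carry a curated
#' pathogenic label, the table being the cohort's adjudicated truth.
#'
#' @param path Path to the TSV (defaults to the shipped fixture).
#' @return List with `cases` (list of [family_case()] objects),
#'   `variants` (curated labelled small-variant calls), `cnv_calls` and
#'   the raw `table`.
#' @export
load_cohort_fixture <- function(path = system.file(
  "extdata", "arrp_cohort_alleles.tsv", package = "panelrp")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", na.strings = "")
  cases <- list()
  var_rows <- list()
  cnv_rows <- list()
  for (i in seq_len(nrow(tab))) {
    fam <- tab$family[i]
    idx <- paste0("IDX-", fam)
    gene <- tab$gene[i]
    a1 <- list(cdna = tab$a1_cdna[i], protein = tab$a1_protein[i],
               method = tab$a1_method[i])
    a2 <- list(cdna = tab$a2_cdna[i], protein = tab$a2_protein[i],
               method = tab$a2_method[i])
    hom <- !is.na(a2$cdna) && identical(a1$cdna, a2$cdna)

    emit <- function(a, zyg) {
      if (is.na(a$cdna)) return(NULL)
      if (grepl("^Deletion", a$cdna)) {
        cnv_rows[[length(cnv_rows) + 1L]] <<- data.frame(
          sample = idx, gene = gene, type = "deletion",
          span = sub("^Deletion ", "", a$cdna),
          first_target = NA_character_, last_target = NA_character_,
          n_targets = NA_integer_, mean_ratio = NA_real_,
          stringsAsFactors = FALSE)
        return(NULL)
      }
      var_rows[[length(var_rows) + 1L]] <<- data.frame(
        sample = idx, gene = gene,
        key = paste(gene, a$cdna, sep = ":"),
        zygosity = zyg,
        consequence = fixture_consequence(a$protein, a$cdna),
        label = "known_pathogenic",
        protein = a$protein,
        method = a$method,
        stringsAsFactors = FALSE)
    }
    if (hom) {
      emit(a1, "hom")
    } else {
      emit(a1, "het")
      emit(a2, "het")
    }
    prior <- if (identical(a1$method, "aC")) paste(gene, a1$cdna, sep = ":")
             else NA_character_
    cases[[fam]] <- family_case(fam, idx, sex = tab$sex[i],
                                prior_allele = prior)
  }
  variants <- do.call(rbind, var_rows)
  rownames(variants) <- NULL
  cnv_calls <- if (length(cnv_rows)) do.call(rbind, cnv_rows) else NULL
  if (!is.null(cnv_calls)) {
    rownames(cnv_calls) <- NULL
    class(cnv_calls) <- c("cnv_calls", "data.frame")
  }
  list(cases = cases, variants = variants, cnv_calls = cnv_calls,
       table = tab)
}

fixture_consequence <- function(protein, cdna) {
  ifelse(grepl("splicing", protein %|NA|% ""), "canonical_splice",
  ifelse(grepl("fs", protein %|NA|% ""), "frameshift",
  ifelse(grepl("\\*$", protein %|NA|% ""), "nonsense", "missense")))
}

#' Resolve every family of the curated cohort table
#'
#' Runs [resolve_family()] and [apply_reclassification()] on each family
#' of the shipped solved-families table.
#'
#' @param fixture Output of [load_cohort_fixture()].
#' @param gene_model Gene table (default catalogue).
#' @param config Configuration list.
#' @return Named list of `rp_resolution` objects.
#' @export
resolve_cohort_fixture <- function(fixture = load_cohort_fixture(),
                                   gene_model = default_gene_table(),
                                   config = default_config()) {
  lapply(fixture$cases, function(case) {
    res <- resolve_family(case, fixture$variants, fixture$cnv_calls,
                          gene_model, config)
    apply_reclassification(res)
  })
}
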