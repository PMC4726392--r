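#' Construct a family case record
#'
#' @param family Family identifier.
#' @param index Index (proband) sample id.
#' @param sex Index sex, `"M"`, `"F"` or `"U"` (unknown).
#' @param prior_allele Optional variant key of an allele known before
#'   panel sequencing (e.g. from a genotyping microarray).
#' @param declared_inheritance `"arRP"` or `"sporadic"`; advisory only —
#'   X-linked and dominant resolutions may override it.
#' @param relatives Optional data frame of relatives: `sample`,
#'   `affected` (logical), `sex`.
#' @return A `family_case` list.
#' @export
family_case <- function(family, index, sex = "U", prior_allele = NA,
                        declared_inheritance = "arRP", relatives = NULL) {
  structure(list(family = family, index = index, sex = sex,
                 prior_allele = prior_allele,
                 declared_inheritance = declared_inheritance,
                 relatives = relatives),
            class = "family_case")
}

codon_of <- function(protein) {
  out <- suppressWarnings(
    as.integer(sub("^p\\.[A-Za-z]{3}([0-9]+).*$", "\\1", protein))
  )
  out[!grepl("^p\\.[A-Za-z]{3}[0-9]+", protein %|NA|% "")] <- NA_integer_
  out
}

`%|NA|%` <- function(x, repl) {
  x[is.na(x)] <- repl
  x
}

# pathogenic small-variant rows of one sample
sample_pathogenic <- function(labeled, sample) {
  labeled[labeled$sample == sample &
            labeled$label %in% pathogenic_labels, , drop = FALSE]
}

#' Search for a second allele given a known first allele
#'
#' Two-phase search mirroring the diagnostic protocol: first a direct
#' look for further pathogenic alleles (small variants or deletion
#' events) in the gene of the known allele; only when that gene yields
#' nothing does the search widen to the full candidate set genome-wide,
#' allowing a gene switch.
#'
#' @param case A `family_case` with `prior_allele` set.
#' @param labeled An `rp_variants` data frame carrying cascade labels.
#' @param cnv_calls Optional `cnv_calls` data frame.
#' @return A data frame of candidate allele rows (small variants, plus
#'   deletion CNV events marked by `allele_type == "cnv"`), with
#'   `attr(, "phase")` equal to 1 (same gene) or 2 (genome-wide).
#' @export
second_allele_search <- function(case, labeled, cnv_calls = NULL) {
  if (is.na(case$prior_allele)) {
    stop("second_allele_search requires a prior allele", call. = FALSE)
  }
  sample_calls <- labeled[labeled$sample == case$index, , drop = FALSE]
  prior_rows <- sample_calls[sample_calls$key == case$prior_allele, ,
                             drop = FALSE]
  if (nrow(prior_rows) == 0) {
    stop("prior allele ", case$prior_allele,
         " absent from the index call set", call. = FALSE)
  }
  g <- prior_rows$gene[1]
  path <- sample_pathogenic(labeled, case$index)
  path <- path[path$key != case$prior_allele, , drop = FALSE]
  cnv_alleles <- allele_rows_from_cnvs(cnv_calls, case$index)

  phase1 <- rbind_allele_rows(path[path$gene == g, , drop = FALSE],
                              cnv_alleles[cnv_alleles$gene == g, ,
                                          drop = FALSE])
  if (nrow(phase1) > 0) {
    attr(phase1, "phase") <- 1L
    return(phase1)
  }
  phase2 <- rbind_allele_rows(path, cnv_alleles)
  attr(phase2, "phase") <- 2L
  phase2
}

# deletion CNV events of one sample expressed as allele-like rows;
# duplications are reported by the caller but are not counted as
# pathogenic alleles (events of that class could not be confirmed by an
# orthogonal assay, so they stay observational)
allele_rows_from_cnvs <- function(cnv_calls, sample) {
  empty <- data.frame(sample = character(), gene = character(),
                      key = character(), zygosity = character(),
                      consequence = character(), label = character(),
                      allele_type = character(), protein = character(),
                      stringsAsFactors = FALSE)
  if (is.null(cnv_calls) || nrow(cnv_calls) == 0) return(empty)
  d <- cnv_calls[cnv_calls$sample == sample &
                   cnv_calls$type == "deletion", , drop = FALSE]
  if (nrow(d) == 0) return(empty)
  data.frame(sample = d$sample, gene = d$gene,
             key = paste0("cnv:", d$gene, ":", d$span),
             zygosity = "het", consequence = "exon_deletion",
             label = "lof_pathogenic", allele_type = "cnv",
             protein = NA_character_, stringsAsFactors = FALSE)
}

rbind_allele_rows <- function(small, cnv) {
  cols <- c("sample", "gene", "key", "zygosity", "consequence", "label",
            "protein")
  small <- small[, intersect(cols, names(small)), drop = FALSE]
  for (col in setdiff(cols, names(small))) small[[col]] <- NA_character_
  small$allele_type <- rep("small_variant", nrow(small))
  out <- rbind(small[, c(cols, "allele_type")], cnv[, c(cols, "allele_type")])
  rownames(out) <- NULL
  out
}

#' Resolve one family to a diagnostic verdict
#'
#' Combines the index sample's labelled small variants and deletion CNV
#' events and asks whether any gene satisfies its inheritance model:
#'
#' * autosomal recessive: a homozygous pathogenic allele, or two distinct
#'   heterozygous pathogenic alleles (small variants and/or an exon
#'   deletion) — without parental genotypes the trans configuration is
#'   assumed and the segregation field stays `not_available`;
#' * X-linked: a hemizygous (or single heterozygous-called) pathogenic
#'   allele in an XL gene in a male index;
#' * autosomal dominant: a single truncating allele inside a gene's
#'   configured dominant hotspot (RP1 by default).
#'
#' One pathogenic allele in exactly one recessive gene gives `partial`;
#' single alleles in two or more genes give `uncertain_two_genes`;
#' otherwise `unsolved`. A homozygous allele plus a distinct second
#' allele in the same gene is contradictory and sets the `review` flag
#' rather than being silently resolved. When relatives with genotypes
#' are available, the verdict is segregation-checked.
#'
#' @param case A `family_case`.
#' @param labeled An `rp_variants` data frame carrying labels (the
#'   `variants` element of a `cascade_report`, or curated calls).
#' @param cnv_calls Optional `cnv_calls` data frame.
#' @param gene_model Gene table with `inheritance` (and hotspot columns),
#'   as from [default_gene_table()].
#' @param config Configuration list.
#' @return An `rp_resolution` list: `family`, `status` (`solved`,
#'   `partial`, `uncertain_two_genes`, `unsolved`), `model` (`AR`, `XL`,
#'   `AD` or `NA`), `gene`, `alleles`, `segregation`, `flags`, `review`,
#'   `has_prior`.
#' @export
resolve_family <- function(case, labeled, cnv_calls = NULL,
                           gene_model = default_gene_table(),
                           config = default_config()) {
  path <- sample_pathogenic(labeled, case$index)
  alleles <- rbind_allele_rows(path, allele_rows_from_cnvs(cnv_calls,
                                                           case$index))
  alleles <- alleles[order(alleles$gene, alleles$key), , drop = FALSE]

  per_gene <- split(alleles, alleles$gene)
  solved_genes <- character(0)
  solved_model <- character(0)
  single_genes <- character(0)
  review <- FALSE

  for (g in names(per_gene)) {
    a <- per_gene[[g]]
    inh <- gene_model$inheritance[match(g, gene_model$gene)] %|NA|% "AR"
    dose <- ifelse(a$zygosity == "hom", 2L, 1L)
    n_alleles <- sum(dose)
    distinct <- length(unique(a$key))
    has_hom <- any(a$zygosity == "hom")
    if (has_hom && distinct > 1) review <- TRUE

    ar_ok <- grepl("AR", inh) && n_alleles >= 2
    xl_ok <- grepl("XL", inh) && identical(case$sex, "M") && n_alleles >= 1
    hs <- c(gene_model$hotspot_start[match(g, gene_model$gene)],
            gene_model$hotspot_end[match(g, gene_model$gene)])
    trunc <- a$consequence %in% c("nonsense", "frameshift")
    codons <- codon_of(a$protein)
    ad_ok <- grepl("AD", inh) && !anyNA(hs) &&
      any(trunc & !is.na(codons) & codons >= hs[1] & codons <= hs[2])

    if (ar_ok) {
      solved_genes <- c(solved_genes, g); solved_model <- c(solved_model, "AR")
    } else if (xl_ok) {
      solved_genes <- c(solved_genes, g); solved_model <- c(solved_model, "XL")
    } else if (ad_ok) {
      solved_genes <- c(solved_genes, g); solved_model <- c(solved_model, "AD")
    } else if (n_alleles == 1) {
      single_genes <- c(single_genes, g)
    }
  }

  if (length(solved_genes) > 0) {
    status <- "solved"
    gene <- solved_genes
    model <- solved_model
    if (length(solved_genes) > 1) {
      warning(sprintf(
        "family %s: full configurations in more than one gene (%s)",
        case$family, paste(solved_genes, collapse = ", ")), call. = FALSE)
    }
    causal <- alleles[alleles$gene %in% solved_genes, , drop = FALSE]
  } else if (length(single_genes) >= 2) {
    status <- "uncertain_two_genes"
    gene <- single_genes
    model <- NA_character_
    causal <- alleles[alleles$gene %in% single_genes, , drop = FALSE]
  } else if (length(single_genes) == 1) {
    status <- "partial"
    gene <- single_genes
    model <- NA_character_
    causal <- alleles[alleles$gene %in% single_genes, , drop = FALSE]
  } else {
    status <- "unsolved"
    gene <- NA_character_
    model <- NA_character_
    causal <- alleles[0, , drop = FALSE]
  }

  res <- structure(
    list(family = case$family, status = status, model = model[1],
         gene = gene, alleles = causal, segregation = "not_available",
         flags = character(0), review = review,
         has_prior = !is.na(case$prior_allele)),
    class = "rp_resolution"
  )
  if (!is.null(case$relatives) && nrow(case$relatives) > 0 &&
      status == "solved") {
    res$segregation <- check_segregation(res, case$relatives, labeled,
                                         config)
  }
  res
}

#' @export
print.rp_resolution <- function(x, ...) {
  cat(sprintf("family %s: %s%s%s\n", x$family, x$status,
              if (!is.na(x$model)) paste0(" (", x$model, ", ",
                                          paste(x$gene, collapse = "+"),
                                          ")") else "",
              if (length(x$flags)) paste0(" [",
                                          paste(x$flags, collapse = ","),
                                          "]") else ""))
  invisible(x)
}

#' Check co-segregation of a resolved genotype in the family
#'
#' For a recessive resolution, affected relatives must carry the full
#' causal configuration (both alleles, or the homozygous allele) and
#' unaffected relatives must not; for a dominant resolution an
#' unaffected carrier makes the verdict inconsistent unless the gene is
#' configured penetrance-exempt; for an X-linked resolution affected
#' males must carry the allele and unaffected males must not.
#'
#' @param resolution An `rp_resolution` with status `solved`.
#' @param relatives Data frame `sample`, `affected`, optional `sex`.
#' @param labeled An `rp_variants` data frame that includes the
#'   relatives' genotypes.
#' @param config Configuration list (penetrance exemptions).
#' @return `"consistent"`, `"inconsistent"` or `"not_available"`.
#' @export
check_segregation <- function(resolution, relatives, labeled,
                              config = default_config()) {
  if (is.null(relatives) || nrow(relatives) == 0) return("not_available")
  causal_keys <- unique(resolution$alleles$key[
    resolution$alleles$allele_type == "small_variant"])
  if (length(causal_keys) == 0) return("not_available")
  hom_config <- length(causal_keys) == 1 &&
    any(resolution$alleles$zygosity == "hom")
  exempt <- resolution$model %in% "AD" &&
    any(resolution$gene %in% config$penetrance_exempt_genes)

  for (i in seq_len(nrow(relatives))) {
    s <- relatives$sample[i]
    rows <- labeled[labeled$sample == s & labeled$key %in% causal_keys, ,
                    drop = FALSE]
    carries_full <- if (resolution$model %in% "AR") {
      if (hom_config) any(rows$zygosity == "hom")
      else all(causal_keys %in% rows$key)
    } else {
      nrow(rows) > 0
    }
    if (relatives$affected[i]) {
      if (!carries_full) return("inconsistent")
    } else {
      if (carries_full && !exempt) return("inconsistent")
    }
  }
  "consistent"
}

#' Default reclassification rules
#'
#' Rules are data, evaluated in order; several may fire on one family:
#' a solved USH2A family is flagged for audiological follow-up (the gene
#' causes both non-syndromic RP and Usher syndrome), a solved ABCA4
#' family for cone-rod dystrophy review, an X-linked resolution and a
#' dominant-hotspot resolution re-assign the inheritance pattern.
#'
#' @return Data frame with `gene` (`NA` matches any), `model` (`NA`
#'   matches any), `flag`.
#' @export
default_reclass_rules <- function() {
  data.frame(
    gene = c("USH2A", "ABCA4", NA, NA),
    model = c(NA, NA, "XL", "AD"),
    flag = c("usher_followup", "cone_rod_dystrophy", "x_linked",
             "autosomal_dominant"),
    stringsAsFactors = FALSE
  )
}

#' Apply reclassification rules to a resolution
#'
#' @param resolution An `rp_resolution`.
#' @param rules Rule table as from [default_reclass_rules()].
#' @return The resolution with matching flags appended.
#' @export
apply_reclassification <- function(resolution,
                                   rules = default_reclass_rules()) {
  if (!identical(resolution$status, "solved")) return(resolution)
  for (i in seq_len(nrow(rules))) {
    gene_ok <- is.na(rules$gene[i]) || rules$gene[i] %in% resolution$gene
    model_ok <- is.na(rules$model[i]) ||
      identical(rules$model[i], resolution$model)
    if (gene_ok && model_ok) {
      resolution$flags <- union(resolution$flags, rules$flag[i])
    }
  }
  resolution
}

#' Summarize a cohort of family resolutions
#'
#' @param resolutions List of `rp_resolution` objects.
#' @param cohort_size Number of families screened (must be at least the
#'   number of resolutions).
#' @return List with counts, the detection rate as a percent of the
#'   cohort, the fraction of solved families whose first allele predated
#'   the panel (`pct_solved_with_prior`), reclassification flag counts
#'   and a per-gene tally of solved families.
#' @export
cohort_summary <- function(resolutions, cohort_size = length(resolutions)) {
  if (cohort_size < length(resolutions)) {
    stop("cohort_size smaller than the number of resolutions",
         call. = FALSE)
  }
  status <- vapply(resolutions, function(r) r$status, "")
  solved <- resolutions[status == "solved"]
  n_solved <- length(solved)
  with_prior <- sum(vapply(solved, function(r) isTRUE(r$has_prior), TRUE))
  flags <- unlist(lapply(resolutions, function(r) r$flags))
  genes <- unlist(lapply(solved, function(r) r$gene))
  list(
    n_families = length(resolutions),
    cohort_size = cohort_size,
    n_solved = n_solved,
    n_partial = sum(status == "partial"),
    n_uncertain_two_genes = sum(status == "uncertain_two_genes"),
    n_unsolved = sum(status == "unsolved"),
    detection_rate_pct = if (cohort_size > 0) 100 * n_solved / cohort_size
                         else 0,
    n_solved_with_prior = with_prior,
    pct_solved_with_prior = if (n_solved > 0) 100 * with_prior / n_solved
                            else 0,
    flag_counts = if (length(flags)) table(flags) else table(character(0)),
    solved_genes = if (length(genes)) table(genes) else table(character(0))
  )
}
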