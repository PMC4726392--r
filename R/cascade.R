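pathogenic_labels <- c("known_pathogenic", "lof_pathogenic",
                       "potentially_pathogenic")
all_labels <- c(pathogenic_labels, "benign_population", "benign_frequency",
                "out_of_region", "uncertain")

# ensure the working columns used by the cascade stages exist
init_cascade_cols <- function(variants) {
  n <- nrow(variants)
  if (!"label" %in% names(variants)) variants$label <- rep(NA_character_, n)
  if (!"evidence" %in% names(variants))
    variants$evidence <- rep(NA_character_, n)
  if (!"novel" %in% names(variants)) variants$novel <- rep(NA, n)
  if (!"votes" %in% names(variants)) variants$votes <- rep(NA_integer_, n)
  variants
}

add_evidence <- function(evidence, tag) {
  ifelse(is.na(evidence), tag, paste(evidence, tag, sep = ";"))
}

#' Region filter (stage 1)
#'
#' Keeps variants in the captured coding space: inside a flanked coding
#' exon target, or at a deep-intronic whitelist position. Variants with
#' UTR or intergenic consequence, deep-intronic variants off the
#' whitelist, and variants outside every target are labelled
#' `out_of_region`. Panel coordinates are 0-based half-open, variant
#' positions 1-based; a variant at the first base of a target is inside
#' it.
#'
#' @param variants An `rp_variants` data frame.
#' @param panel An `rp_panel`.
#' @return The data frame with `label`/`evidence` set on removed rows;
#'   retained rows keep `label` `NA`.
#' @export
filter_by_region <- function(variants, panel) {
  variants <- init_cascade_cols(variants)
  open <- is.na(variants$label)
  if (!any(open)) return(variants)
  if (anyNA(variants$chrom[open]) || anyNA(variants$pos[open])) {
    stop("variant without coordinates cannot be region-filtered",
         call. = FALSE)
  }
  idx <- region_index_of(panel, variants$chrom, variants$pos)
  cls <- panel$regions$region_class[idx]
  in_exon <- !is.na(idx) & cls == "coding_exon_flanked"
  in_wl <- !is.na(idx) & cls == "deep_intronic_whitelist"
  csq <- variants$consequence
  keep <- ifelse(csq %in% c("utr", "intergenic"), FALSE,
          ifelse(csq %in% "deep_intronic", in_wl, in_exon | in_wl))
  out <- open & !keep
  variants$label[out] <- "out_of_region"
  variants$evidence[out] <- add_evidence(variants$evidence[out],
                                         "region:outside_captured_coding")
  variants
}

#' Minor allele frequency filter (stage 2)
#'
#' Retains a variant when the maximum frequency over the databases that
#' report one (1000 Genomes, EVS, ExAC) is at or below the threshold, or
#' when no database reports a frequency at all. A missing frequency is
#' treated as absence of evidence, never as zero.
#'
#' @param variants An `rp_variants` data frame.
#' @param threshold Retention threshold on the maximum MAF (default
#'   0.005).
#' @return The data frame with removed rows labelled `benign_frequency`.
#' @export
filter_by_maf <- function(variants, threshold = 0.005) {
  variants <- init_cascade_cols(variants)
  open <- is.na(variants$label)
  maf <- pmax(
    ifelse(is.na(variants$maf_1000g), -Inf, variants$maf_1000g),
    ifelse(is.na(variants$maf_evs), -Inf, variants$maf_evs),
    ifelse(is.na(variants$maf_exac), -Inf, variants$maf_exac)
  )
  out <- open & is.finite(maf) & maf > threshold
  variants$label[out] <- "benign_frequency"
  variants$evidence[out] <- add_evidence(
    variants$evidence[out], sprintf("maf:%g>threshold", maf[out]))
  variants
}

#' Known-mutation classification (stage 3)
#'
#' Variants carrying an rs identifier and recorded in a known-mutation
#' database (HGMD or LOVD; both required under `require_both_dbs`) are
#' labelled `known_pathogenic`. Variants without an rs identifier are
#' tagged novel and continue; rs-carrying variants without database
#' membership continue untagged.
#'
#' @param variants An `rp_variants` data frame.
#' @param config Configuration list.
#' @return The data frame with `label`, `evidence` and the `novel` tag
#'   updated.
#' @export
classify_known <- function(variants, config = default_config()) {
  variants <- init_cascade_cols(variants)
  open <- is.na(variants$label)
  has_rs <- !is.na(variants$rs_id) & nzchar(variants$rs_id)
  in_hgmd <- !is.na(variants$hgmd) & variants$hgmd
  in_lovd <- !is.na(variants$lovd) & variants$lovd
  in_db <- if (isTRUE(config$require_both_dbs)) in_hgmd & in_lovd
           else in_hgmd | in_lovd
  known <- open & has_rs & in_db
  variants$label[known] <- "known_pathogenic"
  variants$evidence[known] <- add_evidence(
    variants$evidence[known],
    paste0("known:rs+", ifelse(in_hgmd[known] & in_lovd[known], "HGMD+LOVD",
                               ifelse(in_hgmd[known], "HGMD", "LOVD"))))
  variants$novel[open] <- !has_rs[open]
  variants
}

#' Consequence classification (stage 4)
#'
#' Nonsense, frameshift and canonical splice-site variants are
#' loss-of-function and labelled `lof_pathogenic` regardless of predictor
#' annotations. Canonical means the two intronic bases adjacent to an
#' exon; more distal intronic changes are `noncanonical_splice` and take
#' the consensus route instead.
#'
#' @param variants An `rp_variants` data frame.
#' @return The data frame with LOF rows labelled.
#' @export
classify_by_consequence <- function(variants) {
  variants <- init_cascade_cols(variants)
  open <- is.na(variants$label)
  lof <- open & variants$consequence %in%
    c("nonsense", "frameshift", "canonical_splice")
  variants$label[lof] <- "lof_pathogenic"
  variants$evidence[lof] <- add_evidence(
    variants$evidence[lof], paste0("lof:", variants$consequence[lof]))
  variants
}

#' Population-control screen (stage 5)
#'
#' Novel missense and non-canonical splice variants observed in the
#' population-control exome set (267 healthy individuals) are labelled
#' `benign_population`; absent variants are forwarded to the in-silico
#' consensus. Under the `"presence"` policy any observation excludes;
#' under `"frequency"` only control frequencies above `max_freq` do.
#'
#' @param variants An `rp_variants` data frame.
#' @param spv_policy Policy list (`mode`, `max_freq`), e.g.
#'   `default_config()$spv_policy`.
#' @return The data frame with screened-out rows labelled.
#' @export
screen_population_controls <- function(variants,
                                       spv_policy = default_config()$spv_policy) {
  variants <- init_cascade_cols(variants)
  open <- is.na(variants$label)
  eligible <- open & isTRUE_vec(variants$novel) &
    variants$consequence %in% c("missense", "noncanonical_splice")
  present <- !is.na(variants$spv_present) & variants$spv_present
  out <- if (identical(spv_policy$mode, "frequency")) {
    eligible & present & !is.na(variants$spv_freq) &
      variants$spv_freq > spv_policy$max_freq
  } else {
    eligible & present
  }
  variants$label[out] <- "benign_population"
  variants$evidence[out] <- add_evidence(variants$evidence[out],
                                         "spv:present_in_controls")
  variants
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Run the six-stage prioritization cascade
#'
#' Applies, in fixed order: (1) region filter, (2) MAF filter, (3)
#' known-mutation classification, (4) loss-of-function consequence
#' classification, (5) population-control screen, (6) multi-predictor
#' consensus for the remaining missense and non-canonical splice
#' variants. Earlier labels short-circuit later stages. Every input
#' variant receives exactly one terminal label; variants that no stage
#' classifies (e.g. rare synonymous changes) end `uncertain`. The
#' candidate set comprises `known_pathogenic`, `lof_pathogenic` and
#' `potentially_pathogenic`.
#'
#' @param variants An `rp_variants` data frame.
#' @param panel An `rp_panel`.
#' @param config Configuration list.
#' @return A `cascade_report`: list with `variants` (the labelled data
#'   frame), `stage_counts` (per-stage input/retained counts) and
#'   `config`.
#' @export
run_cascade <- function(variants, panel, config = default_config()) {
  variants <- init_cascade_cols(variants)
  n_open <- function(v) sum(is.na(v$label))
  stages <- character(0); n_in <- integer(0); n_ret <- integer(0)
  step <- function(name, before, after) {
    stages <<- c(stages, name)
    n_in <<- c(n_in, before)
    n_ret <<- c(n_ret, after)
  }

  b <- n_open(variants)
  variants <- filter_by_region(variants, panel)
  step("region", b, n_open(variants))

  b <- n_open(variants)
  variants <- filter_by_maf(variants, config$maf_threshold)
  step("maf", b, n_open(variants))

  b <- n_open(variants)
  variants <- classify_known(variants, config)
  step("known_db", b, n_open(variants))

  b <- n_open(variants)
  variants <- classify_by_consequence(variants)
  step("consequence", b, n_open(variants))

  b <- n_open(variants)
  variants <- screen_population_controls(variants, config$spv_policy)
  step("population_controls", b, n_open(variants))

  b <- n_open(variants)
  open <- which(is.na(variants$label))
  for (i in open) {
    csq <- variants$consequence[i]
    if (identical(csq, "missense")) {
      res <- consensus_missense(variants[i, ], config$min_damaging_votes,
                                config)
    } else if (identical(csq, "noncanonical_splice")) {
      res <- consensus_splice(variants[i, ], config$min_damaging_votes,
                              config$splice_drop_fraction)
    } else {
      variants$label[i] <- "uncertain"
      next
    }
    variants$votes[i] <- res$votes
    variants$label[i] <- if (res$flagged) "potentially_pathogenic"
                         else "uncertain"
    variants$evidence[i] <- add_evidence(
      variants$evidence[i],
      sprintf("consensus:%d/%d_damaging", res$votes, res$n_predictors))
  }
  step("consensus", b,
       sum(variants$label[open] == "potentially_pathogenic"))

  variants$label[is.na(variants$label)] <- "uncertain"
  structure(
    list(
      variants = variants,
      stage_counts = data.frame(stage = stages, n_in = n_in,
                                n_retained = n_ret,
                                stringsAsFactors = FALSE),
      config = config
    ),
    class = "cascade_report"
  )
}

#' @export
print.cascade_report <- function(x, ...) {
  cat("cascade_report:", nrow(x$variants), "variant call(s)\n")
  print(x$stage_counts, row.names = FALSE)
  tab <- table(factor(x$variants$label, levels = all_labels))
  cat("labels:\n")
  print(tab)
  invisible(x)
}

#' Candidate pathogenic calls of a cascade report
#'
#' @param report A `cascade_report`.
#' @return The rows labelled `known_pathogenic`, `lof_pathogenic` or
#'   `potentially_pathogenic`.
#' @export
candidate_calls <- function(report) {
  v <- report$variants
  v[v$label %in% pathogenic_labels, , drop = FALSE]
}
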