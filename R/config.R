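#' Default pipeline configuration
#'
#' Collects every tunable constant of the interpretation pipeline in one
#' nested list. The defaults are the operating point of the diagnostic
#' workflow the package implements:
#'
#' * `maf_threshold = 0.005`: a variant is retained when its maximum minor
#'   allele frequency over the 1000 Genomes, EVS and ExAC databases is at or
#'   below this value, or when no database reports a frequency at all.
#' * `min_damaging_votes = 2`: a missense or non-canonical splice variant is
#'   flagged potentially pathogenic when at least this many in-silico
#'   predictors call it damaging.
#' * `splice_drop_fraction = 0.10`: a splice predictor without an explicit
#'   site-loss call votes damaging when its mutant score falls at least this
#'   fraction below the wild-type score.
#' * `agvgd_min_class = "C35"`: lowest Align-GVGD class counted as a
#'   damaging vote (C0--C25 do not vote).
#' * `require_both_dbs = FALSE`: whether a known-pathogenic call needs
#'   membership in both HGMD and LOVD rather than either.
#' * `spv_policy`: how presence in the population-control exome set excludes
#'   a novel variant; `mode = "presence"` excludes on any observation,
#'   `mode = "frequency"` excludes only above `max_freq`.
#' * `cnv`: deletion/duplication ratio thresholds (strict `< 0.7`, `> 1.2`),
#'   the `>= 100x` run-mate median depth eligibility mask and the minimum
#'   number of run-mates below which a warning is emitted.
#' * `coverage_threshold = 10`: per-base depth defining a "covered" base in
#'   QC summaries.
#' * `flank_bp = 20`: intronic flank included on each side of a coding exon
#'   target.
#' * `rp1_hotspot = c(500, 1053)`: codon interval of the RP1 domain in which
#'   a single heterozygous truncating allele is interpreted as autosomal
#'   dominant disease. The boundaries are package configuration, not a
#'   published interval.
#' * `penetrance_exempt_genes = "RP1"`: genes whose dominant alleles may be
#'   carried by unaffected relatives without the segregation verdict turning
#'   inconsistent (incomplete penetrance).
#'
#' @return A named list of configuration entries.
#' @seealso [read_config()]
#' @export
default_config <- function() {
  list(
    maf_threshold = 0.005,
    min_damaging_votes = 2,
    splice_drop_fraction = 0.10,
    agvgd_min_class = "C35",
    sift_score_cutoff = 0.05,
    require_both_dbs = FALSE,
    spv_policy = list(mode = "presence", max_freq = 0.01),
    cnv = list(
      del_threshold = 0.7,
      dup_threshold = 1.2,
      min_ref_coverage = 100,
      min_run_mates = 3
    ),
    coverage_threshold = 10,
    flank_bp = 20,
    rp1_hotspot = c(500L, 1053L),
    penetrance_exempt_genes = "RP1",
    seed = 1L
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Entries present in the file override the corresponding entries of
#' [default_config()]; everything else keeps its default. Nested sections
#' (`cnv`, `spv_policy`) are merged entry-wise.
#'
#' @param path Path to a YAML file.
#' @return A configuration list as from [default_config()].
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_config(), user)
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$maf_threshold > 0,
    cfg$min_damaging_votes >= 1,
    cfg$cnv$del_threshold > 0,
    cfg$cnv$dup_threshold > 0,
    cfg$cnv$min_ref_coverage > 0,
    cfg$coverage_threshold > 0
  )
  if (!(cfg$cnv$del_threshold < 1 && cfg$cnv$dup_threshold > 1)) {
    stop("cnv thresholds must bracket 1: del_threshold < 1 < dup_threshold",
         call. = FALSE)
  }
  invisible(cfg)
}
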