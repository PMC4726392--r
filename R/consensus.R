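agvgd_levels <- c("C0", "C15", "C25", "C35", "C45", "C55", "C65")

agvgd_rank <- function(class) {
  cl <- sub("^Class ", "", class)
  match(cl, agvgd_levels)
}

#' Missense predictor consensus
#'
#' Counts damaging votes over the four missense predictors and flags the
#' variant potentially pathogenic when at least `min_votes` agree. The
#' per-predictor damaging definitions (package configuration, overridable):
#'
#' * SIFT: call `"D"` (deleterious); when only a score is given, score
#'   below `sift_score_cutoff` (default 0.05).
#' * PolyPhen-2: call `"Pos.D"` or `"Pr.D"`.
#' * Align-GVGD: class at or above `agvgd_min_class` (default C35, so
#'   C0--C25 do not vote).
#' * MutationTaster: call `"D"` (disease causing).
#'
#' Predictors without an entry (all fields `NA`) are skipped; a profile
#' with no missense predictor entry at all is an annotation error. The
#' vote count depends only on which predictors voted, never on their
#' order.
#'
#' @param profile One-row data frame (or list) with fields `sift_call`,
#'   `sift_score`, `polyphen_call`, `polyphen_score`, `agvgd_class`,
#'   `mt_call`.
#' @param min_votes Votes required to flag (default 2).
#' @param config Configuration list supplying the damaging definitions.
#' @return List with `votes`, `n_predictors` (entries present) and
#'   `flagged`.
#' @export
consensus_missense <- function(profile, min_votes = 2L,
                               config = default_config()) {
  p <- as.list(profile)
  votes <- 0L
  n <- 0L
  if (!is.na(p$sift_call %||% NA) || !is.na(p$sift_score %||% NA)) {
    n <- n + 1L
    d <- if (!is.na(p$sift_call %||% NA)) {
      identical(p$sift_call, "D")
    } else {
      p$sift_score < config$sift_score_cutoff
    }
    votes <- votes + as.integer(isTRUE(d))
  }
  if (!is.na(p$polyphen_call %||% NA)) {
    n <- n + 1L
    votes <- votes + as.integer(p$polyphen_call %in% c("Pos.D", "Pr.D"))
  }
  if (!is.na(p$agvgd_class %||% NA)) {
    n <- n + 1L
    ok <- agvgd_rank(p$agvgd_class) >= agvgd_rank(config$agvgd_min_class)
    votes <- votes + as.integer(isTRUE(ok))
  }
  if (!is.na(p$mt_call %||% NA)) {
    n <- n + 1L
    votes <- votes + as.integer(identical(p$mt_call, "D"))
  }
  if (n == 0L) {
    stop("no missense predictor annotation present; annotate the variant",
         call. = FALSE)
  }
  list(votes = votes, n_predictors = n, flagged = votes >= min_votes)
}

splice_tools <- c("hsf", "bdgp", "ast", "ng2")

#' Splice predictor consensus
#'
#' Counts damaging votes over the four splice-site predictors (HSF, BDGP,
#' AST, NetGene2) plus ESEfinder and flags the variant potentially
#' pathogenic at `min_votes` agreeing calls. A site predictor votes
#' damaging when it reports the site lost, when it reports a new cryptic
#' site, or when the mutant score drops by at least `drop_fraction` of the
#' wild-type score. ESEfinder votes on loss of an enhancer motif.
#'
#' @param profile One-row data frame (or list) with, per tool `t` in
#'   `hsf`, `bdgp`, `ast`, `ng2`: `t_wt`, `t_mut`, `t_site_lost`,
#'   `t_cryptic`; plus `ese_motif_lost`.
#' @param min_votes Votes required to flag (default 2).
#' @param drop_fraction Relative score reduction counted as damaging
#'   (default 0.10).
#' @return List with `votes`, `n_predictors` and `flagged`.
#' @export
consensus_splice <- function(profile, min_votes = 2L, drop_fraction = 0.10) {
  p <- as.list(profile)
  votes <- 0L
  n <- 0L
  for (tool in splice_tools) {
    wt <- p[[paste0(tool, "_wt")]] %||% NA
    mut <- p[[paste0(tool, "_mut")]] %||% NA
    lost <- p[[paste0(tool, "_site_lost")]] %||% NA
    cryptic <- p[[paste0(tool, "_cryptic")]] %||% NA
    if (is.na(wt) && is.na(mut) && is.na(lost) && is.na(cryptic)) next
    n <- n + 1L
    if (!is.na(wt) && wt <= 0) {
      stop(sprintf("%s wild-type score must be positive", toupper(tool)),
           call. = FALSE)
    }
    d <- isTRUE(lost) || isTRUE(cryptic) ||
      (!is.na(wt) && !is.na(mut) && (wt - mut) / wt >= drop_fraction)
    votes <- votes + as.integer(d)
  }
  ese <- p$ese_motif_lost %||% NA
  if (!is.na(ese)) {
    n <- n + 1L
    votes <- votes + as.integer(isTRUE(ese))
  }
  if (n == 0L) {
    stop("no splice predictor annotation present; annotate the variant",
         call. = FALSE)
  }
  list(votes = votes, n_predictors = n, flagged = votes >= min_votes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
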