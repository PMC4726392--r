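# shared fixtures; everything is generated in code at test time

.fixture_env <- new.env(parent = emptyenv())

# the default 1127-target panel is deterministic; build it once
get_panel <- function() {
  if (is.null(.fixture_env$panel)) .fixture_env$panel <- build_panel()
  .fixture_env$panel
}

# one annotated-variant row with every column the cascade touches;
# override any field through ...
var_row <- function(sample = "S1", gene = "EYS", chrom = NA, pos = NA,
                    ref = "A", alt = "G", zygosity = "het",
                    consequence = "missense", ...) {
  row <- data.frame(
    sample = sample, chrom = chrom, pos = pos, ref = ref, alt = alt,
    key = paste(chrom, pos, ref, alt, sep = ":"),
    zygosity = zygosity, gene = gene, consequence = consequence,
    rs_id = NA_character_, protein = NA_character_,
    maf_1000g = NA_real_, maf_evs = NA_real_, maf_exac = NA_real_,
    hgmd = NA, lovd = NA, spv_present = NA, spv_freq = NA_real_,
    sift_call = NA_character_, sift_score = NA_real_,
    polyphen_call = NA_character_, polyphen_score = NA_real_,
    agvgd_class = NA_character_, mt_call = NA_character_,
    hsf_wt = NA_real_, hsf_mut = NA_real_, hsf_site_lost = NA,
    hsf_cryptic = NA,
    bdgp_wt = NA_real_, bdgp_mut = NA_real_, bdgp_site_lost = NA,
    bdgp_cryptic = NA,
    ast_wt = NA_real_, ast_mut = NA_real_, ast_site_lost = NA,
    ast_cryptic = NA,
    ng2_wt = NA_real_, ng2_mut = NA_real_, ng2_site_lost = NA,
    ng2_cryptic = NA,
    ese_motif_lost = NA,
    stringsAsFactors = FALSE
  )
  dots <- list(...)
  for (nm in names(dots)) row[[nm]] <- dots[[nm]]
  row$key <- paste(row$chrom, row$pos, row$ref, row$alt, sep = ":")
  row
}

# 1-based position inside the exon core of a labelled target
core_pos <- function(panel, label, offset = 5L) {
  r <- panel$regions[panel$regions$label == label, ]
  as.integer(r$start + 1L + panel$flank_bp + offset)
}

region_chrom <- function(panel, label) {
  panel$regions$chrom[panel$regions$label == label]
}

# variant row placed inside a named target of the panel
panel_var <- function(panel, label, offset = 5L, ...) {
  gene <- sub("_[^_]+$", "", label)
  var_row(gene = gene, chrom = region_chrom(panel, label),
          pos = core_pos(panel, label, offset), ...)
}

# curated in-silico predictor profiles (worked examples from the source
# cohort's assessment tables), used by consensus and acceptance tests
curated_missense_profiles <- function() {
  list(
    list(id = "CNGA1:p.Arg346Gln",
         profile = var_row(sift_call = "D", sift_score = 0,
                           polyphen_call = "Pos.D", polyphen_score = 0.852,
                           agvgd_class = "C35", mt_call = "D"),
         votes = 4L, flagged = TRUE),
    list(id = "RP2:p.Cys236Trp",
         profile = var_row(sift_call = "D", sift_score = 0,
                           polyphen_call = "Pr.D", polyphen_score = 0.997,
                           agvgd_class = "C65", mt_call = "D"),
         votes = 4L, flagged = TRUE),
    list(id = "USH2A:p.Cys3570Phe",
         profile = var_row(sift_call = "D", sift_score = 0,
                           polyphen_call = "Pr.D", polyphen_score = 0.996,
                           agvgd_class = "C65", mt_call = "D"),
         votes = 4L, flagged = TRUE),
    list(id = "USH2A:p.Leu3145Phe",
         profile = var_row(sift_call = "D", sift_score = 0.02,
                           polyphen_call = "Pos.D", polyphen_score = 0.598,
                           agvgd_class = "C15", mt_call = "P"),
         votes = 2L, flagged = TRUE),
    list(id = "USH2A:p.Lys1821Arg",
         profile = var_row(sift_call = "T", sift_score = 0.1,
                           polyphen_call = "B", polyphen_score = 0.096,
                           agvgd_class = "C25", mt_call = "P"),
         votes = 0L, flagged = FALSE),
    list(id = "EYS:p.Tyr2822Cys",
         profile = var_row(sift_call = NA, sift_score = NA,
                           polyphen_call = "Pr.D", polyphen_score = 0.997,
                           agvgd_class = "C0", mt_call = "P"),
         votes = 1L, flagged = FALSE),
    list(id = "USH2A:p.Gly1871Asp",
         profile = var_row(sift_call = "D", sift_score = 0,
                           polyphen_call = "Pr.D", polyphen_score = 0.995,
                           agvgd_class = "C65", mt_call = "D"),
         votes = 4L, flagged = TRUE)
  )
}

curated_splice_profiles <- function() {
  list(
    # donor-site loss with a confirming score drop and enhancer loss
    list(id = "PDE6A:c.1620+1G>T",
         profile = var_row(hsf_wt = 95.1, hsf_site_lost = TRUE,
                           bdgp_wt = 0.99, bdgp_site_lost = TRUE,
                           ast_wt = 86.85, ast_mut = 69.73,
                           ng2_wt = 0.82, ng2_site_lost = TRUE,
                           ese_motif_lost = TRUE),
         votes = 5L, flagged = TRUE),
    list(id = "PRCD:c.74+1G>A",
         profile = var_row(hsf_wt = 79.8, hsf_site_lost = TRUE,
                           bdgp_wt = 0.45, bdgp_site_lost = TRUE,
                           ast_wt = 67.08, ast_mut = 49.96,
                           ng2_wt = 0.7, ng2_site_lost = TRUE,
                           ese_motif_lost = TRUE),
         votes = 5L, flagged = TRUE),
    # cryptic acceptor creation reported by three tools plus SRp40 loss
    list(id = "CNGB1:c.2634+6G>A",
         profile = var_row(hsf_wt = 80, hsf_cryptic = TRUE,
                           bdgp_wt = 0.8, bdgp_cryptic = TRUE,
                           ng2_wt = 0.8, ng2_cryptic = TRUE,
                           ese_motif_lost = TRUE),
         votes = 4L, flagged = TRUE)
  )
}

# independent brute-force CNV recomputation: explicit loops, no shared
# code with the caller
brute_force_cnv <- function(mat, panel, test_sample, min_ref = 100,
                            del = 0.7, dup = 1.2) {
  norm <- mat
  for (j in seq_len(ncol(mat))) {
    norm[, j] <- mat[, j] / median(mat[, j])
  }
  others <- setdiff(colnames(mat), test_sample)
  states <- character(nrow(mat))
  names(states) <- rownames(mat)
  ratios <- rep(NA_real_, nrow(mat))
  names(ratios) <- rownames(mat)
  for (t in rownames(mat)) {
    refs <- numeric(0); raws <- numeric(0)
    for (o in others) {
      refs <- c(refs, norm[t, o]); raws <- c(raws, mat[t, o])
    }
    rn <- median(refs)
    ratio <- if (rn > 0) norm[t, test_sample] / rn else NA
    ratios[t] <- ratio
    eligible <- median(raws) >= min_ref && rn > 0
    states[t] <- if (!eligible || is.na(ratio)) "none"
                 else if (ratio < del) "deletion"
                 else if (ratio > dup) "duplication"
                 else "none"
  }
  events <- list()
  for (g in unique(panel$regions$gene)) {
    labs <- panel$regions$label[panel$regions$gene == g]
    labs <- labs[labs %in% rownames(mat)]
    if (!length(labs)) next
    cur_type <- "none"; start <- NULL
    for (i in seq_along(labs)) {
      st <- unname(states[labs[i]])
      if (st != cur_type) {
        if (cur_type != "none") {
          events[[length(events) + 1L]] <- list(
            gene = g, type = cur_type, first = unname(labs[start]),
            last = unname(labs[i - 1L]),
            mean_ratio = unname(mean(ratios[labs[start:(i - 1L)]])))
        }
        cur_type <- st; start <- i
      }
    }
    if (cur_type != "none") {
      events[[length(events) + 1L]] <- list(
        gene = g, type = cur_type, first = unname(labs[start]),
        last = unname(labs[length(labs)]),
        mean_ratio = unname(mean(ratios[labs[start:length(labs)]])))
    }
  }
  events
}
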