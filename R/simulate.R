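#' Simulation configuration for synthetic cohorts
#'
#' Bundles the study conditions a synthetic diagnostic cohort emulates: a
#' 47-family recessive/sporadic RP cohort sequenced in 8-sample runs.
#' The default causal scenario mix reproduces the composition of the
#' reference cohort (6 homozygous, 16 compound-heterozygous, 3 small
#' variant + exon deletion, 4 single-allele, 1 X-linked male, 1
#' dominant-hotspot, 16 families with no causal configuration).
#'
#' Coverage noise places negative-binomial variation on per-target read
#' counts (roughly `read_factor` reads per unit depth for 150 bp reads
#' on exon-sized targets) and derives the integer mean depth from the
#' count, with lognormal per-sample library-size and per-target capture
#' efficiency factors on the mean; heterozygous deletions and
#' duplications scale a target's expected depth by copy/2 (0.5 and 1.5).
#'
#' Predictor profiles are drawn class-conditionally: causal missense
#' alleles always retain at least two damaging calls and benign ones at
#' most one, with the remaining predictors flipped independently at the
#' confusion probability, so the two-vote consensus — not any single
#' predictor — separates the classes.
#'
#' @param seed Integer seed; equal seeds give byte-identical cohorts.
#' @param n_families Number of families (one index sample each).
#' @param samples_per_run Samples pooled per sequencing run (default 8).
#' @param scenario_mix Named proportions over `hom`, `compound_het`,
#'   `het_cnv`, `single_allele`, `xl_male`, `ad_hotspot`, `none`; must
#'   sum to 1.
#' @param prior_fraction Fraction of solved families whose first allele
#'   is already known from a genotyping microarray (emitted as
#'   `prior_allele`).
#' @param causal_class_mix Proportions of loss-of-function, missense and
#'   non-canonical splice alleles among causal small variants.
#' @param n_background_rare,n_background_common Background variants per
#'   sample (rare benign-profile and common polymorphic).
#' @param maf_absent_prob Probability a rare variant has no database
#'   frequency at all.
#' @param predictor_confusion Per-predictor flip probability for the
#'   unconstrained predictors of a profile.
#' @param depth_mean Expected per-target depth at copy number 2.
#' @param nb_size Negative-binomial size of the per-target read count.
#' @param read_factor Reads per unit depth.
#' @param sample_factor_sd,target_factor_sd Lognormal sd of the
#'   library-size and capture-efficiency factors.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_families = 47L,
                       samples_per_run = 8L,
                       scenario_mix = c(hom = 6, compound_het = 16,
                                        het_cnv = 3, single_allele = 4,
                                        xl_male = 1, ad_hotspot = 1,
                                        none = 16) / 47,
                       prior_fraction = 13 / 27,
                       causal_class_mix = c(lof = 0.5, missense = 0.35,
                                            splice = 0.15),
                       n_background_rare = 3L,
                       n_background_common = 5L,
                       maf_absent_prob = 0.3,
                       predictor_confusion = 0.1,
                       depth_mean = 300,
                       nb_size = 2e4,
                       read_factor = 2,
                       sample_factor_sd = 0.1,
                       target_factor_sd = 0.3) {
  if (abs(sum(scenario_mix) - 1) > 1e-8) {
    stop("scenario_mix must sum to 1", call. = FALSE)
  }
  stopifnot(nb_size > 0, depth_mean > 0, samples_per_run >= 2)
  structure(as.list(environment()), class = "sim_config")
}

# largest-remainder apportionment of n among named proportions
apportion <- function(mix, n) {
  raw <- mix * n
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(mix))
}

bases <- c("A", "C", "G", "T")

# registry-backed fabrication of a variant site inside a gene's coding
# targets; guarantees key uniqueness across the cohort
new_site <- function(panel, gene, used, indel = FALSE, flank_offset = NA) {
  r <- panel$regions
  sel <- r[r$gene == gene & r$region_class == "coding_exon_flanked", ,
           drop = FALSE]
  repeat {
    row <- sel[sample.int(nrow(sel), 1L), ]
    core_start <- row$start + 1L + panel_flank(panel)
    core_end <- row$end - panel_flank(panel)
    pos <- if (is.na(flank_offset)) {
      core_start + sample.int(core_end - core_start + 1L, 1L) - 1L
    } else if (flank_offset < 0) {
      core_start + flank_offset # intronic, 5' flank
    } else {
      core_end + flank_offset
    }
    ref <- sample(bases, 1L)
    alt <- sample(setdiff(bases, ref), 1L)
    if (indel) ref <- paste0(ref, sample(bases, 1L))
    key <- variant_key(row$chrom, pos, ref, alt)
    if (!key %in% ls(used)) {
      assign(key, TRUE, envir = used)
      return(list(chrom = row$chrom, pos = pos, ref = ref, alt = alt,
                  key = key, label_region = row$label))
    }
  }
}

panel_flank <- function(panel) panel$flank_bp

# class-conditional missense predictor profile
draw_missense_profile <- function(damaging, confusion) {
  calls <- if (damaging) {
    keep <- sample.int(4L, 2L) # two predictors never flip
    vapply(1:4, function(i) {
      if (i %in% keep) TRUE else runif(1) > confusion
    }, TRUE)
  } else {
    flip <- sample.int(4L, 1L) # at most one predictor may flip
    vapply(1:4, function(i) {
      if (i == flip) runif(1) < confusion else FALSE
    }, TRUE)
  }
  list(
    sift_call = if (calls[1]) "D" else "T",
    sift_score = round(if (calls[1]) runif(1, 0, 0.04)
                       else runif(1, 0.2, 0.9), 3),
    polyphen_call = if (calls[2]) sample(c("Pr.D", "Pos.D"), 1L,
                                         prob = c(0.7, 0.3)) else "B",
    polyphen_score = round(if (calls[2]) runif(1, 0.6, 1)
                           else runif(1, 0, 0.3), 3),
    agvgd_class = if (calls[3]) sample(c("C45", "C55", "C65"), 1L)
                  else sample(c("C0", "C15", "C25"), 1L),
    mt_call = if (calls[4]) "D" else "P"
  )
}

draw_splice_profile <- function(damaging, confusion) {
  calls <- if (damaging) {
    keep <- sample.int(4L, 2L)
    vapply(1:4, function(i) if (i %in% keep) TRUE else runif(1) > confusion,
           TRUE)
  } else {
    flip <- sample.int(4L, 1L)
    vapply(1:4, function(i) if (i == flip) runif(1) < confusion else FALSE,
           TRUE)
  }
  prof <- list()
  tools <- c("hsf", "bdgp", "ast", "ng2")
  scales <- c(hsf = 100, bdgp = 1, ast = 100, ng2 = 1)
  for (i in seq_along(tools)) {
    wt <- round(runif(1, 0.6, 0.99) * scales[[tools[i]]], 2)
    drop <- if (calls[i]) runif(1, 0.2, 1) else runif(1, 0, 0.05)
    prof[[paste0(tools[i], "_wt")]] <- wt
    prof[[paste0(tools[i], "_mut")]] <- round(wt * (1 - drop), 2)
    prof[[paste0(tools[i], "_site_lost")]] <- calls[i] && drop > 0.9
    prof[[paste0(tools[i], "_cryptic")]] <- FALSE
  }
  prof$ese_motif_lost <- if (damaging) runif(1) > confusion
                         else runif(1) < confusion
  prof
}

empty_ann_row <- function() {
  out <- list()
  for (col in ann_character_cols) out[[col]] <- NA_character_
  for (col in ann_numeric_cols) out[[col]] <- NA_real_
  for (col in ann_logical_cols) out[[col]] <- NA
  out
}

rare_maf <- function(absent_prob) {
  if (runif(1) < absent_prob) return(list())
  dbs <- sample(c("maf_1000g", "maf_evs", "maf_exac"),
                sample.int(2L, 1L))
  stats::setNames(as.list(signif(10^runif(length(dbs), -5, -2.5), 2)), dbs)
}

common_maf <- function() {
  f <- round(runif(1, 0.01, 0.3), 4)
  list(maf_1000g = f, maf_exac = round(f * runif(1, 0.8, 1.2), 4))
}

aa3 <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His",
         "Leu", "Lys", "Met", "Phe", "Ser", "Thr", "Trp", "Tyr", "Val")

fab_protein <- function(consequence, codon = sample(20:1500, 1L)) {
  a <- sample(aa3, 1L)
  b <- sample(aa3, 1L)
  switch(consequence,
    nonsense = sprintf("p.%s%d*", a, codon),
    frameshift = sprintf("p.%s%d%sfs*%d", a, codon, b, sample(3:40, 1L)),
    missense = sprintf("p.%s%d%s", a, codon, b),
    NA_character_)
}

#' Generate a seed-reproducible synthetic diagnostic cohort
#'
#' Emits, in the exact dialects the package reads back, a full synthetic
#' cohort: a multi-sample VCF of small-variant calls, the site-level
#' annotation TSV, per-run coverage matrices with spiked deletion
#' events, a family table and the generating truth. Causal alleles
#' receive damaging-class predictor profiles and sub-threshold (or
#' absent) database frequencies; background common variants receive
#' common frequencies; spiked copy-number events scale expected depth by
#' copy/2.
#'
#' @param config A [sim_config()].
#' @param dir Optional directory; when given, all files are written
#'   there (`panel.bed`, `genes.tsv`, `cohort.vcf`, `annotations.tsv`,
#'   `families.tsv`, `coverage_run<k>.tsv`, `truth.json`).
#' @param panel An `rp_panel` (default full 1127-target panel).
#' @return List with `sites`, `gt`, `annotations`, `families`,
#'   `coverage` (list of matrices), `truth` and, if written, `dir`.
#' @export
generate_cohort <- function(config = sim_config(), dir = NULL,
                            panel = build_panel()) {
  set.seed(config$seed)
  n <- config$n_families
  counts <- apportion(config$scenario_mix, n)
  scenarios <- sample(rep(names(counts), counts))
  fams <- sprintf("FAM%03d", seq_len(n))
  samples <- sprintf("S%03d", seq_len(n))
  sex <- ifelse(scenarios == "xl_male", "M", sample(c("M", "F"), n,
                                                    replace = TRUE))

  genes <- panel$genes
  ar_genes <- genes$gene[genes$inheritance == "AR"]
  xl_genes <- genes$gene[genes$inheritance == "XL"]
  used <- new.env(parent = emptyenv())

  sites <- list()     # one per variant site
  ann <- list()
  gt_entries <- list() # (site key, sample, gt string)
  truth_fam <- list()
  cnv_events <- list()
  prior_of <- stats::setNames(rep(NA_character_, n), fams)

  solved_scen <- c("hom", "compound_het", "het_cnv", "xl_male",
                   "ad_hotspot")
  solved_idx <- which(scenarios %in% solved_scen)
  n_prior <- round(config$prior_fraction * length(solved_idx))
  prior_idx <- if (n_prior > 0) sample(solved_idx, n_prior) else integer(0)

  add_site <- function(site, gene, consequence, ann_extra, sample, gt) {
    k <- site$key
    if (is.null(sites[[k]])) {
      row <- empty_ann_row()
      row$gene <- gene
      row$consequence <- consequence
      row[names(ann_extra)] <- ann_extra
      sites[[k]] <<- list(chrom = site$chrom, pos = site$pos,
                          ref = site$ref, alt = site$alt,
                          id = ann_extra$rs_id %||% NA_character_)
      ann[[k]] <<- row
    }
    gt_entries[[length(gt_entries) + 1L]] <<- list(key = k, sample = sample,
                                                   gt = gt)
  }

  # one causal small allele; known = database-recorded (rs + HGMD)
  causal_allele <- function(gene, sample, gt, known, class = NULL,
                            codon = NULL, consequence = NULL) {
    class <- class %||% sample(names(config$causal_class_mix), 1L,
                               prob = config$causal_class_mix)
    extra <- empty_ann_row()[c()] # start empty list
    if (class == "lof") {
      consequence <- consequence %||% sample(c("nonsense", "frameshift",
                                               "canonical_splice"), 1L)
      site <- new_site(panel, gene, used,
                       indel = consequence == "frameshift",
                       flank_offset = if (consequence == "canonical_splice")
                         -1L else NA)
      extra$protein <- fab_protein(
        if (consequence == "canonical_splice") "other" else consequence,
        codon %||% sample(20:1500, 1L))
    } else if (class == "missense") {
      consequence <- "missense"
      site <- new_site(panel, gene, used)
      extra <- c(extra, draw_missense_profile(TRUE,
                                              config$predictor_confusion))
      extra$protein <- fab_protein("missense")
      extra$spv_present <- FALSE
    } else {
      consequence <- "noncanonical_splice"
      site <- new_site(panel, gene, used, flank_offset = -6L)
      extra <- c(extra, draw_splice_profile(TRUE,
                                            config$predictor_confusion))
      extra$spv_present <- FALSE
    }
    extra <- c(extra, rare_maf(config$maf_absent_prob))
    if (known) {
      extra$rs_id <- sprintf("rs%d", sample.int(9e6, 1L) + 1e7)
      extra$hgmd <- TRUE
      extra$lovd <- runif(1) < 0.5
    }
    add_site(site, gene, consequence, extra, sample, gt)
    site$key
  }

  background <- function(sample) {
    g_rare <- sample(ar_genes, config$n_background_rare, replace = TRUE)
    for (g in g_rare) {
      roll <- runif(1)
      if (roll < 0.5) { # rare benign-profile missense
        site <- new_site(panel, g, used)
        extra <- draw_missense_profile(FALSE, config$predictor_confusion)
        extra$spv_present <- runif(1) < 0.5
        extra$spv_freq <- if (isTRUE(extra$spv_present))
          round(runif(1, 0.002, 0.05), 4) else NA_real_
        extra$protein <- fab_protein("missense")
        extra <- c(extra, rare_maf(config$maf_absent_prob))
        add_site(site, g, "missense", extra, sample, "0/1")
      } else { # rare synonymous
        site <- new_site(panel, g, used)
        extra <- rare_maf(config$maf_absent_prob)
        add_site(site, g, "synonymous", extra, sample, "0/1")
      }
    }
    g_common <- sample(ar_genes, config$n_background_common, replace = TRUE)
    for (g in g_common) {
      site <- new_site(panel, g, used)
      extra <- common_maf()
      extra$rs_id <- sprintf("rs%d", sample.int(9e6, 1L))
      if (runif(1) < 0.5) {
        extra <- c(extra, draw_missense_profile(FALSE,
                                                config$predictor_confusion))
        csq <- "missense"
      } else {
        csq <- "synonymous"
      }
      add_site(site, g, csq, extra, sample, sample(c("0/1", "1/1"), 1L,
                                                   prob = c(0.7, 0.3)))
    }
  }

  for (i in seq_len(n)) {
    scen <- scenarios[i]
    s <- samples[i]
    known_first <- i %in% prior_idx
    t <- list(family = fams[i], sample = s, scenario = scen,
              gene = NA_character_, keys = character(0),
              cnv = NULL, expected_status = "unsolved",
              expected_model = NA_character_)
    if (scen == "hom") {
      g <- sample(ar_genes, 1L)
      k <- causal_allele(g, s, "1/1", known = known_first)
      t$gene <- g; t$keys <- k
      t$expected_status <- "solved"; t$expected_model <- "AR"
    } else if (scen == "compound_het") {
      g <- sample(ar_genes, 1L)
      k1 <- causal_allele(g, s, "0/1", known = known_first)
      k2 <- causal_allele(g, s, "0/1", known = FALSE)
      t$gene <- g; t$keys <- c(k1, k2)
      t$expected_status <- "solved"; t$expected_model <- "AR"
    } else if (scen == "het_cnv") {
      g <- sample(c("EYS", "USH2A", "CNGB1"), 1L)
      k <- causal_allele(g, s, "0/1", known = known_first,
                         class = sample(c("lof", "missense"), 1L))
      n_ex <- sum(panel$regions$gene == g &
                    panel$regions$region_class == "coding_exon_flanked")
      len <- sample.int(3L, 1L)
      from <- sample.int(n_ex - len + 1L, 1L)
      ev <- data.frame(sample = s, gene = g, exon_from = from,
                       exon_to = from + len - 1L, copy = 1L,
                       stringsAsFactors = FALSE)
      cnv_events[[length(cnv_events) + 1L]] <- ev
      t$gene <- g; t$keys <- k; t$cnv <- ev
      t$expected_status <- "solved"; t$expected_model <- "AR"
    } else if (scen == "xl_male") {
      g <- sample(xl_genes, 1L)
      k <- causal_allele(g, s, "1", known = known_first,
                         class = sample(c("lof", "missense"), 1L))
      t$gene <- g; t$keys <- k
      t$expected_status <- "solved"; t$expected_model <- "XL"
    } else if (scen == "ad_hotspot") {
      g <- "RP1"
      hs <- panel$genes[panel$genes$gene == g, ]
      codon <- sample(hs$hotspot_start:hs$hotspot_end, 1L)
      # the dominant rule fires on a truncating allele with a codon
      # inside the hotspot, so the consequence is pinned to frameshift
      k <- causal_allele(g, s, "0/1", known = known_first, class = "lof",
                         codon = codon, consequence = "frameshift")
      t$gene <- g; t$keys <- k
      t$expected_status <- "solved"; t$expected_model <- "AD"
    } else if (scen == "single_allele") {
      g <- sample(ar_genes, 1L)
      k <- causal_allele(g, s, "0/1", known = FALSE,
                         class = sample(c("missense", "splice"), 1L))
      t$gene <- g; t$keys <- k
      t$expected_status <- "partial"
    }
    if (known_first && length(t$keys)) prior_of[fams[i]] <- t$keys[1]
    background(s)
    truth_fam[[fams[i]]] <- t
  }

  # assemble site/annotation tables in insertion order
  keys <- names(sites)
  site_df <- do.call(rbind, lapply(keys, function(k) {
    data.frame(chrom = sites[[k]]$chrom, pos = sites[[k]]$pos,
               ref = sites[[k]]$ref, alt = sites[[k]]$alt,
               id = sites[[k]]$id %|NA|% NA_character_,
               stringsAsFactors = FALSE)
  }))
  ord <- order(site_df$chrom, site_df$pos)
  site_df <- site_df[ord, , drop = FALSE]
  keys <- keys[ord]
  ann_df <- do.call(rbind, lapply(keys, function(k) {
    as.data.frame(ann[[k]][c(ann_character_cols, ann_numeric_cols,
                             ann_logical_cols)], stringsAsFactors = FALSE)
  }))
  ann_df <- cbind(site_df[, c("chrom", "pos", "ref", "alt")], ann_df)

  gt <- matrix(NA_character_, nrow = length(keys), ncol = n,
               dimnames = list(keys, samples))
  gt[] <- "0/0"
  for (e in gt_entries) gt[e$key, e$sample] <- e$gt
  # haploid reference for male X outside carried sites stays 0/0; the
  # reader only inspects carrier genotypes

  families <- data.frame(
    family = fams, sample = samples, sex = sex, affected = TRUE,
    role = "index",
    prior_allele = unname(prior_of),
    inheritance = ifelse(scenarios == "xl_male", "sporadic", "arRP"),
    stringsAsFactors = FALSE
  )

  runs <- split(samples, ceiling(seq_along(samples) /
                                   config$samples_per_run))
  cnv_df <- if (length(cnv_events)) do.call(rbind, cnv_events) else NULL
  tf <- exp(stats::rnorm(nrow(panel$regions), 0, config$target_factor_sd))
  names(tf) <- panel$regions$label
  coverage <- lapply(runs, function(rs) {
    ev <- if (!is.null(cnv_df)) cnv_df[cnv_df$sample %in% rs, , drop = FALSE]
          else NULL
    simulate_run_matrix(panel, rs, ev, config, tf)
  })
  names(coverage) <- paste0("run", seq_along(coverage))

  truth <- list(
    families = truth_fam,
    cnv_events = cnv_df,
    scenarios = stats::setNames(scenarios, fams)
  )

  out <- list(sites = site_df, gt = gt, annotations = ann_df,
              families = families, coverage = coverage, truth = truth,
              panel = panel)
  if (!is.null(dir)) {
    write_cohort(out, dir)
    out$dir <- dir
  }
  out
}

# NB read-count coverage for one run with spiked events applied
simulate_run_matrix <- function(panel, run_samples, events, config, tf) {
  labels <- panel$regions$label
  sf <- exp(stats::rnorm(length(run_samples), 0, config$sample_factor_sd))
  copy <- matrix(2, nrow = length(labels), ncol = length(run_samples),
                 dimnames = list(labels, run_samples))
  if (!is.null(events) && nrow(events) > 0) {
    for (j in seq_len(nrow(events))) {
      ev <- events[j, ]
      lab <- paste0(ev$gene, "_ex", seq(ev$exon_from, ev$exon_to))
      copy[lab, ev$sample] <- ev$copy
    }
  }
  mu <- config$read_factor * config$depth_mean *
    outer(tf[labels], sf) * copy / 2
  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = config$nb_size),
                   nrow = nrow(mu), dimnames = dimnames(copy))
  depth <- matrix(as.integer(round(counts / config$read_factor)),
                  nrow = nrow(counts), dimnames = dimnames(copy))
  depth
}

#' Simulate one sequencing run's coverage matrix with spiked events
#'
#' Stand-alone wrapper around the cohort generator's coverage model, for
#' benchmarking the CNV caller: a flat panel-wide expected depth with
#' per-sample library factors and negative-binomial read-count noise,
#' and explicit copy-number events.
#'
#' @param panel An `rp_panel`.
#' @param n_samples Samples in the run (default 8).
#' @param events Data frame `sample` (index into `S01..`), `gene`,
#'   `exon_from`, `exon_to`, `copy`.
#' @param depth_mean Expected depth at copy 2 (default 300).
#' @param seed Integer seed.
#' @param config A `sim_config` supplying the noise parameters.
#' @return List with `matrix` (targets x samples integer depths) and
#'   `events`.
#' @export
simulate_coverage_run <- function(panel, n_samples = 8L, events = NULL,
                                  depth_mean = 300, seed = 1L,
                                  config = sim_config(
                                    depth_mean = depth_mean,
                                    target_factor_sd = 0)) {
  set.seed(seed)
  run_samples <- sprintf("S%02d", seq_len(n_samples))
  tf <- exp(stats::rnorm(nrow(panel$regions), 0, config$target_factor_sd))
  names(tf) <- panel$regions$label
  if (!is.null(events)) events$sample <- run_samples[events$sample]
  mat <- simulate_run_matrix(panel, run_samples, events, config, tf)
  list(matrix = mat, events = events)
}

write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_panel(cohort$panel, file.path(dir, "panel.bed"),
              file.path(dir, "genes.tsv"))
  write_vcf(cohort$sites, cohort$gt, file.path(dir, "cohort.vcf"),
            contigs = unique(cohort$sites$chrom))
  write_annotations(cohort$annotations, file.path(dir, "annotations.tsv"))
  fam <- cohort$families
  utils::write.table(fam, file.path(dir, "families.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  for (k in seq_along(cohort$coverage)) {
    write_coverage_matrix(cohort$coverage[[k]],
                          file.path(dir, sprintf("coverage_run%d.tsv", k)))
  }
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
  invisible(dir)
}

#' Generate the validation cohort of pre-known variants
#'
#' Builds the positive-control experiment: samples each carrying one
#' heterozygous variant known before panel sequencing — a mix of
#' pathogenic mutations (database-recorded, rare) and benign
#' polymorphisms (common) — embedded in the emitted VCF and annotation
#' table together with ordinary common background variants, so that a
#' correct pipeline redetects every one.
#'
#' @param spec List with `n`, `n_mutation`, `n_polymorphism`; the counts
#'   must satisfy `n == n_mutation + n_polymorphism` (default 24 = 17 +
#'   7).
#' @param seed Integer seed.
#' @param dir Optional output directory (`cohort.vcf`,
#'   `annotations.tsv`, `truth.json`).
#' @param panel An `rp_panel`.
#' @param config A `sim_config` (background and profile parameters).
#' @return List with `sites`, `gt`, `annotations`, `truth` (data frame
#'   `sample`, `key`, `class`).
#' @export
generate_validation_set <- function(spec = list(n = 24L, n_mutation = 17L,
                                                n_polymorphism = 7L),
                                    seed = 1L, dir = NULL,
                                    panel = build_panel(),
                                    config = sim_config(seed = seed)) {
  if (spec$n != spec$n_mutation + spec$n_polymorphism) {
    stop("validation spec mismatch: n must equal n_mutation + n_polymorphism",
         call. = FALSE)
  }
  set.seed(seed)
  genes <- panel$genes
  ar_genes <- genes$gene[genes$inheritance == "AR"]
  used <- new.env(parent = emptyenv())
  samples <- if (spec$n > 0) sprintf("VAL%03d", seq_len(spec$n))
             else character(0)
  classes <- c(rep("mutation", spec$n_mutation),
               rep("polymorphism", spec$n_polymorphism))

  sites <- list(); ann <- list(); gts <- list(); truth <- list()
  add <- function(site, gene, consequence, extra, sample, gt) {
    k <- site$key
    row <- empty_ann_row()
    row$gene <- gene; row$consequence <- consequence
    row[names(extra)] <- extra
    sites[[k]] <<- list(chrom = site$chrom, pos = site$pos, ref = site$ref,
                        alt = site$alt, id = extra$rs_id %||% NA_character_)
    ann[[k]] <<- row
    gts[[length(gts) + 1L]] <<- list(key = k, sample = sample, gt = gt)
  }
  for (i in seq_along(samples)) {
    g <- sample(ar_genes, 1L)
    if (classes[i] == "mutation") {
      csq <- sample(c("nonsense", "frameshift", "missense"), 1L)
      site <- new_site(panel, g, used, indel = csq == "frameshift")
      extra <- if (csq == "missense")
        draw_missense_profile(TRUE, config$predictor_confusion) else list()
      extra$protein <- fab_protein(csq)
      extra$spv_present <- FALSE
      extra <- c(extra, rare_maf(config$maf_absent_prob))
      extra$rs_id <- sprintf("rs%d", sample.int(9e6, 1L) + 1e7)
      extra$hgmd <- TRUE
      extra$lovd <- runif(1) < 0.5
    } else {
      csq <- sample(c("missense", "synonymous"), 1L)
      site <- new_site(panel, g, used)
      extra <- if (csq == "missense")
        draw_missense_profile(FALSE, config$predictor_confusion) else list()
      extra <- c(extra, common_maf())
      extra$rs_id <- sprintf("rs%d", sample.int(9e6, 1L))
    }
    add(site, g, csq, extra, samples[i], "0/1")
    truth[[i]] <- data.frame(sample = samples[i], key = site$key,
                             class = classes[i], stringsAsFactors = FALSE)
    # common background so redetection is not trivial
    for (b in seq_len(3)) {
      gb <- sample(ar_genes, 1L)
      sb <- new_site(panel, gb, used)
      eb <- common_maf()
      eb$rs_id <- sprintf("rs%d", sample.int(9e6, 1L))
      add(sb, gb, "synonymous", eb, samples[i], "0/1")
    }
  }
  keys <- names(sites)
  site_df <- do.call(rbind, lapply(keys, function(k) {
    data.frame(chrom = sites[[k]]$chrom, pos = sites[[k]]$pos,
               ref = sites[[k]]$ref, alt = sites[[k]]$alt,
               id = sites[[k]]$id %|NA|% NA_character_,
               stringsAsFactors = FALSE)
  }))
  if (is.null(site_df)) {
    site_df <- data.frame(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          id = character(), stringsAsFactors = FALSE)
  }
  ann_df <- if (length(keys)) cbind(
    site_df[, c("chrom", "pos", "ref", "alt")],
    do.call(rbind, lapply(keys, function(k) {
      as.data.frame(ann[[k]][c(ann_character_cols, ann_numeric_cols,
                               ann_logical_cols)],
                    stringsAsFactors = FALSE)
    }))) else NULL
  gt <- matrix("0/0", nrow = length(keys), ncol = length(samples),
               dimnames = list(keys, samples))
  for (e in gts) gt[e$key, e$sample] <- e$gt
  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame(sample = character(), key = character(),
               class = character(), stringsAsFactors = FALSE)
  out <- list(sites = site_df, gt = gt, annotations = ann_df,
              truth = truth_df)
  if (!is.null(dir) && length(keys)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_vcf(site_df, gt, file.path(dir, "cohort.vcf"),
              contigs = unique(site_df$chrom))
    write_annotations(ann_df, file.path(dir, "annotations.tsv"))
    utils::write.table(truth_df, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    out$dir <- dir
  }
  out
}

#' Run the full interpretation pipeline on an emitted cohort directory
#'
#' Reads back everything [generate_cohort()] wrote (or equivalently
#' formatted real data): panel, VCF + annotations, families and per-run
#' coverage matrices; runs the prioritization cascade; derives the CNV
#' candidate table (samples with exactly one pathogenic heterozygous
#' small variant in a gene) and calls copy-number events in restricted
#' mode; resolves every family and applies the reclassification rules.
#'
#' @param dir Cohort directory.
#' @param config Pipeline configuration.
#' @return List with `report` (cascade), `cnv_calls`, `resolutions`
#'   (named by family) and `summary`.
#' @export
analyze_cohort <- function(dir, config = default_config()) {
  panel <- read_panel(file.path(dir, "panel.bed"),
                      file.path(dir, "genes.tsv"), config)
  variants <- read_variants(file.path(dir, "cohort.vcf"),
                            file.path(dir, "annotations.tsv"))
  families <- utils::read.delim(file.path(dir, "families.tsv"),
                                stringsAsFactors = FALSE,
                                na.strings = c("NA", ""))
  report <- run_cascade(variants, panel, config)

  cand <- candidate_calls(report)
  het <- cand[cand$zygosity == "het", , drop = FALSE]
  tab <- table(het$sample, het$gene)
  idx <- which(tab == 1, arr.ind = TRUE)
  case_table <- data.frame(sample = rownames(tab)[idx[, 1]],
                           gene = colnames(tab)[idx[, 2]],
                           stringsAsFactors = FALSE)

  cov_files <- sort(list.files(dir, pattern = "^coverage_run[0-9]+\\.tsv$",
                               full.names = TRUE))
  cnv_calls <- do.call(rbind, lapply(cov_files, function(f) {
    mat <- read_coverage_matrix(f)
    detect_cnvs(mat, panel, config = config, case_table = case_table)
  }))
  if (!is.null(cnv_calls)) class(cnv_calls) <- c("cnv_calls", "data.frame")

  resolutions <- lapply(seq_len(nrow(families)), function(i) {
    case <- family_case(families$family[i], families$sample[i],
                        sex = families$sex[i],
                        prior_allele = families$prior_allele[i] %||% NA)
    res <- resolve_family(case, report$variants, cnv_calls, panel$genes,
                          config)
    apply_reclassification(res)
  })
  names(resolutions) <- families$family
  list(report = report, cnv_calls = cnv_calls, resolutions = resolutions,
       summary = cohort_summary(resolutions, nrow(families)))
}

#' Score pipeline outputs against generator truth
#'
#' Two complementary modes, selected by the truth object:
#'
#' * variant redetection (`truth` is the data frame emitted by
#'   [generate_validation_set()]): sensitivity is the percent of spiked
#'   (sample, variant) pairs present in the classified cascade output;
#' * cohort resolution (`truth` is the `truth` element of
#'   [generate_cohort()]): sensitivity is the percent of families with a
#'   causal truth configuration resolved `solved` in the truth gene;
#'   specificity is the percent of truth-`none` families not called
#'   solved; a per-scenario confusion table is attached.
#'
#' @param outputs A `cascade_report` (variant mode) or the named
#'   resolution list / [analyze_cohort()] result (cohort mode).
#' @param truth Matching truth object.
#' @return List with `sensitivity`, `specificity` (cohort mode) and
#'   `detail`/`confusion`.
#' @export
score_against_truth <- function(outputs, truth) {
  if (is.data.frame(truth) && all(c("sample", "key") %in% names(truth))) {
    if (!inherits(outputs, "cascade_report")) {
      stop("variant-mode scoring needs a cascade_report", call. = FALSE)
    }
    v <- outputs$variants
    seen <- paste(v$sample, v$key)
    detected <- paste(truth$sample, truth$key) %in% seen
    return(list(
      sensitivity = if (nrow(truth)) 100 * mean(detected) else NA_real_,
      detail = cbind(truth, detected = detected)
    ))
  }
  if (!is.null(outputs$resolutions)) outputs <- outputs$resolutions
  fams <- names(truth$families)
  missing <- setdiff(fams, names(outputs))
  if (length(missing)) {
    stop("resolutions missing for famil(ies): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  status <- vapply(outputs[fams], function(r) r$status, "")
  scen <- vapply(truth$families, function(t) t$scenario, "")
  causal <- vapply(truth$families, function(t)
    identical(t$expected_status, "solved"), TRUE)
  hit <- vapply(fams, function(f) {
    t <- truth$families[[f]]
    r <- outputs[[f]]
    identical(r$status, "solved") && t$gene %in% r$gene
  }, TRUE)
  none <- scen == "none"
  list(
    sensitivity = if (any(causal)) 100 * mean(hit[causal]) else NA_real_,
    specificity = if (any(none)) 100 * mean(status[none] != "solved")
                  else NA_real_,
    confusion = table(scenario = scen, status = status)
  )
}

#' Simulate per-base depth tracks for coverage QC
#'
#' Emulates the per-base coding coverage of a gene panel: most genes are
#' uniformly well covered; a configurable fraction of genes carries a
#' poorly performing segment (GC-rich or repetitive in real panels)
#' whose bases fall below the QC threshold in every sample.
#'
#' @param n_genes,bases_per_gene,n_samples Problem size.
#' @param frac_fully_covered Fraction of genes with every base at or
#'   above the threshold (the generator truth).
#' @param depth_mean Mean depth of well-covered bases.
#' @param threshold QC depth threshold the holes undershoot.
#' @param hole_frac Fraction of a poor gene's bases inside the hole.
#' @param seed Integer seed.
#' @return List with `depth_table` (long `gene`, `pos`, `sample`,
#'   `depth`) and `truth` (`fully_covered_genes`, `frac_fully_covered`).
#' @export
simulate_depth_tracks <- function(n_genes = 75L, bases_per_gene = 120L,
                                  n_samples = 8L,
                                  frac_fully_covered = 0.735,
                                  depth_mean = 300, threshold = 10,
                                  hole_frac = 0.1, seed = 1L) {
  set.seed(seed)
  genes <- sprintf("G%03d", seq_len(n_genes))
  n_full <- round(frac_fully_covered * n_genes)
  full <- sort(sample(genes, n_full))
  hole_len <- max(1L, round(hole_frac * bases_per_gene))
  rows <- lapply(genes, function(g) {
    hole <- if (!g %in% full) seq_len(hole_len) +
      sample.int(bases_per_gene - hole_len, 1L) else integer(0)
    do.call(rbind, lapply(seq_len(n_samples), function(s) {
      depth <- stats::rnbinom(bases_per_gene, mu = depth_mean, size = 50)
      depth[hole] <- sample.int(threshold, length(hole),
                                replace = TRUE) - 1L
      data.frame(gene = g, pos = seq_len(bases_per_gene),
                 sample = sprintf("S%02d", s), depth = depth,
                 stringsAsFactors = FALSE)
    }))
  })
  list(depth_table = do.call(rbind, rows),
       truth = list(fully_covered_genes = full,
                    frac_fully_covered = n_full / n_genes))
}
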