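#' Gene catalogue of the default retinal dystrophy panel
#'
#' Seventy-five genes implicated in retinal degeneration, each tagged with
#' the inheritance models under which it can explain disease: `AR`
#' (autosomal recessive), `AD` (autosomal dominant), `XL` (X-linked), or
#' combinations such as `"AR/AD"`. RP1 additionally carries a dominant
#' hotspot codon interval: a single truncating allele inside that domain is
#' interpreted as autosomal dominant disease even in a recessive cohort.
#'
#' @param config Configuration list; supplies the RP1 hotspot interval.
#' @return A data frame with columns `gene`, `inheritance`,
#'   `hotspot_start`, `hotspot_end`.
#' @export
default_gene_table <- function(config = default_config()) {
  ar <- c(
    "ABCA4", "ARL2BP", "ARL6", "BBS1", "BBS2", "C2orf71", "C8orf37", "CA4",
    "CEP290", "CERKL", "CLRN1", "CNGA1", "CNGB1", "CRB1", "DHDDS", "DHX38",
    "EMC1", "EYS", "FAM161A", "GPR125", "GUCY2D", "IDH3B", "IFT140",
    "IMPG2", "KIAA1549", "KIZ", "LCA5", "LRAT", "MAK", "MERTK", "MFRP",
    "MVK", "NMNAT1", "NR2E3", "NRL", "PDE6A", "PDE6B", "PDE6G", "POMGNT1",
    "PRCD", "PROM1", "RBP3", "RDH12", "RGR", "RLBP1", "RPE65", "RPGRIP1",
    "SAG", "SLC7A14", "SPATA7", "TTC8", "TULP1", "USH2A", "ZNF513"
  )
  ad <- c(
    "BEST1", "CRX", "FSCN2", "GUCA1B", "IMPDH1", "KLHL7", "PRPF3", "PRPF31",
    "PRPF6", "PRPF8", "PRPH2", "RHO", "ROM1", "RP9", "SEMA4A", "SNRNP200",
    "TOPORS"
  )
  xl <- c("OFD1", "RP2", "RPGR")
  mixed <- "RP1" # recessive gene with a dominant truncation hotspot
  genes <- data.frame(
    gene = c(ar, ad, xl, mixed),
    inheritance = c(
      rep("AR", length(ar)), rep("AD", length(ad)), rep("XL", length(xl)),
      "AR/AD"
    ),
    hotspot_start = NA_integer_,
    hotspot_end = NA_integer_,
    stringsAsFactors = FALSE
  )
  hs <- config$rp1_hotspot
  genes$hotspot_start[genes$gene == "RP1"] <- hs[1]
  genes$hotspot_end[genes$gene == "RP1"] <- hs[2]
  genes <- genes[order(genes$gene), , drop = FALSE]
  rownames(genes) <- NULL
  genes
}

# exon counts per gene summing to n_regions - 4 whitelist positions;
# large genes get realistic counts, the remainder is spread evenly.
panel_exon_counts <- function(genes, n_regions) {
  big <- c(USH2A = 72L, EYS = 43L, ABCA4 = 50L, CEP290 = 54L, CRB1 = 12L,
           CNGB1 = 33L, RP1 = 4L, RPGR = 19L, GUCY2D = 20L, PRPF8 = 43L)
  counts <- stats::setNames(rep(NA_integer_, nrow(genes)), genes$gene)
  big <- big[names(big) %in% names(counts)]
  counts[names(big)] <- big
  n_coding <- n_regions - 4L # four deep-intronic whitelist targets
  rest <- names(counts)[is.na(counts)]
  per <- (n_coding - sum(big)) %/% length(rest)
  extra <- (n_coding - sum(big)) %% length(rest)
  counts[rest] <- per
  if (extra > 0) counts[rest[seq_len(extra)]] <- per + 1L
  stopifnot(sum(counts) == n_coding, all(counts >= 1))
  counts
}

#' Build the synthetic reference panel
#'
#' Constructs a structurally realistic capture panel on a toy genome: for
#' each of the 75 catalogue genes a run of coding exons (150 bp cores spaced
#' 1 kb apart) captured together with `flank_bp` intronic bases on each
#' side, plus four deep-intronic whitelist targets in CEP290, OFD1, PRPF31
#' and USH2A. The default size is 1127 target regions. Region labels follow
#' the `GENE_ex<N>` convention (`GENE_di<N>` for whitelist positions);
#' coordinates are stored 0-based half-open as in BED.
#'
#' @param n_regions Total number of target regions.
#' @param genes Gene catalogue as from [default_gene_table()].
#' @param config Configuration list (flank width).
#' @return An object of class `rp_panel`: a list with elements `regions`
#'   (data frame `chrom`, `start`, `end`, `gene`, `label`, `region_class`),
#'   `genes`, and `flank_bp`.
#' @export
build_panel <- function(n_regions = 1127L, genes = default_gene_table(),
                        config = default_config()) {
  flank <- config$flank_bp
  counts <- panel_exon_counts(genes, n_regions)
  xl_genes <- genes$gene[genes$inheritance == "XL"]
  regions <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes$gene[i]
    chrom <- if (g %in% xl_genes) "chrX" else paste0("chr", 1L + (i - 1L) %% 22L)
    gstart <- 1e6 + (i - 1L) * 1e5 # 1-based start of first exon core; the
    # per-index offset keeps genes disjoint even where several share a
    # chromosome (all XL genes sit on chrX)
    j <- seq_len(counts[g])
    core_start <- gstart + (j - 1L) * 1150
    regions[[i]] <- data.frame(
      chrom = chrom,
      start = as.integer(core_start - flank - 1L), # 0-based
      end = as.integer(core_start + 149L + flank),
      gene = g,
      label = paste0(g, "_ex", j),
      region_class = "coding_exon_flanked",
      stringsAsFactors = FALSE
    )
  }
  regions <- do.call(rbind, regions)
  # deep-intronic whitelist: one position per named gene, 21 bp target
  wl <- c("CEP290", "OFD1", "PRPF31", "USH2A")
  for (g in wl) {
    ex2 <- regions[regions$gene == g & regions$label == paste0(g, "_ex2"), ]
    pos <- ex2$end + flank + 500L # 1-based, mid-intron, beyond any flank
    regions <- rbind(regions, data.frame(
      chrom = ex2$chrom, start = pos - 11L, end = pos + 10L, gene = g,
      label = paste0(g, "_di1"), region_class = "deep_intronic_whitelist",
      stringsAsFactors = FALSE
    ))
  }
  regions <- regions[order(regions$chrom, regions$start), , drop = FALSE]
  rownames(regions) <- NULL
  new_panel(regions, genes, flank)
}

new_panel <- function(regions, genes, flank_bp) {
  stopifnot(all(regions$start < regions$end), !anyDuplicated(regions$label),
            all(regions$gene %in% genes$gene))
  structure(list(regions = regions, genes = genes, flank_bp = flank_bp),
            class = "rp_panel")
}

#' @export
print.rp_panel <- function(x, ...) {
  cat(sprintf(
    "rp_panel: %d target regions over %d genes, %s bp total span\n",
    nrow(x$regions), length(unique(x$regions$gene)),
    format(sum(x$regions$end - x$regions$start), big.mark = ",")
  ))
  cat(sprintf("  %d deep-intronic whitelist position(s), flank %d bp\n",
              sum(x$regions$region_class == "deep_intronic_whitelist"),
              x$flank_bp))
  invisible(x)
}

#' Deep-intronic whitelist positions of a panel
#'
#' @param panel An `rp_panel`.
#' @return Data frame with `gene`, `chrom`, `pos` (1-based centre of each
#'   whitelist target).
#' @export
panel_whitelist <- function(panel) {
  wl <- panel$regions[panel$regions$region_class == "deep_intronic_whitelist", ]
  data.frame(gene = wl$gene, chrom = wl$chrom,
             pos = as.integer(wl$start + 11L), stringsAsFactors = FALSE)
}

#' Read a capture panel from BED + gene table
#'
#' The BED file is consumed as 0-based half-open with at least four columns
#' (`chrom`, `start`, `end`, `name`); the name column carries the target
#' label in the `GENE_ex<N>` / `GENE_di<N>` convention from which the gene
#' symbol and region class are derived. The gene table is a TSV with
#' columns `gene`, `inheritance` and optional `hotspot_start`,
#' `hotspot_end`.
#'
#' @param bed_path Path to the target BED file.
#' @param gene_table_path Path to the gene table TSV.
#' @param config Configuration list.
#' @return An `rp_panel`; printing it reports the region count and span.
#' @export
read_panel <- function(bed_path, gene_table_path, config = default_config()) {
  lines <- readLines(bed_path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4)) {
    stop(sprintf("malformed BED line %d: fewer than 4 fields",
                 which(nf < 4)[1]), call. = FALSE)
  }
  start <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  if (anyNA(start) || anyNA(end)) {
    stop(sprintf("malformed BED line %d: non-integer coordinates",
                 which(is.na(start) | is.na(end))[1]), call. = FALSE)
  }
  bad <- which(start >= end)
  if (length(bad)) {
    stop(sprintf("malformed BED line %d: start >= end", bad[1]),
         call. = FALSE)
  }
  label <- vapply(fields, `[`, "", 4L)
  if (anyDuplicated(label)) {
    stop("duplicate target label: ", label[duplicated(label)][1],
         call. = FALSE)
  }
  regions <- data.frame(
    chrom = vapply(fields, `[`, "", 1L),
    start = start, end = end,
    gene = sub("_[^_]+$", "", label),
    label = label,
    region_class = ifelse(grepl("_di[0-9]+$", label),
                          "deep_intronic_whitelist", "coding_exon_flanked"),
    stringsAsFactors = FALSE
  )
  genes <- utils::read.delim(gene_table_path, stringsAsFactors = FALSE)
  if (!all(c("gene", "inheritance") %in% names(genes))) {
    stop("gene table must have columns 'gene' and 'inheritance'",
         call. = FALSE)
  }
  unknown <- setdiff(regions$gene, genes$gene)
  if (length(unknown)) {
    stop("BED gene(s) absent from gene table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  regions <- regions[order(regions$chrom, regions$start), , drop = FALSE]
  rownames(regions) <- NULL
  new_panel(regions, genes, config$flank_bp)
}

#' Write a panel to BED + gene table files
#'
#' Inverse of [read_panel()]; a write-then-read round trip reproduces the
#' panel exactly.
#'
#' @param panel An `rp_panel`.
#' @param bed_path,gene_table_path Output paths.
#' @return Invisibly, the panel.
#' @export
write_panel <- function(panel, bed_path, gene_table_path) {
  r <- panel$regions
  bed <- data.frame(r$chrom, r$start, r$end, r$label, 0L, "+",
                    stringsAsFactors = FALSE)
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(panel$genes, gene_table_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(panel)
}

# map a 1-based position to the panel region containing it (NA if none)
region_index_of <- function(panel, chrom, pos) {
  r <- panel$regions
  gr <- GenomicRanges::GRanges(r$chrom, IRanges::IRanges(r$start + 1L, r$end))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  hit <- GenomicRanges::findOverlaps(q, gr, select = "first")
  as.integer(hit)
}
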