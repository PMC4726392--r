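---
title: "Variant interpretation for a targeted retinal dystrophy panel: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variant interpretation for a targeted retinal dystrophy panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelrp)
```

## The diagnostic problem

Autosomal recessive retinitis pigmentosa (arRP) is genetically
heterogeneous: tens of genes, compound heterozygosity, phenocopies and
genes that also cause dominant, X-linked or syndromic disease. A
targeted capture panel over the known retinal dystrophy (RD) genes
turns the diagnostic question into a computational one: given a
sample's called variants with their annotations, its per-target
coverage relative to run-mates, and what is already known about the
family, which families can be declared molecularly solved, by which
alleles, and under which inheritance model?

`panelrp` implements that interpretation layer. It deliberately starts
*after* alignment and small-variant calling (a VCF plus a site-level
annotation table are its inputs) and stops *before* wet-lab
confirmation: Sanger validation, MLPA and array CGH are outside its
scope, as is recomputing predictor scores — SIFT, PolyPhen-2,
Align-GVGD, MutationTaster and the splice-site tools are consumed as
annotations, the way a diagnostic lab receives them.

## The data model

A `Panel` is the captured territory: each coding exon with a 20 bp
intronic flank on either side (splice donors and acceptors live in
those flanks), plus a small whitelist of deep-intronic positions with
known pathogenic mutations in CEP290, OFD1, PRPF31 and USH2A —
positions that standard exome logic would discard. The default
synthetic panel has 1127 target regions over 75 genes, matching the
scale of the design it emulates; coordinates live on a toy genome
because no real reference is required for any computation the package
performs. BED input is consumed as 0-based half-open, variant
positions as 1-based; a variant on the first base of a target is
inside it.

Each gene carries inheritance capability tags (`AR`, `AD`, `XL`, or
combinations). RP1 additionally has a dominant hotspot: a codon
interval in which a single truncating allele behaves dominantly. The
interval (default codons 500–1053) is package configuration — the
clinical literature locates the domain but prints no canonical
boundaries, so the default is documented configuration rather than an
established constant, and can be overridden per gene table.

## The prioritization cascade

Variants pass six stages in a fixed order; the first stage that can
classify a variant does so and later stages are skipped:

1. **Region**: keep variants in the captured coding space (flanked
   exons plus whitelist). UTR, intergenic and off-whitelist
   deep-intronic variants are labelled `out_of_region`.
2. **Frequency**: keep a variant when its maximum minor allele
   frequency over 1000 Genomes, EVS and ExAC is ≤ 0.005 *or when no
   database reports it at all*. A missing frequency is absence of
   evidence and is never coerced to zero; this matters because truly
   novel pathogenic alleles are exactly the ones without records.
3. **Known mutations**: an rs identifier together with membership in a
   curated disease-mutation database (HGMD or LOVD) makes a variant
   `known_pathogenic` outright. Variants without an rs number are
   tagged novel. The source protocol's wording can be read as
   requiring both databases; the package defaults to either sufficing
   (the worked examples only ever show one) and offers
   `require_both_dbs` for the literal reading.
4. **Consequence**: nonsense, frameshift and canonical splice-site
   variants (intronic positions ±1/±2) are loss-of-function,
   `lof_pathogenic`, regardless of any predictor. More distal intronic
   changes are *non-canonical* splice variants and take the consensus
   route — the distinction mirrors the protocol's separation of the
   two classes.
5. **Population controls**: novel missense and non-canonical splice
   variants observed in a population-matched control exome set (267
   individuals) are `benign_population`. The default policy excludes
   on any observation, because the protocol forwards only variants
   *not present* in the controls; a frequency-threshold policy is
   available because population-specific benign variants are described
   by their high control frequency.
6. **In-silico consensus**: the remaining candidates are flagged
   `potentially_pathogenic` when at least two independent predictors
   call them damaging.

Anything never classified ends `uncertain`. The candidate set is
`known_pathogenic ∪ lof_pathogenic ∪ potentially_pathogenic`.

### What counts as a damaging vote

The protocol names the tools but not each tool's damaging definition,
so the mapping is a design decision, fixed as configuration:

* SIFT — call `D` (score < 0.05 when only a score is present);
* PolyPhen-2 — `Pos.D` or `Pr.D`;
* Align-GVGD — class C35 or higher. C15 is described as "less likely
  pathogenic" in the source material's own footnotes, so C0–C25 do not
  vote;
* MutationTaster — call `D`.

For splice predictors (HSF, BDGP, AST, NetGene2), a tool votes when it
reports the wild-type site lost, when it reports a **new cryptic
site**, or when the mutant score drops by ≥ 10% of the wild-type score
(`splice_drop_fraction`; the protocol prints wild-type/mutant score
pairs but no cutoff, and 10% is the conventional screening threshold
for these tools). ESEfinder votes on loss of an enhancer motif.
Counting cryptic-site creation as a vote is required for a
non-canonical CNGB1 intron-6 change — reported only as a new cryptic
acceptor by three tools plus an SRp40 loss — to be carried forward as
a pathogenic allele, which the reference cohort does.

One consequence is worth stating plainly: a reported causative USH2A
missense (p.Lys1821Arg) receives zero damaging votes under any
reasonable mapping (T / B / C25 / P). The cascade keeps consensus and
segregation as separate evidence streams rather than inventing an
override rule; that allele enters the package's curated cohort table
as adjudicated truth, not as a consensus product.

## The coverage-ratio CNV caller

Exon-level deletions and duplications are detected from the
targets × samples depth matrix of one sequencing run:

1. each sample's column is divided by its own **median** target depth
   (median, not mean, so the normalization is robust to the very
   events being sought);
2. the test sample's normalized coverage at each target is divided by
   the **median** of its run-mates' normalized coverage, giving a
   ratio near 1 at diploid targets, near 0.5 for a heterozygous
   deletion and near 1.5 for a heterozygous duplication;
3. strict thresholds call per-target states: deletion below 0.7,
   duplication above 1.2 (exactly 0.7 or 1.2 is no call);
4. targets whose run-mate median *raw* depth is below 100× are masked
   ineligible — the motive is false-positive avoidance, so the mask is
   a property of the reference panel, shared by every test sample;
5. same-type calls on targets adjacent in the gene's exon order merge
   into one event with its span and mean ratio; there is no gap
   tolerance.

Fewer than three run-mates triggers a warning: the run-mate median is
then barely robust. The reference workflow pooled eight samples per
run and stated no minimum, so three is a package convention.

In the diagnostic protocol the caller runs **restricted**: only
(sample, gene) pairs where the sample already carries exactly one
pathogenic heterozygous small variant are analyzed, because the CNV is
being sought as the second allele. Unrestricted mode exists for
survey use; restriction only removes calls, never adds them, so a
family solved in restricted mode stays solved without it.

Duplications deserve one caveat: duplication calls are reported
but are **not** counted as pathogenic alleles during case resolution.
The reference cohort's only duplication calls could not be confirmed
orthogonally, and a tandem duplication's pathogenicity is not
interpretable from a ratio alone.

## Coverage QC

Per-base depth tables yield, per gene and sample, the percent of
coding bases covered by at least 10 reads (inclusive), per-sample
means, and per-gene quartiles across samples — the numbers behind the
standard per-gene coverage boxplot. Outliers use the 1.5 × IQR fence
rule. Quartiles are computed by linear interpolation between order
statistics (R's type-7 default); the fence rule needs *some* fixed
convention and none is canonical in the source material. The
summaries also report the fraction of genes with every base covered,
per sample and pooled (pooled = fully covered in every sample).

## Case resolution

Per family, the index sample's candidate alleles (small variants plus
deletion events) are tested against each gene's inheritance models:

* **AR** — homozygous pathogenic, or two distinct heterozygous
  pathogenic alleles (small variants and/or an exon deletion). Without
  parental genotypes the trans configuration is assumed and
  segregation is reported `not_available` — reference cohorts resolve
  several families exactly this way;
* **XL** — a hemizygous pathogenic allele in an X-linked gene in a
  male index;
* **AD** — a single truncating allele inside a configured dominant
  hotspot (RP1 by default).

Exactly one pathogenic allele in one recessive gene gives `partial`;
single alleles in two or more genes give `uncertain_two_genes`
(digenic inference is deliberately not attempted); nothing pathogenic
gives `unsolved`. A homozygous call plus a distinct allele in the same
gene is contradictory and raises a review flag instead of being
silently interpreted. Should two genes each reach a full configuration
— never observed in the reference cohort — both are reported with a
warning rather than forcing a choice.

The declared inheritance of a family (arRP or sporadic) is advisory:
X-linked and dominant resolutions may override it, which is precisely
how such cohorts get genetically reclassified. Reclassification rules
are data, evaluated in order: solved-in-USH2A flags audiological
follow-up (the gene causes both non-syndromic RP and Usher syndrome),
solved-in-ABCA4 flags cone-rod dystrophy review, and the XL and
AD-hotspot routes flag inheritance reassignment. Segregation checking
treats an unaffected carrier of a dominant allele as consistent only
for genes configured penetrance-exempt (RP1 by default, where
incomplete penetrance is documented).

When a family arrives with a prior known allele (from a genotyping
microarray), `second_allele_search()` follows the two-phase protocol:
look for a second pathogenic allele in the prior gene first, and only
if that fails widen to the whole candidate set — which is how a family
with a recurrent USH2A allele can end up diagnosed in RP1.

## The synthetic cohort generator

The generator is first-class, tested code: it emits a full cohort —
multi-sample VCF, annotation TSV, per-run coverage matrices, family
table and truth — in exactly the dialects the readers consume, so the
entire pipeline can be exercised with no external data.

**What it emulates.** A 47-family cohort sequenced in 8-sample runs
with the reference composition: 6 homozygous, 16 compound-
heterozygous, 3 small-variant + exon-deletion, 4 single-allele, 1
X-linked male and 1 dominant-hotspot family, and 16 families with no
causal configuration; about half of the solved families carry a prior
microarray-known first allele. Causal alleles split roughly 50/35/15
between loss-of-function, missense and non-canonical splice classes.
Background variants per sample comprise rare benign-profile and
common polymorphic variants; rare backgrounds are placed in autosomal
recessive genes, so a truth-`none` family cannot be spuriously solved
through the XL or AD routes, which fire on single alleles.

**Predictor profiles** are drawn class-conditionally: a causal
missense allele keeps at least two damaging calls and a benign one at
most one, with the remaining predictors flipped independently at a
10% confusion probability. Votes therefore vary (2–4 against 0–1) and
the two-vote consensus, not any single predictor, separates the
classes — but the class outcome is well-defined, which is what makes
"the pipeline recovers every truth resolution" a meaningful test
rather than a coin flip.

**Coverage noise.** Negative-binomial variation is placed on
per-target *read counts* (about two reads per unit depth for 150 bp
reads on exon-sized targets; NB size 20 000, i.e. mild
overdispersion above Poisson counting noise), and the emitted integer
depth is derived from the count. Systematic capture-efficiency
differences between targets are a separate lognormal per-target
factor, and library size a lognormal per-sample factor — the
normalization steps exist precisely to remove these. The resulting
depth coefficient of variation at 300× is ≈ 4–5%, which is what
per-target *mean* depth shows in practice, because a target's mean
depth averages over many read placements. At that operating point a
heterozygous deletion at 300× sits > 4σ below the 0.7 threshold and a
copy-3 duplication > 4σ above 1.2.

A floor worth documenting: with integer depths at 300×, the
duplication threshold of 1.2 lies only ~4.5σ from a diploid target's
ratio even at pure Poisson noise, so across tens of thousands of null
target-evaluations an occasional just-above-threshold false
duplication call is expected from counting statistics alone, whatever
the dispersion parameter. The caller's benchmark therefore asserts
exact recovery of every spiked event plus a bound of at most one
stray call per run, rather than pretending a zero-false-positive
regime exists.

**What it does not emulate** — and hence what passing tests do not
show about real data: alignment and capture artifacts (GC bias,
pseudogene cross-mapping, the notorious RPGR ORF15 dropout),
correlated noise between adjacent targets, population linkage
structure and realistic site-frequency spectra, mosaicism, and
annotation disagreement between transcript sets. Real-data
performance additionally depends on the upstream caller and
annotator, which are out of scope.

## Problem sizes and determinism

Every simulation is seeded and byte-reproducible; equal seeds give
identical output files. The shipped tests run the full 1127-target
panel end to end: a 47-family cohort for the specificity check, a
24-sample validation set (17 embedded mutations, 7 polymorphisms) for
the redetection check, and 50 seeded replicates of an 8-sample run
carrying three heterozygous deletions (2, 1 and 5 exons) and two
duplications (2 exons each) at 300× for the CNV benchmark — sizes
chosen to match the emulated study's own scale while keeping the
whole suite in the tens of seconds. Published per-family outcomes are
checked against the curated allele table shipped in
`inst/extdata/arrp_cohort_alleles.tsv` (27 solved families of a
47-family cohort; 13 solved via a prior microarray allele).

## Known limitations

* Consequence assignment is an input, not a computation; the package
  trusts its annotation table.
* Multi-allelic VCF records must be split upstream.
* Homozygous-deletion genotyping, breakpoint resolution and
  duplication interpretation are out of scope.
* The cohort-level tallies printed in the reference material (novel
  mutation counts, per-class fractions) do not reconcile exactly with
  an independent recount of its own per-family table; the package
  reports raw recounts and makes no attempt to force agreement.
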