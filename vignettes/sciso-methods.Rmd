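---
title: "Isoform statistics for long-read single-cell RNA-seq: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isoform statistics for long-read single-cell RNA-seq: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sciso)
```

`sciso` analyzes isoform-resolved single-cell expression from long-read
platforms, contrasting cancer cells against a normal epithelial
baseline. This vignette documents the models, the parameters that
matter, the synthetic-data generator that backs the test suite, and the
design decisions taken where the methodology was genuinely open.

## Normalization and shared substrate

Counts are scaled to reads per million mapped full-length reads per
feature (called TPM throughout; long-read counting is transcript-level,
so no length correction applies) and log-transformed as
`log(TPM/10 + 1)` with the natural logarithm. The `/10` compresses the
dynamic range of deeply sequenced single cells before the log; the
natural log matches the convention of the surrounding single-cell
toolchain.

Cell QC drops cells with fewer than 500 detected genes (count ≥ 1
defines "detected") or a mitochondrial count fraction strictly above
60%; isoforms are kept only when expressed in at least 3 cells in each
of at least 3 individuals. Fold changes in `wilcoxon_de()` are computed
on mean TPM with a pseudocount of 1 TPM on both means — symmetric and
finite at zero — and significance requires BH-adjusted p < 0.05 plus
fold change ≥ 2 (or ≤ 0.5). Highly variable genes are ranked per
technology batch by binned standardized dispersion (20 equal-frequency
mean-expression bins) and the per-batch top lists are unioned, so a
gene variable in either technology is retained.

## UTR deviation

The expressed UTR length of gene $g$ in cell $c$ is the
expression-weighted mean of its isoforms' UTR lengths,

$$\mathrm{EUL}_{g,c} = \frac{\sum_i M_{g,i}\, C_{i,c}\, l_i}
                            {\sum_i M_{g,i}\, C_{i,c}},$$

with TPM as the weight $C_{i,c}$ so that sequencing depth cancels and
the statistic is invariant to library-size scaling. EUL is undefined in
cells where no UTR-bearing isoform of the gene is expressed; non-coding
isoforms (no CDS, hence no defined UTR) are excluded from both sums.
Gene UTR deviation subtracts the gene's mean EUL over the normal cell
baseline, so normal cells center at zero by construction.

Classification of shortened/lengthened genes fits, per gene,
`GUD ~ cell_type` with a technology-batch term: a random intercept
(via lmerTest) when three or more batches are present, a fixed
covariate otherwise — a random intercept on two levels is
under-identified and routinely singular. A gene is called only when the
cell-type coefficient sign, its p-value (< 0.05), and the signed mean
GUD difference (≤ −10 bp for shortening, ≥ +10 bp for lengthening) all
agree; the ±10 bp magnitude rule keeps statistically significant but
biologically negligible shifts out. Genes with fewer than 10
deviation-bearing cells per type are reported `unchanged` with a note,
as are singular fits.

## Local splicing events and PSI

Events are enumerated from transcript structure per gene: skipped exon
(SE), retained intron (RI), alternative 5'/3' splice site (A5/A3,
strand-aware), alternative first/last exon (AF/AL) and mutually
exclusive exons (MX, which additionally require that no isoform of the
gene carries both exons). Event ids are built from the 1-based exon
boundary coordinates flanking the variable region
(`SE:chrom:upstreamEnd-skippedStart:skippedEnd-downstreamStart:strand`),
which makes them order-independent; inclusion/exclusion membership is
recomputed over all isoforms of the gene, so the output does not depend
on transcript input order. Inclusion-form conventions are fixed and
deterministic: the exon-containing form (SE), the intron-retaining form
(RI), the longer-exon form (A5/A3), the distal terminal exon (AF/AL)
and the genomic-left exon (MX).

PSI of an event in a cell is the inclusion share of the event's total
isoform TPM, missing when that total is below 1 TPM (too little signal
to estimate a ratio). Differential splicing tests per-cell PSI with a
two-sided rank-sum test — distribution-free and honest at single-cell
granularity — and gates on raw p < 0.05 together with |ΔPSI| ≥ 0.1;
a BH-adjusted column is reported alongside but does not enter the gate,
matching the event-filter convention. At least 10 defined-PSI cells per
group are required. Splicing-factor analysis correlates event PSI with
factor expression (Pearson, defined-PSI cells only), clusters events on
their correlation profiles (Euclidean distance, average linkage) and
tests each cluster for retained-intron enrichment with Fisher's exact
test. Overlap between two differential-splicing signatures uses a 5%
PSI-difference gate without a significance requirement and an
upper-tail hypergeometric test on the qualifying-set intersection; a
rescue mode requires opposite signs, for perturbations expected to
revert an in vivo change.

## Differential transcript and CDS usage

Usage changes are tested in two stages on within-gene unit proportions,
where units are transcripts or transcripts collapsed by shared CCDS id
(falling back to identical CDS interval sets; non-coding transcripts
form flagged singletons). Stage 1 screens genes: per-unit rank-sum
p-values on per-cell proportions are combined by Šidák and BH across
genes yields the overall FDR. Because unit proportions sum to one, a
$k$-unit gene has $k-1$ free dimensions — for $k=2$ the two per-unit
tests are the same test — so the Šidák exponent is $k-1$; with
exponent $k$ the screen p-value is visibly super-uniform under label
permutation, which the test suite checks by KS test. Stage 2 confirms
units within screened genes (Holm within gene). A unit is significant
only when OFDR < 0.05, the confirmed p < 0.05, and the pooled-count
proportion difference strictly exceeds 10%. Genes whose transcripts all
share one CDS therefore produce no CDS-usage units at all — UTR-only
switches cannot leak into the CDS analysis.

For significant genes the dominant up- and down-switching units (max
and min proportion difference) are compared: CDS length difference
(flagged as protein-changing above 20 bp), exon-set symmetric
difference, and — when a domain table is supplied — domains whose
CDS-relative span maps to genomic bases absent from the partner
isoform.

## Allele-specific expression

At each somatic mutation site, per-cell pileup counts are split into
wild-type, mutant and other (neither allele). The sequencing error rate
is $\epsilon = C_{other}/(C_{wt}+C_{mut}+C_{other})$. Two estimation
modes exist: the per-cell ratio is the literal definition but
degenerates to 0 whenever a cell shows no other-base read, making any
single mutant read "significant"; the default therefore pools
$\epsilon$ per site across cells and applies a floor of 0.001. Under
the null that mutant reads are sequencing errors, the one-sided p-value
is $P(X \ge C_{mut})$ with $X \sim \mathrm{Bin}(n, \epsilon)$ and $n =
C_{wt}+C_{mut}+C_{other}$ (the denominator of $\epsilon$ suggests total
reads; the choice is documented and switchable by construction of the
inputs). Using $\epsilon$ rather than $\epsilon/3$ as the
mutant-specific error expectation is conservative: misreads land on
three bases but the test charges the full error rate to one. BH
correction runs across all tested (site, cell) pairs; confirmation
additionally requires allelic coverage $C_{wt}+C_{mut} \ge 3$ in cancer
cells or $\ge 10$ in normal cells, where mutant alleles are not
expected. FDR is controlled globally per run; per-patient control is a
matter of running per patient.

Allelic matrices (wt/mut/total × cell) are normalized like expression
— counts per million mapped reads of the cell, `log(CPM/10 + 1)` — and
correlated (Pearson) with highly-variable-gene expression over cells
with allelic coverage (≥ 15 by default; correlations on fewer cells are
too unstable to cluster). The shift `r_mut − r_wt` per gene is the
quantity of interest; genes are clustered on their shift profiles.

## Signatures

Module scores use binned control genes: all genes are ranked by average
log expression into 25 equal-frequency bins and each set gene draws 100
controls from its own bin (with replacement when the bin is small);
the score is mean set expression minus mean control expression per
cell. The iCMS score of a subtype is its up-set score minus its
down-set score; a patient is assigned to the subtype with the higher
mean score over its cancer cells, with a configurable tie margin below
which the patient stays unassigned (the assignment rule operates on
cancer cells only, so normal-cell content cannot move it). The tie
margin defaults to 0 — any nonzero ties are astronomically unlikely on
continuous scores — and is exposed because the appropriate margin is a
judgment call no data can fix. Subtype-consistent calls require the
same direction against both comparators (the other subtype and normal
epithelium) at fold change ≥ 2 / ΔPSI ≥ 0.1 with p < 0.05, which makes
the classes mutually exclusive by construction.

## The synthetic-data generator

The generator emulates the data structure the statistics consume: genes
built from an 8-exon backbone (200 bp exons, 600 bp introns) whose
isoforms are derived by structural variant operations (exon skip,
intron retention, splice-site shifts of 60 bp, alternative first/last
exons, mutually exclusive exons, UTR-end moves), CDS anchored between
the middles of the second and second-to-last exons so internal variants
change the CDS while terminal/UTR variants do not; two cancer/normal
groups split over patients and two technology batches; log-normal
library sizes (default median 20,000 reads/cell, σ = 0.3 on the log);
negative-binomial counts with shared dispersion 0.3 around expected
isoform means. Proportions are encoded through expected means rather
than per-cell Dirichlet draws so every planted effect has closed-form
truth: an APA gene's groups differ in expected expressed-UTR length by
exactly the configured Δbp; a splicing gene's inclusion PSI is 0.5
versus 0.5 + ΔPSI; a usage gene's isoform-1 proportion switches between
the configured vectors. Allelic counts at mutation sites use
zero-inflated Poisson coverage (default mean 6, 40% dropout),
uniform sequencing error splitting misreads 1/3 onto the mutant base
and 2/3 onto the remaining bases, and carrier cells whose
mut/(wt+mut) expectation equals the configured mutant allele fraction
exactly.

What the generator does not emulate — and what passing tests therefore
do not establish about real data: read-level errors and coverage bias
along transcripts, ambient RNA and doublets, patient-level biological
heterogeneity beyond the planted effects, correlated gene programs
(genes are independent given depth), isoform-assembly artifacts, and
batch effects beyond a label (batches differ only in which patients
they contain). Calibration results transfer to real data only to the
extent that rank-based tests are insensitive to these distributional
details.

## Numerical choices and degenerate inputs

Threshold comparisons at published boundaries carry a ±1e-9 guard so
binary rounding cannot flip a decision: a ΔPSI of exactly 0.1 passes
the "≥ 0.1" gate even when computed as 0.6 − 0.5, and a proportion
difference of exactly 0.10 fails the "exceeding 10%" gate. Ties in HVG
ranking break by gene id; all-zero cells normalize to all-zero columns
and are flagged; genes never expressed in the baseline are dropped from
deviation analysis with a log entry; events with too few defined-PSI
cells, genes with one unit, and sites with insufficient covered cells
are skipped with an explicit reason rather than silently. Singular
model fits classify as `unchanged` with a diagnostic note.

## Problem sizes

The test suite and `scripts/acceptance.R` run at sizes chosen to give
stable Monte-Carlo estimates while keeping a laptop-scale run: null
calibration on one 100-gene × 400-cell cohort plus 50 carrier-free
allelic cohorts (15 sites × 200 cells); recovery at 20 planted APA
genes (200 + 200 cells), 20 planted SE events (40 + 40 cells — the
deliberate small-sample power check), 5 usage switches (200 + 200
cells), and ~1,000 covered carrier site-cells. The whole suite runs in
well under a minute.

## Known limitations

Event extraction enumerates local binary events; complex nested
rearrangements are represented only through their pairwise-detectable
parts. The two-stage usage test is rank-based and trades the parametric
power of a Dirichlet-multinomial fit for distribution-freeness; it is
swappable behind the same interface. The per-patient splicing mode
pools reference cells across patients of the same cohort, so
patient-specific reference shifts are absorbed into the comparison. The
mutation caller assumes error reads are uniform across bases; locus-
specific error profiles (homopolymers, strand bias) are not modeled.
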