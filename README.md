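# sciso

Isoform-level statistics for long-read single-cell RNA-seq of tumor and
matched normal epithelium.

Long reads resolve full-length transcripts per cell, which makes three
questions tractable that short-read scRNA-seq cannot answer directly:
how 3'/5'-UTR lengths shift in cancer cells (alternative
polyadenylation), how local splicing changes between cell populations,
and whether somatic mutant alleles are expressed in individual cells.
`sciso` implements the statistics for all three, plus the shared
substrate (normalization, QC, differential expression, differential
transcript usage, gene-set scoring) and a seeded synthetic-data
generator with planted effects so that every stage can be validated
against known ground truth.

## The statistics at the core

**Expressed UTR length and UTR deviation.** For gene *g* in cell *c*,
with isoform expression *C<sub>i,c</sub>* (TPM) and isoform UTR length
*l<sub>i</sub>*:

    EUL_gc = Σ_i M_gi · C_ic · l_i / Σ_i M_gi · C_ic
    GUD_gc = EUL_gc − mean(EUL_g over normal cells)

where *M<sub>gi</sub>* is the gene-isoform incidence indicator. Genes
are classified shortened/lengthened with a linear (mixed) model of GUD
on cell type with a technology-batch term, requiring coefficient sign,
p < 0.05 and a signed mean difference beyond ±10 bp.

**Local splicing events and PSI.** Seven event types (SE, RI, A5, A3,
AF, AL, MX) are enumerated from transcript structure; PSI of an event
in a cell is the inclusion-form share of the event's isoform TPM.
Differential splicing uses a per-cell rank-sum test with the
p < 0.05 and |ΔPSI| ≥ 0.1 gates, splicing-factor coupling is assessed
by Pearson correlation of PSI with factor expression plus hierarchical
clustering, and signature overlap between comparisons is tested with
the hypergeometric upper tail.

**Differential transcript/CDS usage.** A two-stage screen/confirm
procedure on within-gene unit proportions (units are transcripts, or
transcripts collapsed by shared CCDS), with BH over gene screens
(overall FDR) and Holm-confirmed units, significant only when
OFDR < 0.05 and the pooled proportion difference exceeds 10%. Isoform
switches are annotated for coding changes (> 20 bp CDS difference) and
lost protein domains.

**Allele-specific mutation calling.** From per-cell pileup counts
(C<sub>wt</sub>, C<sub>mut</sub>, C<sub>other</sub>) at somatic
mutation sites, the sequencing error rate is ε =
C<sub>other</sub>/(C<sub>wt</sub>+C<sub>mut</sub>+C<sub>other</sub>)
(pooled per site by default); a one-sided binomial test asks whether
observed mutant reads exceed error expectation, BH-corrected across all
(site, cell) pairs, confirmed when FDR < 0.05 with allelic coverage ≥ 3
in cancer or ≥ 10 in normal cells. Downstream: mutant-allele dominance
per site and correlation-shift analysis (r<sub>mut</sub> −
r<sub>wt</sub> against highly variable genes).

## Worked example

```r
library(sciso)

cfg <- sim_config(seed = 11, n_genes = 30,
                  planted_apa = data.frame(delta_utr3 = -50, group = "cancer"),
                  n_cells_per_group = c(normal = 100, cancer = 100))
anno <- simulate_annotation(cfg)
sim  <- simulate_expression(cfg, anno)
meta <- sim$expr$metadata

nm  <- normalize_expression(sim$expr, "isoform")
eul <- compute_eul(nm, anno, end = "3p")
dev <- compute_gud(eul, meta$cell_id[meta$cell_class == "normal"])
calls <- classify_utr_genes(dev,
                            setNames(meta$cell_type, meta$cell_id),
                            target = "stem_TA_like", reference = "stem_TA",
                            batch = setNames(meta$batch, meta$cell_id))
calls[calls$gene_id == "apa01", ]
#>   gene_id  estimate      p_value mean_diff     class note
#> 1   apa01 -44.10053 5.752276e-14 -44.10053 shortened
```

The planted gene carried a −50 bp expected 3'-UTR shift in cancer
cells; the classifier recovers a −44 bp cell-type coefficient (the
per-cell proportion noise attenuates the estimate slightly) at
p ≈ 6e-14 and labels the gene `shortened`. The 30 background genes are
null and remain `unchanged`.

Splicing, usage and allelic stages work the same way: plant effects
with `planted_das` / `planted_dtu` / `mutant_cell_fraction`, then run
`extract_events()` → `compute_psi()` → `differential_splicing()`,
`usage_test()` → `annotate_cds_change()`, or
`call_mutations()` → `mutant_dominance()` / `correlation_shift()`.

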